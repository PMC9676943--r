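#' Length of the human mitochondrial reference (rCRS), in base pairs
#'
#' All positions handled by this package are 1-based coordinates on the
#' 16,569-bp revised Cambridge Reference Sequence.
#' @export
MT_GENOME_LENGTH <- 16569L

#' Mitochondrial gene map
#'
#' Coordinates of the 13 protein-coding genes, the two rRNAs and the control
#' region on the rCRS, with the OXPHOS complex each protein gene belongs to
#' (MT-ND* = CI, MT-CYB = CIII, MT-CO* = CIV, MT-ATP6/8 = CV). Positions not
#' covered by any listed feature are treated as tRNA/intergenic for the
#' purposes of functional-class assignment in the synthetic annotation table.
#'
#' @return A data.frame with columns `gene`, `start`, `end`, `class`, `complex`.
#' @export
mt_gene_map <- function() {
  df <- data.frame(
    gene = c("control_region_5p", "MT-RNR1", "MT-RNR2",
             "MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
             "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
             "MT-CYB", "control_region_3p"),
    start = c(1L, 648L, 1671L,
              3307L, 4470L, 5904L, 7586L, 8366L, 8527L,
              9207L, 10059L, 10470L, 10760L, 12337L, 14149L,
              14747L, 16024L),
    end = c(576L, 1601L, 3229L,
            4262L, 5511L, 7445L, 8269L, 8572L, 9207L,
            9990L, 10404L, 10766L, 12137L, 14148L, 14673L,
            15887L, 16569L),
    class = c("control_region", "rRNA", "rRNA",
              rep("protein", 13), "control_region"),
    complex = c("none", "none", "none",
                "CI", "CI", "CIV", "CIV", "CV", "CV",
                "CIV", "CI", "CI", "CI", "CI", "CI",
                "CIII", "none"),
    stringsAsFactors = FALSE
  )
  df
}

#' Locate a position on the mitochondrial gene map
#'
#' @param position Integer vector of 1-based rCRS positions.
#' @return data.frame with columns `position`, `gene`, `class`, `complex`.
#'   Positions falling outside every mapped feature are reported as
#'   gene `"tRNA_or_intergenic"`, class `"tRNA"`, complex `"none"`.
#' @export
mt_gene_at <- function(position) {
  stopifnot(all(position >= 1L), all(position <= MT_GENOME_LENGTH))
  gm <- mt_gene_map()
  gene <- rep("tRNA_or_intergenic", length(position))
  class <- rep("tRNA", length(position))
  complex <- rep("none", length(position))
  for (i in seq_len(nrow(gm))) {
    hit <- position >= gm$start[i] & position <= gm$end[i]
    gene[hit] <- gm$gene[i]
    class[hit] <- gm$class[i]
    complex[hit] <- gm$complex[i]
  }
  data.frame(position = as.integer(position), gene = gene, class = class,
             complex = complex, stringsAsFactors = FALSE)
}

#' Map a gene symbol to its OXPHOS complex
#'
#' @param gene Character vector of mitochondrial gene symbols.
#' @return Character vector in \{"CI","CIII","CIV","CV","none"\}.
#' @export
oxphos_complex <- function(gene) {
  out <- rep("none", length(gene))
  out[grepl("^MT-ND", gene)] <- "CI"
  out[gene == "MT-CYB"] <- "CIII"
  out[grepl("^MT-CO[123]$", gene)] <- "CIV"
  out[gene %in% c("MT-ATP6", "MT-ATP8")] <- "CV"
  out
}

# transition partner of a base (mtDNA marker variants are transitions)
transition_base <- function(base) {
  c(A = "G", G = "A", C = "T", T = "C")[base]
}

#' Synthetic reference base at an rCRS coordinate
#'
#' The package does not ship the rCRS sequence itself; simulated cohorts use a
#' deterministic synthetic reference in which haplogroup-panel positions carry
#' the ancestral (non-marker) allele, so that every marker on a sample's
#' haplogroup path appears as an ALT allele, and all remaining positions cycle
#' through A/C/G/T by coordinate. It is labelled synthetic wherever written.
#'
#' @param position Integer vector of positions in `[1, 16569]`.
#' @return Character vector of reference bases.
#' @export
synthetic_reference_base <- function(position) {
  stopifnot(all(position >= 1L), all(position <= MT_GENOME_LENGTH))
  base <- c("A", "C", "G", "T")[(as.integer(position) %% 4L) + 1L]
  panel <- default_marker_panel()
  idx <- match(position, panel$position)
  hit <- !is.na(idx)
  base[hit] <- panel$ancestral_allele[idx[hit]]
  base
}
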