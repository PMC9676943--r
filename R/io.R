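# Deterministic TSV writing: fixed separators, no quoting, "." for NA,
# so identical cohorts serialize byte-identically.
write_tsv_det <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    v <- df[[cn]]
    df[[cn]] <- ifelse(is.na(v), NA,
                       ifelse(v == round(v) & abs(v) < 1e15,
                              sprintf("%d", as.integer(round(v))),
                              sprintf("%.6g", v)))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", eol = "\n", fileEncoding = "UTF-8")
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write one sample's calls as a VCF 4.2 file
#'
#' CHROM is `chrM`, positions are 1-based coordinates on the 16,569-bp
#' mitochondrial reference. Per-genotype FORMAT fields: `AD` (ref,alt
#' depths), `DP` (total depth), `HF` (heteroplasmy fraction in `[0,1]`),
#' `SB` (ref_fw,ref_rv,alt_fw,alt_rv). Per-caller support is carried in the
#' INFO key `CALLERS`; mean base/mapping qualities in `BQ`/`MQ`; rejected
#' sites (if present, column `fail_reasons`) carry `FAIL=<codes>` and a
#' non-PASS FILTER.
#'
#' @param calls data.frame of calls for one sample.
#' @param sample_id Sample name for the genotype column.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(calls, sample_id, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=mitofam(synthetic)",
    sprintf("##contig=<ID=chrM,length=%d>", MT_GENOME_LENGTH),
    "##INFO=<ID=CALLERS,Number=1,Type=String,Description=\"Supporting callers\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean base quality\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean mapping quality\">",
    "##INFO=<ID=FAIL,Number=1,Type=String,Description=\"Failed filter reason codes\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Ref,alt read depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=HF,Number=1,Type=Float,Description=\"Heteroplasmy fraction\">",
    "##FORMAT=<ID=SB,Number=4,Type=Integer,Description=\"ref_fw,ref_rv,alt_fw,alt_rv\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_id))
  calls <- calls[order(calls$position, calls$alt_allele), , drop = FALSE]
  dp <- calls$ref_fw + calls$ref_rv + calls$alt_fw + calls$alt_rv
  fail <- if ("fail_reasons" %in% names(calls)) calls$fail_reasons else ""
  filter <- ifelse(nzchar(fail), "FAIL", "PASS")
  info <- sprintf("CALLERS=%s;BQ=%s;MQ=%s",
                  gsub(",", "|", calls$callers),
                  sprintf("%.1f", calls$mean_base_quality),
                  sprintf("%.1f", calls$mean_mapping_quality))
  info <- ifelse(nzchar(fail), paste0(info, ";FAIL=", fail), info)
  gt <- ifelse(calls$heteroplasmy_fraction > 0.95, "1/1", "0/1")
  body <- sprintf(
    "chrM\t%d\t.\t%s\t%s\t.\t%s\t%s\tGT:AD:DP:HF:SB\t%s:%d,%d:%d:%.6g:%d,%d,%d,%d",
    calls$position, calls$ref_allele, calls$alt_allele, filter, info, gt,
    calls$ref_fw + calls$ref_rv, calls$alt_fw + calls$alt_rv, dp,
    calls$heteroplasmy_fraction,
    calls$ref_fw, calls$ref_rv, calls$alt_fw, calls$alt_rv)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a per-sample VCF back into a calls table
#'
#' Parses a VCF written by [write_sample_vcf()] (or any VCF exposing AD/DP/
#' HF/SB genotype fields) through `vcfR` and rebuilds the site-call table.
#' Records without an SB field get `NA` strand counts, which downstream
#' filtering treats as "skip the SOR filter".
#'
#' @param path VCF file path.
#' @return data.frame of calls (`sample_id`, `position`, `ref_allele`,
#'   `alt_allele`, strand counts, qualities, `callers`,
#'   `heteroplasmy_fraction`).
#' @export
read_sample_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  sample_id <- colnames(v@gt)[2]
  sb <- tryCatch(vcfR::extract.gt(v, "SB"), error = function(e) NULL)
  hfv <- tryCatch(vcfR::extract.gt(v, "HF"), error = function(e) NULL)
  info <- fix[, "INFO"]
  grab <- function(keys, key) {
    vapply(regmatches(keys, gregexpr(paste0("(^|;)", key, "=[^;]*"), keys)),
           function(x) if (length(x) && nzchar(x[1]))
             sub(paste0(".*", key, "="), "", x[1]) else NA_character_,
           character(1))
  }
  n <- nrow(fix)
  sbm <- matrix(NA_integer_, n, 4)
  if (!is.null(sb)) {
    parts <- strsplit(as.character(sb[, 1]), ",")
    for (i in seq_len(n))
      if (length(parts[[i]]) == 4) sbm[i, ] <- as.integer(parts[[i]])
  }
  hf <- if (!is.null(hfv)) as.numeric(hfv[, 1]) else rep(NA_real_, n)
  data.frame(
    sample_id = sample_id,
    position = as.integer(fix[, "POS"]),
    ref_allele = fix[, "REF"], alt_allele = fix[, "ALT"],
    ref_fw = sbm[, 1], ref_rv = sbm[, 2], alt_fw = sbm[, 3],
    alt_rv = sbm[, 4],
    mean_base_quality = as.numeric(grab(info, "BQ")),
    mean_mapping_quality = as.numeric(grab(info, "MQ")),
    callers = gsub("\\|", ",", grab(info, "CALLERS")),
    heteroplasmy_fraction = hf,
    stringsAsFactors = FALSE)
}

#' Write a simulated cohort to disk
#'
#' Emits `pedigree.tsv`, `genotypes.tsv`, `annotation.tsv`,
#' `contamination.tsv` (level as percent, matching contamination-checker
#' report conventions), `covariates.tsv`, `truth.json` and one VCF per
#' sample under `vcf/`. Output is deterministic: the same cohort always
#' produces byte-identical files.
#'
#' @param cohort A `mito_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mito_cohort"))
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  write_tsv_det(cohort$pedigree, file.path(dir, "pedigree.tsv"))
  write_tsv_det(cohort$genotypes, file.path(dir, "genotypes.tsv"))
  write_tsv_det(cohort$annotation, file.path(dir, "annotation.tsv"))
  contam <- data.frame(sample_id = cohort$contamination$sample_id,
                       level_percent = 100 * cohort$contamination$level,
                       used_minor_count = cohort$contamination$used_minor_count,
                       stringsAsFactors = FALSE)
  write_tsv_det(contam, file.path(dir, "contamination.tsv"))
  write_tsv_det(cohort$covariates, file.path(dir, "covariates.tsv"))
  for (id in unique(cohort$calls$sample_id))
    write_sample_vcf(cohort$calls[cohort$calls$sample_id == id, , drop = FALSE],
                     id, file.path(dir, "vcf", paste0(id, ".vcf")))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return A `mito_cohort` (without the originating config).
#' @export
read_cohort <- function(dir) {
  pedigree <- read_tsv_plain(file.path(dir, "pedigree.tsv"))
  genotypes <- read_tsv_plain(file.path(dir, "genotypes.tsv"))
  annotation <- read_tsv_plain(file.path(dir, "annotation.tsv"))
  contam <- read_tsv_plain(file.path(dir, "contamination.tsv"))
  covariates <- read_tsv_plain(file.path(dir, "covariates.tsv"))
  vcfs <- list.files(file.path(dir, "vcf"), pattern = "\\.vcf$",
                     full.names = TRUE)
  calls <- do.call(rbind, lapply(vcfs, read_sample_vcf))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  structure(list(config = NULL, pedigree = pedigree, calls = calls,
                 genotypes = genotypes, annotation = annotation,
                 contamination = data.frame(
                   sample_id = contam$sample_id,
                   level = contam$level_percent / 100,
                   used_minor_count = contam$used_minor_count,
                   stringsAsFactors = FALSE),
                 covariates = covariates, truth = truth),
            class = "mito_cohort")
}

#' @export
print.mito_cohort <- function(x, ...) {
  cat("Synthetic mtDNA family cohort:",
      length(unique(x$pedigree$family_id)), "families,",
      nrow(x$pedigree), "individuals,",
      if (!is.null(x$calls)) nrow(x$calls) else 0, "variant calls\n")
  invisible(x)
}
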