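#' Default mtDNA haplogroup marker panel
#'
#' The diagnostic SNP panel used for haplogroup assignment, one row per marker:
#' 2706A (H), 1438A (H2), 72C (HV0), 10034C (I), 16069T (J), 3010A (J1 when
#' the J context is matched, H1 when the H context is matched), 7476T (J2),
#' 11251G (JT), 10550G (K), 10688G (L2'3'4'6), 1018G (L3), 13650C (L3'4),
#' 15043A (M), 9540T (N), 10238C (N1), 13780G (N1a), 12705C (R), 1888A (T),
#' 11467G (U), 1811G (U2'3'4'7'8'9), 16270T (U5), 3197C (U5a'b), 3348G (U6),
#' with U5 refinement markers 14793G and 16256T defining U5a and 150T defining
#' U5b. Labels form a forest via the `parent` column; `context_dependent`
#' flags the shared 3010A marker, which is only interpreted under an already
#' matched parent clade.
#'
#' `ancestral_allele` is the non-marker allele at each position (the
#' transition partner; mtDNA diagnostic markers are transitions), used by the
#' synthetic cohort generator to type off-path panel positions.
#'
#' @return data.frame with columns `label`, `parent`, `position`,
#'   `marker_allele`, `ancestral_allele`, `context_dependent`.
#' @export
default_marker_panel <- function() {
  if (!is.null(.panel_cache$panel)) return(.panel_cache$panel)
  rows <- list(
    # label           parent        pos     allele context
    c("L2'3'4'6",      NA,           10688L, "G",   FALSE),
    c("L3'4",          "L2'3'4'6",   13650L, "C",   FALSE),
    c("L3",            "L3'4",       1018L,  "G",   FALSE),
    c("M",             "L3",         15043L, "A",   FALSE),
    c("N",             "L3",         9540L,  "T",   FALSE),
    c("N1",            "N",          10238L, "C",   FALSE),
    c("N1a",           "N1",         13780L, "G",   FALSE),
    c("I",             "N1a",        10034L, "C",   FALSE),
    c("R",             "N",          12705L, "C",   FALSE),
    c("HV0",           "R",          72L,    "C",   FALSE),
    c("H",             "R",          2706L,  "A",   FALSE),
    c("H1",            "H",          3010L,  "A",   TRUE),
    c("H2",            "H",          1438L,  "A",   FALSE),
    c("JT",            "R",          11251L, "G",   FALSE),
    c("J",             "JT",         16069L, "T",   FALSE),
    c("J1",            "J",          3010L,  "A",   TRUE),
    c("J2",            "J",          7476L,  "T",   FALSE),
    c("T",             "JT",         1888L,  "A",   FALSE),
    c("U",             "R",          11467L, "G",   FALSE),
    c("U2'3'4'7'8'9",  "U",          1811L,  "G",   FALSE),
    c("U5",            "U",          16270L, "T",   FALSE),
    c("U5a'b",         "U5",         3197L,  "C",   FALSE),
    c("U5a",           "U5a'b",      14793L, "G",   FALSE),
    c("U5a",           "U5a'b",      16256L, "T",   FALSE),
    c("U5b",           "U5a'b",      150L,   "T",   FALSE),
    c("U6",            "U",          3348L,  "G",   FALSE),
    c("K",             "U",          10550L, "G",   FALSE)
  )
  m <- do.call(rbind, rows)
  panel <- data.frame(
    label = m[, 1],
    parent = m[, 2],
    position = as.integer(m[, 3]),
    marker_allele = m[, 4],
    context_dependent = as.logical(m[, 5]),
    stringsAsFactors = FALSE
  )
  panel$ancestral_allele <- unname(transition_base(panel$marker_allele))
  validate_marker_panel(panel)
  .panel_cache$panel <- panel
  panel
}

.panel_cache <- new.env(parent = emptyenv())

validate_marker_panel <- function(panel) {
  need <- c("label", "parent", "position", "marker_allele",
            "ancestral_allele", "context_dependent")
  stopifnot(all(need %in% names(panel)))
  if (any(panel$position < 1L | panel$position > MT_GENOME_LENGTH))
    stop("panel positions must lie in [1, ", MT_GENOME_LENGTH, "]")
  if (!all(panel$marker_allele %in% c("A", "C", "G", "T")))
    stop("panel marker alleles must be A/C/G/T")
  known <- unique(panel$label)
  bad <- setdiff(stats::na.omit(unique(panel$parent)), known)
  if (length(bad))
    stop("panel parent labels missing from panel: ", paste(bad, collapse = ", "))
  invisible(panel)
}

# ancestor chain (self first, root last) for a label in the panel forest
panel_path <- function(label, panel) {
  path <- character(0)
  cur <- label
  while (!is.na(cur)) {
    if (cur %in% path) stop("cycle in marker panel at label ", cur)
    path <- c(path, cur)
    parents <- unique(panel$parent[panel$label == cur])
    cur <- if (length(parents)) parents[[1]] else NA_character_
  }
  path
}

#' Aggregate a haplogroup label into its super-haplogroup
#'
#' Reporting scheme: any H clade (H, H1, H2, ...) maps to "H"; J, T and JT
#' clades map to "JT"; U and K clades map to "UK"; everything else (HV, HV0,
#' I, L, M, N, R, W, X, ...) maps to "Others". HV/HV0 are *not* counted under
#' H in this scheme.
#'
#' @param label Character vector of haplogroup labels (not "undetermined").
#' @return Character vector in \{"H","JT","UK","Others"\}.
#' @export
super_haplogroup <- function(label) {
  if (any(is.na(label) | label == "" | label == "undetermined"))
    stop("super_haplogroup() requires an assigned haplogroup label; ",
         "undetermined calls must be excluded or counted separately")
  out <- rep("Others", length(label))
  out[grepl("^H[0-9]*$", label)] <- "H"
  out[label == "JT" | grepl("^[JT][0-9]*[a-z]*$", label)] <- "JT"
  out[grepl("^[UK]", label)] <- "UK"
  out
}
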