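#' Strand odds ratio (SOR) for strand-bias filtering
#'
#' Symmetric odds-ratio statistic over the strand-split ref/alt read counts,
#' computed with a pseudocount of 1 added to every cell: with
#' `r1 = ref_fw + 1`, `r2 = ref_rv + 1`, `a1 = alt_fw + 1`, `a2 = alt_rv + 1`,
#' \deqn{R = \frac{r_1 a_2}{r_2 a_1} + \frac{r_2 a_1}{r_1 a_2}}
#' \deqn{SOR = \ln R + \ln\frac{\min(r_1,r_2)}{\max(r_1,r_2)} -
#'             \ln\frac{\min(a_1,a_2)}{\max(a_1,a_2)}}
#' High values indicate the alternative allele is supported by one strand
#' only; calls with SOR above the configured cutoff (default 4) are treated
#' as strand-bias artifacts. The statistic is symmetric under exchanging
#' forward and reverse strands on both alleles simultaneously.
#'
#' @param ref_fw,ref_rv,alt_fw,alt_rv Non-negative read counts (vectorized).
#' @return Numeric vector of SOR values.
#' @examples
#' compute_sor(10, 10, 5, 5)   # log(2)
#' compute_sor(10, 10, 10, 0)  # ~4.80, fails the default cutoff of 4
#' @export
compute_sor <- function(ref_fw, ref_rv, alt_fw, alt_rv) {
  counts <- cbind(ref_fw, ref_rv, alt_fw, alt_rv)
  if (any(is.na(counts)) || any(counts < 0))
    stop("strand counts must be non-negative")
  r1 <- ref_fw + 1; r2 <- ref_rv + 1
  a1 <- alt_fw + 1; a2 <- alt_rv + 1
  big <- (r1 * a2) / (r2 * a1) + (r2 * a1) / (r1 * a2)
  ref_ratio <- pmin(r1, r2) / pmax(r1, r2)
  alt_ratio <- pmin(a1, a2) / pmax(a1, a2)
  log(big) + log(ref_ratio) - log(alt_ratio)
}

#' Filter configuration for consensus heteroplasmy calling
#'
#' @param min_base_quality Minimum mean base quality (Phred), default 20.
#' @param min_mapping_quality Minimum mean mapping quality (Phred), default 20.
#' @param max_sor Maximum strand odds ratio, default 4.
#' @param mono_allelic_floor Alternative alleles below this fraction are
#'   ignored when judging mono-allelicity (defaults to `detection_floor`);
#'   without it, sequencing noise would mark every deep site multi-allelic.
#' @param consensus_rule `"strict_intersection"` (keep calls present in every
#'   caller's set) or `"majority"` (present in at least two).
#' @param detection_floor Minimum reportable heteroplasmy fraction,
#'   default 0.002 (0.2%); must be below 0.15.
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(min_base_quality = 20, min_mapping_quality = 20,
                          max_sor = 4, mono_allelic_floor = detection_floor,
                          consensus_rule = c("strict_intersection", "majority"),
                          detection_floor = 0.002) {
  consensus_rule <- match.arg(consensus_rule)
  cfg <- list(min_base_quality = min_base_quality,
              min_mapping_quality = min_mapping_quality,
              max_sor = max_sor,
              mono_allelic_floor = mono_allelic_floor,
              consensus_rule = consensus_rule,
              detection_floor = detection_floor)
  num <- unlist(cfg[c("min_base_quality", "min_mapping_quality", "max_sor",
                      "mono_allelic_floor", "detection_floor")])
  if (any(is.na(num)) || any(num < 0))
    stop("filter thresholds must be non-negative")
  if (detection_floor >= 0.15)
    stop("detection_floor must be below 0.15 (the private-variant threshold)")
  structure(cfg, class = "filter_config")
}

#' Heteroplasmy fraction from read counts
#'
#' @param ref_fw,ref_rv,alt_fw,alt_rv Read counts.
#' @return `(alt_fw+alt_rv)/(ref_fw+ref_rv+alt_fw+alt_rv)`; `NA` at zero depth.
#' @export
heteroplasmy_fraction <- function(ref_fw, ref_rv, alt_fw, alt_rv) {
  tot <- ref_fw + ref_rv + alt_fw + alt_rv
  ifelse(tot > 0, (alt_fw + alt_rv) / tot, NA_real_)
}

#' Apply per-site quality, mono-allelicity and strand-bias filters
#'
#' Evaluates each candidate call against the configured thresholds and
#' returns the complete set of failed-filter reason codes:
#' `quality` (mean base quality below threshold), `mapping` (mean mapping
#' quality below threshold), `multi_allelic` (two or more alternative alleles
#' above `mono_allelic_floor` at the same position in the same sample),
#' `strand_bias` (SOR above `max_sor`), `no_coverage` (zero total depth).
#' A call passes iff its reason set is empty. Calls without strand-split
#' counts (all four `NA`) skip the SOR filter with a warning.
#'
#' @param calls data.frame of site calls with columns `position`,
#'   `ref_allele`, `alt_allele`, `ref_fw`, `ref_rv`, `alt_fw`, `alt_rv`,
#'   `mean_base_quality`, `mean_mapping_quality` (optionally `sample_id`;
#'   mono-allelicity is judged within sample when present).
#' @param config A [filter_config()].
#' @return The input data.frame with added columns `heteroplasmy_fraction`,
#'   `sor`, `pass` (logical) and `fail_reasons` (comma-separated codes).
#' @export
apply_site_filters <- function(calls, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  need <- c("position", "ref_allele", "alt_allele", "ref_fw", "ref_rv",
            "alt_fw", "alt_rv", "mean_base_quality", "mean_mapping_quality")
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop("calls table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(calls)
  reasons <- vector("list", n)

  hf <- heteroplasmy_fraction(calls$ref_fw, calls$ref_rv,
                              calls$alt_fw, calls$alt_rv)
  calls$heteroplasmy_fraction <- hf

  sb_missing <- is.na(calls$ref_fw) & is.na(calls$ref_rv) &
    is.na(calls$alt_fw) & is.na(calls$alt_rv)
  if (any(sb_missing))
    warning(sum(sb_missing),
            " call(s) lack strand-split counts; SOR filter skipped for them")
  sor <- rep(NA_real_, n)
  ok <- !sb_missing
  sor[ok] <- compute_sor(calls$ref_fw[ok], calls$ref_rv[ok],
                         calls$alt_fw[ok], calls$alt_rv[ok])
  calls$sor <- sor

  grp <- if ("sample_id" %in% names(calls))
    paste(calls$sample_id, calls$position) else as.character(calls$position)
  considered <- !is.na(hf) & hf >= config$mono_allelic_floor
  n_alts <- stats::ave(ifelse(considered, 1L, 0L), grp, FUN = sum)

  for (i in seq_len(n)) {
    rs <- character(0)
    depth_known <- !sb_missing[i]
    if (depth_known &&
        (calls$ref_fw[i] + calls$ref_rv[i] + calls$alt_fw[i] + calls$alt_rv[i]) == 0)
      rs <- c(rs, "no_coverage")
    if (!is.na(calls$mean_base_quality[i]) &&
        calls$mean_base_quality[i] < config$min_base_quality)
      rs <- c(rs, "quality")
    if (!is.na(calls$mean_mapping_quality[i]) &&
        calls$mean_mapping_quality[i] < config$min_mapping_quality)
      rs <- c(rs, "mapping")
    if (considered[i] && n_alts[i] >= 2L)
      rs <- c(rs, "multi_allelic")
    if (!is.na(sor[i]) && sor[i] > config$max_sor)
      rs <- c(rs, "strand_bias")
    reasons[[i]] <- rs
  }
  calls$pass <- lengths(reasons) == 0L
  calls$fail_reasons <- vapply(reasons, paste, character(1), collapse = ",")
  calls
}

#' Merge per-caller call sets into a consensus
#'
#' Calls are keyed by `(position, alt_allele)` within a sample. Under
#' `strict_intersection` a key is retained only when present in every
#' supplied caller set; under `majority`, when present in at least two.
#' The merged call records the supporting caller set and carries the median
#' heteroplasmy fraction across supporting callers (which always lies within
#' the range of the callers' fractions).
#'
#' @param calls_a,calls_b,calls_c data.frames with columns `position`,
#'   `ref_allele`, `alt_allele`, `heteroplasmy_fraction` (plus any strand
#'   count/quality columns, taken from the first supporting caller).
#'   `calls_c` may be `NULL` for a two-caller merge.
#' @param rule `"strict_intersection"` or `"majority"`.
#' @return data.frame of consensus calls with a `callers` column like "A,B,C".
#' @export
consensus_merge <- function(calls_a, calls_b, calls_c = NULL,
                            rule = c("strict_intersection", "majority")) {
  rule <- match.arg(rule)
  sets <- Filter(Negate(is.null), list(A = calls_a, B = calls_b, C = calls_c))
  caller_names <- names(sets)
  sets <- lapply(sets, function(s) {
    stopifnot(all(c("position", "ref_allele", "alt_allele",
                    "heteroplasmy_fraction") %in% names(s)))
    s$key <- paste(s$position, s$alt_allele, sep = ":")
    s
  })
  all_keys <- unique(unlist(lapply(sets, `[[`, "key")))
  if (!length(all_keys)) {
    out <- sets[[1]][0, , drop = FALSE]
    out$callers <- character(0)
    out$key <- NULL
    return(out)
  }
  # ref-allele consistency across callers at shared positions
  refs <- do.call(rbind, lapply(sets, function(s)
    s[, c("position", "ref_allele")]))
  dup <- refs[!duplicated(refs), ]
  if (anyDuplicated(dup$position))
    stop("conflicting ref alleles across callers at position(s): ",
         paste(unique(dup$position[duplicated(dup$position)]), collapse = ", "))

  support <- vapply(sets, function(s) all_keys %in% s$key,
                    logical(length(all_keys)))
  if (length(all_keys) == 1L) support <- matrix(support, nrow = 1)
  need <- if (rule == "strict_intersection") length(sets) else 2L
  keep <- rowSums(support) >= need
  kept_keys <- all_keys[keep]
  if (!length(kept_keys)) {
    out <- sets[[1]][0, , drop = FALSE]
    out$callers <- character(0)
    out$key <- NULL
    return(out)
  }
  rows <- lapply(seq_along(kept_keys), function(j) {
    key <- kept_keys[j]
    sup <- caller_names[support[match(key, all_keys), ]]
    first <- sets[[sup[1]]]
    row <- first[first$key == key, , drop = FALSE][1, ]
    hfs <- vapply(sup, function(cn) {
      s <- sets[[cn]]
      s$heteroplasmy_fraction[s$key == key][1]
    }, numeric(1))
    row$heteroplasmy_fraction <- stats::median(hfs)
    row$callers <- paste(sort(sup), collapse = ",")
    row
  })
  out <- do.call(rbind, rows)
  out$key <- NULL
  rownames(out) <- NULL
  out[order(out$position, out$alt_allele), , drop = FALSE]
}

#' Contamination-based sample gating
#'
#' A sample is excluded from the low-level heteroplasmy analysis when its
#' contamination level exceeds 1% (strict) *and* its count of minor
#' heteroplasmies used by the contamination checker is positive. Haplogroup
#' analysis always retains the sample: contamination at these levels does not
#' affect the major-allele haplogroup assignment.
#'
#' @param report List or one-row data.frame with `sample_id`, `level`
#'   (proportion in `[0,1]`) and `used_minor_count`, or `NULL`/missing.
#' @param missing_action What to do without a report: `"include"` (default,
#'   with a warning) or `"error"`.
#' @return `"exclude_from_heteroplasmy"` or `"include_all"`.
#' @export
contamination_gate <- function(report,
                               missing_action = c("include", "error")) {
  missing_action <- match.arg(missing_action)
  if (is.null(report) || (is.data.frame(report) && nrow(report) == 0)) {
    if (missing_action == "error") stop("contamination report missing")
    warning("contamination report missing; sample included")
    return("include_all")
  }
  level <- as.numeric(report$level)
  used <- as.numeric(report$used_minor_count)
  if (is.na(level) || level < 0 || level > 1)
    stop("contamination level must be a proportion in [0,1]")
  if (level > 0.01 && used > 0) "exclude_from_heteroplasmy" else "include_all"
}
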