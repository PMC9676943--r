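#' Heteroplasmy binning schemes
#'
#' Two partitions of the low-level heteroplasmy window `(0, 15%]`:
#' * `"coarse"`: the four regression classes "15%-5%" (`[5,15]`),
#'   "4.9%-1%" (`[1,5)`), "0.9%-0.5%" (`[0.5,1)`), "0.4%-0%" (`(0,0.5)`),
#'   all on the percent scale, lower-closed/upper-open except the topmost
#'   bin, which is closed at 15%.
#' * `"fine"`: classes of width 0.1% from 0 up to 4.9% (the last fine class
#'   is `[4.9,5)`), plus a single class from 5% to 15%, for
#'   heteroplasmy-profile plots.
#'
#' @param fraction Numeric vector of heteroplasmy fractions in `(0, 0.15]`.
#' @param scheme `"coarse"` or `"fine"`.
#' @return Character vector of bin labels.
#' @examples
#' bin_heteroplasmy(c(0.003, 0.05, 0.0095))
#' @export
bin_heteroplasmy <- function(fraction, scheme = c("coarse", "fine")) {
  scheme <- match.arg(scheme)
  if (any(is.na(fraction)) || any(fraction <= 0) || any(fraction > 0.15))
    stop("heteroplasmy fractions must lie in (0, 0.15]; ",
         "route >15% variants to the private-variant triage instead")
  pct <- fraction * 100
  if (scheme == "coarse") {
    labels <- c("0.4%-0%", "0.9%-0.5%", "4.9%-1%", "15%-5%")
    idx <- findInterval(pct, c(0.5, 1, 5)) + 1L
    labels[idx]
  } else {
    # [0,0.1), [0.1,0.2), ..., [4.9,5), [5,15]
    lo <- findInterval(pct, seq(0.1, 5, by = 0.1)) # 0..50
    ifelse(lo >= 50, "15%-5%",
           sprintf("%.1f%%-%.1f%%", lo / 10 + 0.1, lo / 10))
  }
}

#' Detect putative de novo heteroplasmic variants in a mother-offspring pair
#'
#' An offspring consensus variant is putatively de novo when its heteroplasmy
#' fraction lies in `[floor, ceiling]` (default 0.2%-15%) and the same
#' `(position, alt_allele)` is not observed in the mother's consensus at or
#' above `floor`. "Not inherited" is operationalized as the mother's fraction
#' being below the detection floor rather than literally zero: sequencing
#' cannot certify absolute absence below the reportable window. A different
#' alternative allele at the same position in the mother does not make the
#' offspring variant inherited.
#'
#' @param offspring,mother data.frames of consensus calls (`position`,
#'   `alt_allele`, `heteroplasmy_fraction`); both samples must have passed
#'   the contamination gate.
#' @param floor,ceiling Heteroplasmy window; defaults 0.002 and 0.15.
#' @param pair_id Optional identifier recorded on the result.
#' @return Object of class `denovo_set`: list with `pair_id`, `variants`
#'   (the de novo calls with the mother's fraction attached) and `n_denovo`.
#' @export
detect_denovo_mtdna <- function(offspring, mother, floor = 0.002,
                                ceiling = 0.15, pair_id = NULL) {
  if (is.null(mother))
    stop("missing mother profile for pair ",
         if (is.null(pair_id)) "<unnamed>" else pair_id)
  stopifnot(all(c("position", "alt_allele", "heteroplasmy_fraction") %in%
                  names(offspring)))
  stopifnot(floor > 0, ceiling > floor)
  in_window <- !is.na(offspring$heteroplasmy_fraction) &
    offspring$heteroplasmy_fraction >= floor &
    offspring$heteroplasmy_fraction <= ceiling
  cand <- offspring[in_window, , drop = FALSE]
  mkey <- paste(mother$position, mother$alt_allele)
  mdetected <- mkey[!is.na(mother$heteroplasmy_fraction) &
                      mother$heteroplasmy_fraction >= floor]
  ckey <- paste(cand$position, cand$alt_allele)
  dn <- cand[!(ckey %in% mdetected), , drop = FALSE]
  midx <- match(paste(dn$position, dn$alt_allele), mkey)
  dn$mother_fraction <- ifelse(is.na(midx), 0,
                               mother$heteroplasmy_fraction[midx])
  rownames(dn) <- NULL
  structure(list(pair_id = pair_id, variants = dn, n_denovo = nrow(dn)),
            class = "denovo_set")
}

#' mtDNA mutational rate per site per transmission
#'
#' `rate = n_denovo / (n_pairs * 16569)`: de novo heteroplasmic variants per
#' mitochondrial base pair per mother-offspring transmission. An optional
#' nonparametric bootstrap over pairs (resampling per-pair de novo counts)
#' yields a percentile confidence interval.
#'
#' @param n_denovo Total de novo variant count (or, when `pair_counts` is
#'   given, it is taken as `sum(pair_counts)` and must agree).
#' @param n_pairs Number of mother-offspring pairs (>= 1).
#' @param pair_counts Optional integer vector of per-pair de novo counts of
#'   length `n_pairs`, enabling the bootstrap CI.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf_level CI level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `rate_estimate`: list with `n_denovo`, `n_pairs`,
#'   `genome_length`, `rate`, and `ci` (or `NULL`).
#' @examples
#' mutational_rate(295, 117)$rate  # 1.52e-4
#' @export
mutational_rate <- function(n_denovo, n_pairs, pair_counts = NULL,
                            n_boot = 1000, conf_level = 0.95, seed = NULL) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (n_denovo < 0) stop("n_denovo must be non-negative")
  if (!is.null(pair_counts)) {
    if (length(pair_counts) != n_pairs)
      stop("pair_counts must have length n_pairs")
    if (sum(pair_counts) != n_denovo)
      stop("sum(pair_counts) must equal n_denovo")
  }
  rate <- n_denovo / (n_pairs * MT_GENOME_LENGTH)
  ci <- NULL
  if (!is.null(pair_counts) && n_boot > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv))
        get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    boots <- vapply(seq_len(n_boot), function(b) {
      res <- sample(pair_counts, n_pairs, replace = TRUE)
      sum(res) / (n_pairs * MT_GENOME_LENGTH)
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  }
  structure(list(n_denovo = n_denovo, n_pairs = n_pairs,
                 genome_length = MT_GENOME_LENGTH, rate = rate, ci = ci),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("mtDNA mutational rate: %d de novo / (%d pairs x %d bp) = %.3g substitutions/site/transmission\n",
              x$n_denovo, x$n_pairs, x$genome_length, x$rate))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap CI: [%.3g, %.3g]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Cohort-wide de novo detection over mother-offspring pairs
#'
#' Runs [detect_denovo_mtdna()] for every child in the pedigree whose mother
#' is present, skipping samples excluded by the contamination gate.
#'
#' @param calls data.frame of consensus calls for all samples (`sample_id`,
#'   `position`, `alt_allele`, `heteroplasmy_fraction`).
#' @param pedigree Pedigree data.frame (`individual_id`, `mother_id`, `role`,
#'   `affected`).
#' @param excluded_samples Sample ids to drop (contaminated).
#' @param floor,ceiling Heteroplasmy window.
#' @return data.frame with one row per pair: `pair_id`, `offspring_id`,
#'   `mother_id`, `affected`, `n_denovo`; attribute `"variants"` holds the
#'   concatenated de novo variant table.
#' @export
detect_denovo_cohort <- function(calls, pedigree, excluded_samples = character(0),
                                 floor = 0.002, ceiling = 0.15) {
  kids <- pedigree[!is.na(pedigree$mother_id) &
                     pedigree$role %in% c("proband", "sibling"), , drop = FALSE]
  kids <- kids[!(kids$individual_id %in% excluded_samples) &
                 !(kids$mother_id %in% excluded_samples), , drop = FALSE]
  res <- vector("list", nrow(kids))
  vars <- vector("list", nrow(kids))
  for (i in seq_len(nrow(kids))) {
    kid <- kids$individual_id[i]
    mom <- kids$mother_id[i]
    ds <- detect_denovo_mtdna(
      calls[calls$sample_id == kid, , drop = FALSE],
      calls[calls$sample_id == mom, , drop = FALSE],
      floor = floor, ceiling = ceiling,
      pair_id = paste(mom, kid, sep = "->"))
    res[[i]] <- data.frame(pair_id = ds$pair_id, offspring_id = kid,
                           mother_id = mom, affected = kids$affected[i],
                           n_denovo = ds$n_denovo, stringsAsFactors = FALSE)
    if (ds$n_denovo > 0) {
      v <- ds$variants
      v$pair_id <- ds$pair_id
      vars[[i]] <- v
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(pair_id = character(0), offspring_id = character(0),
                      mother_id = character(0), affected = logical(0),
                      n_denovo = integer(0))
  attr(out, "variants") <- do.call(rbind, Filter(Negate(is.null), vars))
  out
}

#' High-confidence nuclear trio de novo filter
#'
#' Retains a candidate de novo call iff it is supported by both callers, all
#' three trio members have depth `DP >= 12` and genotype quality `GQ > 20`,
#' the child's allele balance satisfies `0.30 <= AB <= 0.70`, both parents
#' are homozygous reference and the child heterozygous, and the population
#' allele frequency passes the frequency filter (default: exclude sites with
#' `MAF >= maf_cutoff`; direction configurable). A missing `population_maf`
#' is treated as 0.
#'
#' @param records data.frame with columns `variant_id`, `child_id`,
#'   `child_dp`, `mother_dp`, `father_dp`, `child_gq`, `mother_gq`,
#'   `father_gq`, `child_gt`, `mother_gt`, `father_gt` (genotypes as
#'   "0/0", "0/1", "1/1"), `child_ab`, `population_maf`, `caller1`,
#'   `caller2` (logical support flags).
#' @param maf_cutoff Population-frequency cutoff, default 0.001.
#' @param maf_direction `"exclude_common"` (default; drop `MAF >= cutoff`)
#'   or `"exclude_rare"` (drop `MAF < cutoff`).
#' @return list with `retained` (the passing records) and `per_child_counts`
#'   (data.frame `child_id`, `n_dnm`), for use as a regression covariate.
#' @export
filter_nuclear_dnm <- function(records, maf_cutoff = 0.001,
                               maf_direction = c("exclude_common",
                                                 "exclude_rare")) {
  maf_direction <- match.arg(maf_direction)
  need <- c("variant_id", "child_id", "child_dp", "mother_dp", "father_dp",
            "child_gq", "mother_gq", "father_gq", "child_gt", "mother_gt",
            "father_gt", "child_ab", "population_maf", "caller1", "caller2")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    stop("trio table lacks columns: ", paste(missing_cols, collapse = ", "))
  gt_ok <- function(gt) gt %in% c("0/0", "0/1", "1/0", "1/1", "0|0", "0|1",
                                  "1|0", "1|1")
  malformed <- !(gt_ok(records$child_gt) & gt_ok(records$mother_gt) &
                   gt_ok(records$father_gt))
  if (any(malformed)) {
    warning(sum(malformed), " trio record(s) with malformed genotypes skipped")
    records <- records[!malformed, , drop = FALSE]
  }
  is_het <- function(gt) gt %in% c("0/1", "1/0", "0|1", "1|0")
  is_homref <- function(gt) gt %in% c("0/0", "0|0")
  maf <- ifelse(is.na(records$population_maf), 0, records$population_maf)
  maf_pass <- if (maf_direction == "exclude_common")
    maf < maf_cutoff else maf >= maf_cutoff
  keep <- records$caller1 & records$caller2 &
    records$child_dp >= 12 & records$mother_dp >= 12 & records$father_dp >= 12 &
    records$child_gq > 20 & records$mother_gq > 20 & records$father_gq > 20 &
    records$child_ab >= 0.30 & records$child_ab <= 0.70 &
    is_het(records$child_gt) & is_homref(records$mother_gt) &
    is_homref(records$father_gt) & maf_pass
  retained <- records[keep, , drop = FALSE]
  counts <- as.data.frame(table(child_id = retained$child_id),
                          stringsAsFactors = FALSE)
  all_children <- unique(records$child_id)
  n_dnm <- stats::setNames(rep(0L, length(all_children)), all_children)
  if (nrow(counts)) n_dnm[counts$child_id] <- counts$Freq
  list(retained = retained,
       per_child_counts = data.frame(child_id = all_children,
                                     n_dnm = as.integer(unname(n_dnm)),
                                     stringsAsFactors = FALSE))
}
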