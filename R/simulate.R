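#' Configuration for synthetic family-cohort simulation
#'
#' Defines the study conditions emulated by the generator: a cohort of ASD
#' families (default 98, of which 73 simplex), with parents, probands and
#' unaffected siblings; deep amplicon-style mtDNA coverage (default mean
#' 16,718x); maternal transmission of haplogroup backbones, private variants
#' and shared low-level heteroplasmies with a germline-bottleneck resampling
#' step; de novo heteroplasmic variants per transmission at a configurable
#' per-site rate; somatic variants accumulating linearly with age at
#' sub-percent fractions; group-wise log-normal mtDNA content with a lower
#' location in affected subjects; Poisson nuclear de novo mutation counts
#' increasing with paternal age at conception; and a logistic severity model
#' on the affected children.
#'
#' @param n_families Number of families (default 98).
#' @param simplex_fraction Proportion of simplex families, i.e. exactly one
#'   affected child (default 73/98); multiplex families carry two.
#' @param sibling_rate Expected unaffected siblings per family (Poisson;
#'   default 59/98).
#' @param haplogroup_freqs Named numeric vector of haplogroup frequencies
#'   summing to 1 over labels resolvable by the marker panel; the default
#'   aggregates the control-population distribution onto panel labels.
#' @param denovo_rate_mu De novo substitutions per site per mother-offspring
#'   transmission (default 1.5e-4).
#' @param inherited_het_rate Expected shared mother-offspring low-level
#'   (<15%) heteroplasmies per mother (Poisson; default 3).
#' @param somatic_rate_per_year Expected somatic sub-percent variants per
#'   year of age (default 0.05).
#' @param mean_coverage Mean reads per site (Poisson; default 16718).
#' @param strand_bias Strand skew of alternative reads in `[0,1]`: 0 is
#'   balanced, 1 places all alt reads on the forward strand.
#' @param content_params List with `meanlog`, `sdlog` and `affected_shift`
#'   (additive shift of `meanlog` in affected subjects; negative = lower
#'   content) for the log-normal mtDNA copies/cell distribution.
#' @param nuclear_dnm_intercept,nuclear_dnm_age_slope Poisson mean of a
#'   child's nuclear DNM count = intercept + slope * paternal age at
#'   conception.
#' @param severity_logit_effects Named numeric log-odds for severe (vs
#'   mild/moderate) phenotype; recognised names: `intercept`, `het_15_5`
#'   (any 5-15% heteroplasmic variant), `paternal_H`, `paternal_JT`.
#' @param bottleneck_size Effective segregating mtDNA copies for the
#'   mother-to-child heteroplasmy bottleneck (binomial resampling;
#'   default 200).
#' @param seed Integer seed fixing every downstream draw.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 98,
                              simplex_fraction = 73 / 98,
                              sibling_rate = 59 / 98,
                              haplogroup_freqs = default_haplogroup_freqs(),
                              denovo_rate_mu = 1.5e-4,
                              inherited_het_rate = 3,
                              somatic_rate_per_year = 0.05,
                              mean_coverage = 16718,
                              strand_bias = 0,
                              content_params = list(meanlog = log(560),
                                                    sdlog = 0.35,
                                                    affected_shift =
                                                      log(505 / 564)),
                              nuclear_dnm_intercept = 20,
                              nuclear_dnm_age_slope = 1.5,
                              severity_logit_effects =
                                c(intercept = 0.3, het_15_5 = log(3.32),
                                  paternal_H = log(0.32),
                                  paternal_JT = log(0.15)),
                              bottleneck_size = 200,
                              seed = 1L) {
  cfg <- list(n_families = n_families, simplex_fraction = simplex_fraction,
              sibling_rate = sibling_rate,
              haplogroup_freqs = haplogroup_freqs,
              denovo_rate_mu = denovo_rate_mu,
              inherited_het_rate = inherited_het_rate,
              somatic_rate_per_year = somatic_rate_per_year,
              mean_coverage = mean_coverage, strand_bias = strand_bias,
              content_params = content_params,
              nuclear_dnm_intercept = nuclear_dnm_intercept,
              nuclear_dnm_age_slope = nuclear_dnm_age_slope,
              severity_logit_effects = severity_logit_effects,
              bottleneck_size = bottleneck_size,
              seed = as.integer(seed))
  check_prop <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("configuration error: ", name, " must be a proportion in [0,1]")
  }
  check_rate <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("configuration error: ", name, " must be a non-negative rate")
  }
  check_prop("simplex_fraction"); check_prop("strand_bias")
  for (nm in c("sibling_rate", "denovo_rate_mu", "inherited_het_rate",
               "somatic_rate_per_year", "nuclear_dnm_intercept",
               "nuclear_dnm_age_slope"))
    check_rate(nm)
  if (cfg$n_families < 1)
    stop("configuration error: n_families must be >= 1")
  if (cfg$mean_coverage <= 0)
    stop("configuration error: mean_coverage must be positive")
  hf <- cfg$haplogroup_freqs
  if (is.null(names(hf)) || any(!nzchar(names(hf))))
    stop("configuration error: haplogroup_freqs must be named")
  if (any(hf < 0) || abs(sum(hf) - 1) > 1e-9)
    stop("configuration error: haplogroup_freqs must be non-negative and ",
         "sum to 1 (within 1e-9)")
  panel <- default_marker_panel()
  unknown <- setdiff(names(hf), panel$label)
  if (length(unknown))
    stop("configuration error: haplogroup_freqs labels not in marker panel: ",
         paste(unknown, collapse = ", "))
  structure(cfg, class = "simulation_config")
}

#' Default haplogroup frequencies for simulated cohorts
#'
#' Control-population haplogroup distribution (n = 242) aggregated onto the
#' labels resolvable by the marker panel: clades the panel cannot
#' distinguish (e.g. H3/H5, U1-U4, W, X, R0a, HV) are folded into their
#' nearest panel-resolvable ancestor (H, U, N, R, HV0) so that classifier
#' round-trips are exact on clean backbones.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_haplogroup_freqs <- function() {
  counts <- c(H = 87, H1 = 14, J = 27, T = 24, U = 19, U5a = 4, U5b = 4,
              K = 15, HV0 = 14, I = 9, L3 = 2, M = 0, N = 17, R = 6)
  counts / sum(counts)
}

#' Simulate strand-split read counts at one site
#'
#' The alternative-allele read total is a binomial draw with size `coverage`
#' and success probability `true_fraction`; alt reads land on the forward
#' strand with probability `(1 + strand_bias)/2` (so 0 is symmetric in
#' expectation and 1 puts every alt read on one strand), reference reads
#' with probability 1/2.
#'
#' @param true_fraction Heteroplasmy fraction(s) in `[0,1]`.
#' @param coverage Read depth (positive integer, recycled).
#' @param strand_bias Strand skew in `[0,1]`.
#' @param seed Optional local seed.
#' @return data.frame with columns `ref_fw`, `ref_rv`, `alt_fw`, `alt_rv`.
#' @export
simulate_site_counts <- function(true_fraction, coverage, strand_bias = 0,
                                 seed = NULL) {
  if (any(is.na(true_fraction)) || any(true_fraction < 0) ||
      any(true_fraction > 1))
    stop("true_fraction must lie in [0,1]")
  if (any(coverage <= 0)) stop("coverage must be positive")
  if (strand_bias < 0 || strand_bias > 1)
    stop("strand_bias must lie in [0,1]")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  n <- max(length(true_fraction), length(coverage))
  f <- rep_len(true_fraction, n)
  cov <- rep_len(as.integer(coverage), n)
  alt <- stats::rbinom(n, cov, f)
  alt_fw <- stats::rbinom(n, alt, (1 + strand_bias) / 2)
  ref <- cov - alt
  ref_fw <- stats::rbinom(n, ref, 0.5)
  data.frame(ref_fw = ref_fw, ref_rv = ref - ref_fw,
             alt_fw = alt_fw, alt_rv = alt - alt_fw)
}

# non-panel positions available for random variant placement
.sim_free_positions <- function(panel)
  setdiff(seq_len(MT_GENOME_LENGTH), panel$position)

# truth variant table for one individual; fractions are *true* fractions
sim_individual_variants <- function(cfg, hap, age, panel,
                                    mother_truth = NULL, is_child = FALSE,
                                    backbone = NULL, free_positions = NULL) {
  if (is.null(free_positions)) free_positions <- .sim_free_positions(panel)
  pos <- integer(0); alt <- character(0); frac <- numeric(0)
  orig <- character(0)
  pick_positions <- function(n, avoid) {
    p <- sample(free_positions, n)
    while (any(p %in% avoid))
      p[p %in% avoid] <- sample(free_positions, sum(p %in% avoid))
    p
  }
  add <- function(p, f, o, a = NULL) {
    # random positions are off-panel, so the reference base is the plain cycle
    if (is.null(a))
      a <- unname(transition_base(c("A", "C", "G", "T")[(p %% 4L) + 1L]))
    pos <<- c(pos, as.integer(p)); alt <<- c(alt, a)
    frac <<- c(frac, f); orig <<- c(orig, rep_len(o, length(p)))
  }

  # haplogroup backbone (inherited maternally for children by construction)
  if (is.null(backbone)) {
    path <- panel_path(hap, panel)
    bk <- panel[panel$label %in% path, , drop = FALSE]
    bk <- bk[!duplicated(bk$position), , drop = FALSE]
    backbone <- stats::setNames(bk$marker_allele, bk$position)
  }
  if (length(backbone))
    add(as.integer(names(backbone)), rep(1, length(backbone)), "backbone",
        unname(backbone))

  if (is.null(mother_truth)) {
    # founder: private variants of their own
    n_priv <- stats::rpois(1, 0.6)
    if (n_priv > 0) {
      p <- pick_positions(n_priv, pos)
      f <- ifelse(stats::runif(n_priv) < 0.7, 1,
                  stats::runif(n_priv, 0.16, 0.95))
      add(p, f, "private")
    }
    # founder low-level heteroplasmies (shared with offspring if mother)
    n_inh <- stats::rpois(1, cfg$inherited_het_rate)
    if (n_inh > 0) {
      p <- pick_positions(n_inh, pos)
      f <- pmin(pmax(stats::rbeta(n_inh, 0.8, 79.2), 0.004), 0.149)
      add(p, f, "inherited_low")
    }
  } else {
    # child: inherit mother's non-backbone variants through the bottleneck
    mv <- mother_truth[mother_truth$origin != "backbone", , drop = FALSE]
    if (nrow(mv)) {
      f_c <- ifelse(mv$fraction >= 0.999, 1,
                    stats::rbinom(nrow(mv), cfg$bottleneck_size,
                                  mv$fraction) / cfg$bottleneck_size)
      keep <- f_c > 0
      if (any(keep))
        add(mv$position[keep], f_c[keep],
            ifelse(f_c[keep] < 0.15, "inherited_low", "inherited_high"),
            mv$alt_allele[keep])
    }
    # de novo heteroplasmies of this transmission
    n_dn <- stats::rpois(1, cfg$denovo_rate_mu * MT_GENOME_LENGTH)
    if (n_dn > 0) {
      mother_detectable <- mother_truth$position[mother_truth$fraction >=
                                                   0.002]
      p <- pick_positions(n_dn, c(pos, mother_detectable))
      # log-uniform inside the detection window, away from the 0.2% floor so
      # binomial observation noise cannot push true events below it
      f <- exp(stats::runif(n_dn, log(0.003), log(0.145)))
      add(p, f, "denovo")
    }
  }
  # somatic variants accumulating with age, all sub-percent
  n_som <- stats::rpois(1, cfg$somatic_rate_per_year * age)
  if (n_som > 0) {
    avoid <- pos
    if (!is.null(mother_truth)) avoid <- c(avoid, mother_truth$position)
    p <- pick_positions(n_som, avoid)
    add(p, stats::runif(n_som, 0.0003, 0.01), "somatic")
  }
  data.frame(position = pos, alt_allele = alt, fraction = frac,
             origin = orig, stringsAsFactors = FALSE)
}

# observed calls (strand counts, qualities, caller support) from truth
sim_observe_calls <- function(cfg, sample_id, truth_variants) {
  n <- nrow(truth_variants)
  if (n == 0)
    return(NULL)
  depth <- pmax(stats::rpois(n, cfg$mean_coverage), 10L)
  cnt <- simulate_site_counts(truth_variants$fraction, depth,
                              cfg$strand_bias)
  hf <- heteroplasmy_fraction(cnt$ref_fw, cnt$ref_rv, cnt$alt_fw, cnt$alt_rv)
  detected <- (cnt$alt_fw + cnt$alt_rv) >= 2L
  out <- data.frame(
    sample_id = sample_id,
    position = truth_variants$position,
    ref_allele = synthetic_reference_base(truth_variants$position),
    alt_allele = truth_variants$alt_allele,
    ref_fw = cnt$ref_fw, ref_rv = cnt$ref_rv,
    alt_fw = cnt$alt_fw, alt_rv = cnt$alt_rv,
    mean_base_quality = round(stats::runif(n, 28, 38), 1),
    mean_mapping_quality = round(stats::runif(n, 40, 60), 1),
    callers = "A,B,C",
    heteroplasmy_fraction = hf,
    stringsAsFactors = FALSE)
  out[detected, , drop = FALSE]
}

#' Simulate a complete synthetic family cohort
#'
#' Generates pedigree, per-sample variant calls with strand-split pileup
#' counts, marker-panel genotypes, a variant annotation table, contamination
#' reports, covariates and a truth record, under the conditions encoded in
#' the [simulation_config()]. The number of simplex families is the rounded
#' configured proportion (so the default yields exactly 73 of 98). The same
#' configuration and seed always reproduce the identical cohort; with
#' `out_dir` set, the emitted files are byte-identical across runs.
#'
#' @param config A [simulation_config()].
#' @param out_dir Optional directory: when given, all cohort files (pedigree
#'   TSV, per-sample VCFs, genotype/annotation/contamination/covariate TSVs,
#'   truth JSON) are written there via [write_cohort()].
#' @return Object of class `mito_cohort`: list with `config`, `pedigree`,
#'   `calls`, `genotypes`, `annotation`, `contamination`, `covariates`,
#'   `truth`.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  panel <- default_marker_panel()
  hf <- config$haplogroup_freqs
  n_simplex <- round(config$n_families * config$simplex_fraction)
  free_positions <- .sim_free_positions(panel)
  backbones <- lapply(stats::setNames(nm = names(hf)), function(l) {
    path <- panel_path(l, panel)
    bk <- panel[panel$label %in% path, , drop = FALSE]
    bk <- bk[!duplicated(bk$position), , drop = FALSE]
    stats::setNames(bk$marker_allele, bk$position)
  })
  geno_backbones <- lapply(stats::setNames(nm = names(hf)),
                           haplogroup_backbone, panel = panel)

  ped <- list(); calls <- list(); genos <- list(); covs <- list()
  truth <- list()
  sev_eff <- config$severity_logit_effects
  eff <- function(nm) if (nm %in% names(sev_eff)) sev_eff[[nm]] else 0

  for (fam in seq_len(config$n_families)) {
    fam_id <- sprintf("F%03d", fam)
    simplex <- fam <= n_simplex
    mother_hap <- sample(names(hf), 1, prob = hf)
    father_hap <- sample(names(hf), 1, prob = hf)
    father_age_con <- min(max(round(stats::rnorm(1, 35, 5.5)), 20), 60)
    mother_age_con <- min(max(round(stats::rnorm(1, 32, 4.5)), 18), 50)
    n_aff <- if (simplex) 1L else 2L
    n_sib <- stats::rpois(1, config$sibling_rate)
    kid_ages <- sample(3:16, n_aff + n_sib, replace = TRUE)
    mother_age <- mother_age_con + max(kid_ages)
    father_age <- father_age_con + max(kid_ages)

    mother_id <- paste0(fam_id, ".M")
    father_id <- paste0(fam_id, ".F")
    mother_truth <- sim_individual_variants(
      config, mother_hap, mother_age, panel,
      backbone = backbones[[mother_hap]], free_positions = free_positions)
    father_truth <- sim_individual_variants(
      config, father_hap, father_age, panel,
      backbone = backbones[[father_hap]], free_positions = free_positions)

    fam_members <- list(
      list(id = mother_id, role = "mother", sex = "F", affected = FALSE,
           hap = mother_hap, age = mother_age, truth = mother_truth,
           age_con = mother_age_con),
      list(id = father_id, role = "father", sex = "M", affected = FALSE,
           hap = father_hap, age = father_age, truth = father_truth,
           age_con = father_age_con))

    for (k in seq_len(n_aff + n_sib)) {
      affected <- k <= n_aff
      kid_id <- sprintf("%s.%s%d", fam_id, if (affected) "P" else "S",
                        if (affected) k else k - n_aff)
      sex <- if (affected) {
        if (stats::runif(1) < 93 / 117) "M" else "F"
      } else {
        if (stats::runif(1) < 0.5) "M" else "F"
      }
      kt <- sim_individual_variants(config, mother_hap, kid_ages[k], panel,
                                    mother_truth = mother_truth,
                                    is_child = TRUE,
                                    backbone = backbones[[mother_hap]],
                                    free_positions = free_positions)
      fam_members[[length(fam_members) + 1L]] <-
        list(id = kid_id, role = if (affected) "proband" else "sibling",
             sex = sex, affected = affected, hap = mother_hap,
             age = kid_ages[k], truth = kt, age_con = NA_integer_)
    }

    for (m in fam_members) {
      is_kid <- m$role %in% c("proband", "sibling")
      content <- exp(stats::rnorm(
        1, config$content_params$meanlog +
          if (m$affected) config$content_params$affected_shift else 0,
        config$content_params$sdlog))
      n_dnm <- if (is_kid)
        stats::rpois(1, config$nuclear_dnm_intercept +
                       config$nuclear_dnm_age_slope * father_age_con)
      else NA_integer_
      het_15_5 <- any(m$truth$fraction >= 0.05 & m$truth$fraction <= 0.15)
      severity <- NA_character_
      if (m$affected) {
        eta <- eff("intercept") +
          eff("het_15_5") * het_15_5 +
          eff("paternal_H") * (super_haplogroup(father_hap) == "H") +
          eff("paternal_JT") * (super_haplogroup(father_hap) == "JT")
        severity <- if (stats::runif(1) < stats::plogis(eta)) "severe"
          else sample(c("moderate", "mild"), 1, prob = c(0.75, 0.25))
      }
      ped[[length(ped) + 1L]] <- data.frame(
        individual_id = m$id, family_id = fam_id,
        mother_id = if (is_kid) mother_id else NA_character_,
        father_id = if (is_kid) father_id else NA_character_,
        role = m$role, sex = m$sex, affected = m$affected,
        severity = severity, age = m$age, age_at_conception = m$age_con,
        family_type = if (simplex) "simplex" else "multiplex",
        stringsAsFactors = FALSE)
      obs <- sim_observe_calls(config, m$id, m$truth)
      if (!is.null(obs)) calls[[length(calls) + 1L]] <- obs
      bkb <- geno_backbones[[m$hap]]
      genos[[length(genos) + 1L]] <- data.frame(
        sample_id = m$id, position = as.integer(names(bkb)),
        allele = unname(bkb), stringsAsFactors = FALSE)
      covs[[length(covs) + 1L]] <- data.frame(
        individual_id = m$id, mtdna_content = round(content, 1),
        nuclear_dnm = n_dnm,
        paternal_age_conception = father_age_con,
        maternal_age_conception = mother_age_con,
        stringsAsFactors = FALSE)
      truth[[m$id]] <- list(
        haplogroup = m$hap,
        denovo_positions = m$truth$position[m$truth$origin == "denovo"],
        inherited_low = m$truth[m$truth$origin == "inherited_low",
                                c("position", "fraction")],
        het_15_5 = het_15_5,
        paternal_haplogroup = father_hap,
        mtdna_content = round(content, 1),
        nuclear_dnm = n_dnm)
    }
  }

  pedigree <- do.call(rbind, ped)
  calls <- do.call(rbind, calls)
  rownames(pedigree) <- rownames(calls) <- NULL
  genotypes <- do.call(rbind, genos)
  covariates <- do.call(rbind, covs)
  contamination <- data.frame(sample_id = pedigree$individual_id,
                              level = 0, used_minor_count = 0L,
                              stringsAsFactors = FALSE)
  annotation <- sim_annotation(calls)
  cohort <- structure(list(config = config, pedigree = pedigree,
                           calls = calls, genotypes = genotypes,
                           annotation = annotation,
                           contamination = contamination,
                           covariates = covariates, truth = truth),
                      class = "mito_cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

# synthetic annotation table for every distinct variant seen in the cohort
sim_annotation <- function(calls) {
  key <- paste(calls$position, calls$alt_allele)
  u <- !duplicated(key)
  pos <- calls$position[u]
  alt <- calls$alt_allele[u]
  ref <- calls$ref_allele[u]
  feat <- mt_gene_at(pos)
  n <- length(pos)
  fc <- character(n)
  fc[feat$class == "protein"] <-
    ifelse(stats::runif(sum(feat$class == "protein")) < 0.65,
           "missense", "synonymous")
  fc[feat$class == "rRNA"] <- "rRNA"
  fc[feat$class == "tRNA"] <- "tRNA"
  fc[feat$class == "control_region"] <- "control_region"
  mitomap <- sample(c("absent", "reported", "confirmed"), n, replace = TRUE,
                    prob = c(0.55, 0.44, 0.01))
  genbank <- ifelse(stats::runif(n) < 0.4, 0L,
                    stats::rpois(n, 20) + 1L)
  ann <- data.frame(
    position = pos, ref = ref, alt = alt,
    gene = feat$gene, functional_class = fc, complex = feat$complex,
    mitomap_status = mitomap, genbank_count = genbank,
    cadd_phred = ifelse(fc == "missense",
                        round(stats::runif(n, 0, 40), 2), NA_real_),
    mtoolbox_score = ifelse(fc == "missense",
                            round(stats::runif(n), 3), NA_real_),
    mitotip_raw = ifelse(fc == "tRNA",
                         round(stats::runif(n, 0, 20), 2), NA_real_),
    stringsAsFactors = FALSE)
  ann[order(ann$position, ann$alt), , drop = FALSE]
}

#' Inject cross-sample contamination into a sample's profile
#'
#' Adds the contaminating donor haplogroup's marker alleles as minor alleles
#' at the panel positions where donor and host backbones disagree, at the
#' stated level, and updates the contamination report (level as a
#' proportion; `used_minor_count` = number of discordant marker positions).
#' At a host marker position whose donor allele is ancestral, the host
#' call's heteroplasmy drops to `1 - level` instead.
#'
#' @param profile list with `sample_id`, `calls` (consensus-call data.frame),
#'   `haplogroup` (host label) and `contamination` (list `level`,
#'   `used_minor_count`).
#' @param level Contamination proportion in `[0, 0.5)`; at 0.5 and above the
#'   major/minor identity of the mixture would flip.
#' @param donor_haplogroup Donor haplogroup label.
#' @param panel Marker panel.
#' @return The updated profile.
#' @export
inject_contamination <- function(profile, level, donor_haplogroup,
                                 panel = default_marker_panel()) {
  if (level < 0 || level >= 0.5)
    stop("contamination level must lie in [0, 0.5)")
  if (level == 0) return(profile)
  host <- haplogroup_backbone(profile$haplogroup, panel)
  donor <- haplogroup_backbone(donor_haplogroup, panel)
  disc <- names(host)[host != donor[names(host)]]
  calls <- profile$calls
  n_minor <- 0L
  for (pos in disc) {
    donor_allele <- donor[[pos]]
    p <- as.integer(pos)
    at_pos <- which(calls$position == p)
    if (length(at_pos) && any(calls$alt_allele[at_pos] != donor_allele)) {
      # host marker call: donor carries the reference allele as minor
      i <- at_pos[1]
      calls$heteroplasmy_fraction[i] <- 1 - level
      tot <- calls$ref_fw[i] + calls$ref_rv[i] + calls$alt_fw[i] +
        calls$alt_rv[i]
      ref_n <- round(tot * level)
      calls$ref_fw[i] <- ceiling(ref_n / 2)
      calls$ref_rv[i] <- ref_n - calls$ref_fw[i]
      calls$alt_fw[i] <- ceiling((tot - ref_n) / 2)
      calls$alt_rv[i] <- (tot - ref_n) - calls$alt_fw[i]
    } else {
      # donor marker appears as a new minor alternative allele
      depth <- if (nrow(calls)) round(mean(calls$ref_fw + calls$ref_rv +
                                             calls$alt_fw + calls$alt_rv))
        else 1000L
      alt_n <- max(round(depth * level), 1L)
      new <- calls[0, , drop = FALSE]
      template <- list(
        sample_id = profile$sample_id, position = p,
        ref_allele = synthetic_reference_base(p), alt_allele = donor_allele,
        ref_fw = ceiling((depth - alt_n) / 2),
        ref_rv = (depth - alt_n) - ceiling((depth - alt_n) / 2),
        alt_fw = ceiling(alt_n / 2), alt_rv = alt_n - ceiling(alt_n / 2),
        mean_base_quality = 33, mean_mapping_quality = 50,
        callers = "A,B,C", heteroplasmy_fraction = alt_n / depth)
      new <- as.data.frame(template[names(template) %in% names(calls)],
                           stringsAsFactors = FALSE)
      miss <- setdiff(names(calls), names(new))
      for (nm in miss) new[[nm]] <- NA
      calls <- rbind(calls, new[names(calls)])
    }
    n_minor <- n_minor + 1L
  }
  profile$calls <- calls[order(calls$position), , drop = FALSE]
  profile$contamination <- list(level = level, used_minor_count = n_minor)
  profile
}
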