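#' Run the full family-cohort mtDNA analysis
#'
#' End-to-end orchestration over a (typically simulated) cohort:
#' contamination gating, per-site filtering and caller-consensus
#' enforcement, haplogroup classification from the marker-panel genotypes,
#' private-variant triage with pathogenicity classification and per-complex
#' burden tables, mother-offspring de novo detection with mutational-rate
#' estimates per group, haplogroup frequency tables against a control
#' population (simulated from the cohort's configured haplogroup
#' frequencies when none is supplied), rank-based mtDNA-content
#' comparisons, and the two stepwise regression analyses (family-matched
#' conditional logistic for ASD status; family-clustered mixed logistic for
#' severity).
#'
#' @param cohort A `mito_cohort` from [simulate_cohort()] or [read_cohort()].
#' @param filter_cfg A [filter_config()].
#' @param control_haplogroups Optional character vector of control-population
#'   haplogroup labels; when `NULL`, 242 controls are simulated from the
#'   cohort's configured frequencies (seeded from the cohort seed).
#' @param n_controls Number of controls to simulate when none are given.
#' @return list with elements `consensus`, `excluded_samples`,
#'   `haplogroups`, `triage`, `burden`, `denovo_pairs`, `rates`,
#'   `frequency_report`, `content_tests`, `risk_model`, `severity_model`.
#' @export
run_cohort_analysis <- function(cohort, filter_cfg = filter_config(),
                                control_haplogroups = NULL,
                                n_controls = 242) {
  stopifnot(inherits(cohort, "mito_cohort"))
  ped <- cohort$pedigree

  # 1. contamination gate
  gate <- vapply(seq_len(nrow(cohort$contamination)), function(i)
    contamination_gate(cohort$contamination[i, ]), character(1))
  excluded <- cohort$contamination$sample_id[gate == "exclude_from_heteroplasmy"]

  # 2. site filters + consensus rule on caller support
  filtered <- apply_site_filters(cohort$calls, filter_cfg)
  n_support <- lengths(strsplit(filtered$callers, ","))
  need <- if (filter_cfg$consensus_rule == "strict_intersection") 3L else 2L
  consensus <- filtered[filtered$pass & n_support >= need, , drop = FALSE]

  # 3. haplogroup classification (all samples, contaminated included)
  haplogroups <- classify_cohort(cohort$genotypes)

  # 4. triage of consensus variants
  panel <- default_marker_panel()
  triage <- do.call(rbind, lapply(unique(consensus$sample_id), function(id) {
    hg <- haplogroups$label[haplogroups$sample_id == id]
    keys <- if (length(hg) && !is.na(hg)) {
      path <- panel_path(hg, panel)
      pp <- panel[panel$label %in% path, ]
      paste0(pp$position, pp$marker_allele)
    } else character(0)
    partition_private(consensus[consensus$sample_id == id, , drop = FALSE],
                      keys)
  }))
  ann <- classify_pathogenicity(cohort$annotation)
  idx <- match(paste(triage$position, triage$alt_allele),
               paste(ann$position, ann$alt))
  for (cn in c("gene", "functional_class", "complex", "pathogenicity",
               "rationale"))
    triage[[cn]] <- ann[[cn]][idx]
  burden <- rbind(
    complex_burden(triage, ped, grouping = "maternal_lines"),
    complex_burden(triage, ped, grouping = "paternal_lines"))

  # 5. de novo heteroplasmy and mutational rates
  low <- consensus[consensus$heteroplasmy_fraction <= 0.15, , drop = FALSE]
  pairs <- detect_denovo_cohort(low, ped, excluded_samples = excluded,
                                floor = filter_cfg$detection_floor)
  rate_of <- function(sub) {
    if (!nrow(sub)) return(NULL)
    mutational_rate(sum(sub$n_denovo), nrow(sub),
                    pair_counts = sub$n_denovo, n_boot = 0)
  }
  rates <- list(
    asd = rate_of(pairs[pairs$affected, , drop = FALSE]),
    siblings = rate_of(pairs[!pairs$affected, , drop = FALSE]),
    pooled = rate_of(pairs))

  # 6. haplogroup frequency report (test lines vs controls)
  if (is.null(control_haplogroups)) {
    seed <- if (!is.null(cohort$config)) cohort$config$seed + 1000L else 1000L
    freqs <- if (!is.null(cohort$config)) cohort$config$haplogroup_freqs
      else default_haplogroup_freqs()
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    control_haplogroups <- sample(names(freqs), n_controls, replace = TRUE,
                                  prob = freqs)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  mat_labels <- line_haplogroups(haplogroups, ped, "maternal")
  pat_labels <- line_haplogroups(haplogroups, ped, "paternal")
  frequency_report <- rbind(
    cbind(comparison = "paternal_vs_controls",
          haplogroup_frequency_table(pat_labels, control_haplogroups)),
    cbind(comparison = "maternal_vs_controls",
          haplogroup_frequency_table(mat_labels, control_haplogroups)))

  # 7. mtDNA content comparisons
  cov <- merge(ped, cohort$covariates, by = "individual_id")
  kids <- cov[cov$role %in% c("proband", "sibling"), ]
  content_tests <- list(
    asd_vs_sibling = content_compare(list(
      asd = kids$mtdna_content[kids$affected],
      sibling = kids$mtdna_content[!kids$affected])),
    by_sex_status = tryCatch(content_compare(split(
      kids$mtdna_content,
      paste(ifelse(kids$affected, "asd", "unaffected"), kids$sex,
            sep = "_"))), error = function(e) NULL))

  # 8. regressions
  reg_data <- build_regression_data(cohort, consensus, haplogroups)
  risk_model <- tryCatch(fit_risk_model(reg_data), error = function(e)
    list(error = conditionMessage(e)))
  severity_model <- tryCatch(fit_severity_model(reg_data),
                             error = function(e)
                               list(error = conditionMessage(e)))

  list(consensus = consensus, excluded_samples = excluded,
       haplogroups = haplogroups, triage = triage, burden = burden,
       denovo_pairs = pairs, rates = rates,
       frequency_report = frequency_report, content_tests = content_tests,
       risk_model = risk_model, severity_model = severity_model)
}

# one haplogroup label per family line
line_haplogroups <- function(haplogroups, ped, line = c("maternal",
                                                        "paternal")) {
  line <- match.arg(line)
  ids <- if (line == "maternal") ped$individual_id[ped$role == "mother"]
    else ped$individual_id[ped$role == "father"]
  lab <- haplogroups$label[match(ids, haplogroups$sample_id)]
  lab[!is.na(lab)]
}

#' Haplogroup frequency table at three taxonomic levels
#'
#' Builds the frequency-report rows comparing a set of test-line haplogroup
#' labels with a control set: super-haplogroup rows (H, JT, UK, Others),
#' haplogroup rows, and sub-haplogroup rows (U5a/U5b), each tested with
#' [frequency_compare()] and BH-adjusted *within its taxonomic level*
#' (the default multiple-testing family; Fisher/chi-square chosen by
#' expected counts).
#'
#' @param test_labels,control_labels Character vectors of haplogroup labels.
#' @return data.frame as from [frequency_table()] plus a `level` column.
#' @export
haplogroup_frequency_table <- function(test_labels, control_labels) {
  n_a <- length(test_labels); n_b <- length(control_labels)
  sup_a <- super_haplogroup(test_labels)
  sup_b <- super_haplogroup(control_labels)
  hap_a <- haplogroup_row(test_labels)
  hap_b <- haplogroup_row(control_labels)
  sub_a <- test_labels[test_labels %in% c("U5a", "U5b")]
  sub_b <- control_labels[control_labels %in% c("U5a", "U5b")]

  lvl <- function(cats, xa, xb, level) {
    if (!length(cats)) return(NULL)
    cbind(level = level,
          frequency_table(cats,
                          k_a = vapply(cats, function(cc) sum(xa == cc),
                                       integer(1)),
                          n_a = n_a,
                          k_b = vapply(cats, function(cc) sum(xb == cc),
                                       integer(1)),
                          n_b = n_b))
  }
  out <- rbind(
    lvl(c("H", "JT", "UK", "Others"), sup_a, sup_b, "super_haplogroup"),
    lvl(sort(unique(c(hap_a, hap_b))), hap_a, hap_b, "haplogroup"),
    lvl(sort(unique(c(sub_a, sub_b))), sub_a, sub_b, "sub_haplogroup"))
  rownames(out) <- NULL
  out
}

# haplogroup-level reporting row for a classifier label: H clades keep their
# clade (H itself reports as "H*"), J/T/U/K clades collapse to their root,
# everything else reports as its top label
haplogroup_row <- function(label) {
  out <- label
  out[label == "H"] <- "H*"
  out[grepl("^J", label) & label != "JT"] <- "J"
  out[grepl("^T", label)] <- "T"
  out[grepl("^U", label)] <- "U"
  out[grepl("^K", label)] <- "K"
  out[grepl("^L", label)] <- "L"
  out
}

# assemble per-child regression rows
build_regression_data <- function(cohort, consensus, haplogroups) {
  ped <- cohort$pedigree
  kids <- ped[ped$role %in% c("proband", "sibling"), , drop = FALSE]
  cov <- cohort$covariates
  bins <- c("15%-5%", "4.9%-1%", "0.9%-0.5%", "0.4%-0%")
  bin_cols <- c(het_15_5 = "15%-5%", het_4_9_1 = "4.9%-1%",
                het_0_9_0_5 = "0.9%-0.5%", het_0_4_0 = "0.4%-0%")
  has_bin <- function(id, bin) {
    hf <- consensus$heteroplasmy_fraction[consensus$sample_id == id]
    hf <- hf[hf > 0 & hf <= 0.15]
    if (!length(hf)) return(FALSE)
    bin %in% bin_heteroplasmy(hf)
  }
  fathers_hg <- haplogroups$label[match(kids$father_id,
                                        haplogroups$sample_id)]
  pat_super <- ifelse(is.na(fathers_hg), NA_character_,
                      vapply(fathers_hg, function(l)
                        if (is.na(l)) NA_character_ else super_haplogroup(l),
                        character(1)))
  mt_dn <- vapply(kids$individual_id, function(id) {
    hf <- consensus$heteroplasmy_fraction[consensus$sample_id == id]
    sum(hf >= 0.002 & hf <= 0.15)
  }, numeric(1))
  df <- data.frame(
    individual_id = kids$individual_id,
    family_id = kids$family_id,
    affected = as.numeric(kids$affected),
    severity = kids$severity,
    male = as.numeric(kids$sex == "M"),
    family_multiplex = as.numeric(kids$family_type == "multiplex"),
    mtdna_content = cov$mtdna_content[match(kids$individual_id,
                                            cov$individual_id)],
    nuclear_dnm = cov$nuclear_dnm[match(kids$individual_id,
                                        cov$individual_id)],
    paternal_age = cov$paternal_age_conception[match(kids$individual_id,
                                                     cov$individual_id)],
    maternal_age = cov$maternal_age_conception[match(kids$individual_id,
                                                     cov$individual_id)],
    paternal_H = as.numeric(pat_super == "H"),
    paternal_JT = as.numeric(pat_super == "JT"),
    mtdna_denovo = mt_dn,
    stringsAsFactors = FALSE)
  for (nm in names(bin_cols))
    df[[nm]] <- as.numeric(vapply(kids$individual_id, has_bin, logical(1),
                                  bin = bin_cols[[nm]]))
  df
}

# ASD risk: families with >= 1 unaffected sibling, conditional on family
fit_risk_model <- function(reg_data) {
  fam_ok <- tapply(reg_data$affected, reg_data$family_id,
                   function(a) any(a == 1) & any(a == 0))
  d <- reg_data[reg_data$family_id %in% names(fam_ok)[fam_ok], , drop = FALSE]
  if (!nrow(d)) stop("no families with both an affected child and a sibling")
  cand <- c("mtdna_content", "male", "het_15_5", "het_4_9_1", "het_0_9_0_5",
            "het_0_4_0", "mtdna_denovo", "nuclear_dnm")
  fit_fn <- function(data, outcome, covariates)
    fit_conditional_logistic(data, outcome, "family_id", covariates)
  sel <- suppressWarnings(
    stepwise_select(d, "affected", cand, fit_fn, enter_p = 0.2))
  sel$n_cases <- sum(d$affected == 1)
  sel$n_controls <- sum(d$affected == 0)
  sel
}

# ASD severity: mild+moderate aggregated vs severe, family random intercept
fit_severity_model <- function(reg_data) {
  d <- reg_data[reg_data$affected == 1 & !is.na(reg_data$severity), ,
                drop = FALSE]
  d$severe <- as.numeric(d$severity == "severe")
  cand <- c("maternal_age", "paternal_age", "paternal_H", "paternal_JT",
            "mtdna_content", "male", "family_multiplex", "het_15_5",
            "het_4_9_1", "het_0_9_0_5", "het_0_4_0", "mtdna_denovo",
            "nuclear_dnm")
  fit_fn <- function(data, outcome, covariates)
    fit_mixed_logistic(data, outcome, "family_id", covariates)
  sel <- suppressWarnings(suppressMessages(
    stepwise_select(d, "severe", cand, fit_fn, enter_p = 0.2)))
  sel$n_mild_moderate <- sum(d$severe == 0)
  sel$n_severe <- sum(d$severe == 1)
  sel
}
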