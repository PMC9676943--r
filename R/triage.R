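#' Partition consensus variants into haplogroup-defining, private and
#' low-level streams
#'
#' A variant whose `(position, alt_allele)` pair belongs to the sample's
#' haplogroup marker path is `haplogroup_defining`. Any other variant with a
#' heteroplasmy fraction strictly above 15% is `private` (eligible for
#' pathogenicity triage); variants at or below 15% are `low_level` and are
#' analysed by the heteroplasmy/de novo module instead. Every consensus
#' variant thus lands in exactly one stream.
#'
#' @param calls data.frame of consensus calls with `position`, `alt_allele`,
#'   `heteroplasmy_fraction` (and optionally `sample_id`).
#' @param marker_keys Character vector of haplogroup-defining markers as
#'   `"<position><allele>"` (e.g. `"2706A"`), typically the
#'   `matched_markers` of the sample's [classify_from_markers()] call.
#' @param private_threshold Heteroplasmy fraction above which a non-marker
#'   variant is private; default 0.15, read strictly (">15%"), so a variant
#'   at exactly 15% goes to the low-level stream.
#' @return The input with an added `privacy` column in
#'   \{"haplogroup_defining", "private", "low_level"\}.
#' @export
partition_private <- function(calls, marker_keys,
                              private_threshold = 0.15) {
  stopifnot(all(c("position", "alt_allele", "heteroplasmy_fraction") %in%
                  names(calls)))
  key <- paste0(calls$position, calls$alt_allele)
  privacy <- ifelse(key %in% marker_keys, "haplogroup_defining",
                    ifelse(calls$heteroplasmy_fraction > private_threshold,
                           "private", "low_level"))
  calls$privacy <- privacy
  calls
}

#' Classify pathogenic potential of an annotated variant
#'
#' Decision rule: a variant is `confirmed_pathogenic` iff its MITOMAP status
#' is "confirmed". Otherwise it is `predicted_deleterious` iff it has never
#' been observed in GenBank (`genbank_count == 0`) *and* its
#' class-appropriate predictors exceed their thresholds: missense variants
#' need CADD Phred > 20 and MToolBox score > 0.43; tRNA variants need MitoTip
#' raw score > 12.66 (all strict). Anything else is `not_flagged`, with the
#' first failed criterion recorded in the rationale; a missing required score
#' yields `not_flagged` with rationale `missing_annotation`.
#'
#' @param ann data.frame of annotation records with columns `position`,
#'   `ref`, `alt`, `gene`, `functional_class`, `mitomap_status`,
#'   `genbank_count`, `cadd_phred`, `mtoolbox_score`, `mitotip_raw`.
#' @param cadd_threshold,mtoolbox_threshold,mitotip_threshold Prediction
#'   thresholds; defaults 20, 0.43 and 12.66.
#' @return The input with `pathogenicity` and `rationale` columns added.
#' @export
classify_pathogenicity <- function(ann, cadd_threshold = 20,
                                   mtoolbox_threshold = 0.43,
                                   mitotip_threshold = 12.66) {
  need <- c("functional_class", "mitomap_status", "genbank_count",
            "cadd_phred", "mtoolbox_score", "mitotip_raw")
  missing_cols <- setdiff(need, names(ann))
  if (length(missing_cols))
    stop("annotation table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(ann)
  path <- character(n)
  rationale <- character(n)
  for (i in seq_len(n)) {
    if (identical(ann$mitomap_status[i], "confirmed")) {
      path[i] <- "confirmed_pathogenic"
      rationale[i] <- "mitomap_confirmed"
      next
    }
    if (is.na(ann$genbank_count[i])) {
      path[i] <- "not_flagged"; rationale[i] <- "missing_annotation"; next
    }
    if (ann$genbank_count[i] > 0) {
      path[i] <- "not_flagged"; rationale[i] <- "seen_in_genbank"; next
    }
    cls <- ann$functional_class[i]
    if (identical(cls, "missense")) {
      cadd <- ann$cadd_phred[i]; mtb <- ann$mtoolbox_score[i]
      if (is.na(cadd) || is.na(mtb)) {
        path[i] <- "not_flagged"; rationale[i] <- "missing_annotation"
      } else if (cadd <= cadd_threshold) {
        path[i] <- "not_flagged"; rationale[i] <- "cadd_below_threshold"
      } else if (mtb <= mtoolbox_threshold) {
        path[i] <- "not_flagged"; rationale[i] <- "mtoolbox_below_threshold"
      } else {
        path[i] <- "predicted_deleterious"
        rationale[i] <- "rare_and_predicted_deleterious"
      }
    } else if (identical(cls, "tRNA")) {
      mtp <- ann$mitotip_raw[i]
      if (is.na(mtp)) {
        path[i] <- "not_flagged"; rationale[i] <- "missing_annotation"
      } else if (mtp <= mitotip_threshold) {
        path[i] <- "not_flagged"; rationale[i] <- "mitotip_below_threshold"
      } else {
        path[i] <- "predicted_deleterious"
        rationale[i] <- "rare_and_predicted_deleterious"
      }
    } else {
      path[i] <- "not_flagged"; rationale[i] <- "class_not_scored"
    }
  }
  ann$pathogenicity <- path
  ann$rationale <- rationale
  ann
}

#' Per-complex burden table of private variants across family lines
#'
#' Counts private missense (and predicted-pathogenic) variants per OXPHOS
#' complex and per cohort group, deduplicated by family line: a variant
#' shared along one maternal line (mother and her children carry the same
#' mtDNA) is counted once for that line; the same variant in another family
#' counts again. Paternal variants are one line per father. Groupings:
#' `maternal_lines` (mothers + their children, deduplicated per family),
#' `paternal_lines` (fathers), `probands`, `controls` (any individual whose
#' pedigree `role` is "control").
#'
#' @param triage data.frame of triaged variants: `sample_id`, `position`,
#'   `ref_allele`, `alt_allele`, `privacy`, plus annotation columns
#'   `functional_class`, `complex`, `pathogenicity`.
#' @param pedigree Pedigree data.frame (`individual_id`, `family_id`,
#'   `mother_id`, `role`).
#' @param grouping Which line grouping to tabulate; one or more of
#'   `"maternal_lines"`, `"paternal_lines"`, `"probands"`, `"controls"`.
#' @param subset `"missense"` (default) or `"predicted_pathogenic"`.
#' @return data.frame with columns `group`, `complex`
#'   (CI/CIII/CIV/CV/overall), `n_variants`, `n_lines`.
#' @export
complex_burden <- function(triage, pedigree,
                           grouping = c("maternal_lines", "paternal_lines",
                                        "probands", "controls"),
                           subset = c("missense", "predicted_pathogenic")) {
  subset <- match.arg(subset)
  grouping <- match.arg(grouping, several.ok = TRUE)
  stopifnot(all(c("sample_id", "position", "alt_allele", "privacy") %in%
                  names(triage)))
  priv <- triage[triage$privacy == "private", , drop = FALSE]
  priv <- if (subset == "missense")
    priv[priv$functional_class == "missense", , drop = FALSE]
  else
    priv[priv$pathogenicity %in% c("confirmed_pathogenic",
                                   "predicted_deleterious"), , drop = FALSE]

  ped <- pedigree
  line_of <- function(id) {
    row <- ped[ped$individual_id == id, , drop = FALSE]
    if (!nrow(row)) return(NA_character_)
    if (row$role %in% c("mother", "proband", "sibling") &&
        (row$role == "mother" || !is.na(row$mother_id)))
      paste0(row$family_id, ":maternal")
    else if (row$role == "father")
      paste0(row$family_id, ":paternal")
    else if (row$role == "control")
      paste0("control:", id)
    else NA_character_
  }
  members <- function(group) {
    switch(group,
      maternal_lines = ped$individual_id[ped$role %in%
                                           c("mother", "proband", "sibling")],
      paternal_lines = ped$individual_id[ped$role == "father"],
      probands = ped$individual_id[ped$role == "proband"],
      controls = ped$individual_id[ped$role == "control"])
  }
  complexes <- c("CI", "CIII", "CIV", "CV", "overall")
  out <- list()
  for (g in grouping) {
    ids <- members(g)
    sub <- priv[priv$sample_id %in% ids, , drop = FALSE]
    if (nrow(sub)) {
      skipped <- unique(sub$sample_id[is.na(vapply(sub$sample_id, line_of,
                                                   character(1)))])
      if (length(skipped))
        message("complex_burden: skipping sample(s) without line assignment: ",
                paste(skipped, collapse = ", "))
      sub$line <- if (g %in% c("probands", "controls"))
        sub$sample_id else vapply(sub$sample_id, line_of, character(1))
      sub <- sub[!is.na(sub$line), , drop = FALSE]
      # one observation per (line, variant)
      sub <- sub[!duplicated(paste(sub$line, sub$position, sub$alt_allele)), ,
                 drop = FALSE]
    }
    n_lines <- if (g %in% c("probands", "controls")) length(unique(ids))
      else length(unique(stats::na.omit(vapply(ids, line_of, character(1)))))
    for (cx in complexes) {
      nv <- if (!nrow(sub)) 0L
        else if (cx == "overall") nrow(sub) else sum(sub$complex == cx)
      out[[length(out) + 1L]] <- data.frame(
        group = g, complex = cx, n_variants = nv, n_lines = n_lines,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
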