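#' Classify an mtDNA haplogroup from marker-panel genotypes
#'
#' Assigns the deepest clade in the marker-panel forest whose marker path is
#' compatible with the typed alleles. A clade is *matched* when every one of
#' its own marker positions is typed with the marker allele; it is *blocked*
#' when any of its marker positions is typed with a different allele. A clade
#' is a candidate when it is matched, none of its ancestors is blocked, and
#' (for context-dependent markers such as 3010A) its parent clade is itself
#' matched, which resolves 3010A to J1 under a matched J and to H1 under a
#' matched H. Untyped ancestor markers do not block a path: array panels
#' rarely type every backbone position.
#'
#' Candidates are ranked by (1) number of matched markers along the path,
#' (2) number of matched clades along the path, (3) context-dependent
#' refinements preferred at ties, so that e.g. a genotype carrying 2706A,
#' 1438A and 3010A resolves to H1 rather than its sibling H2. Matched clades
#' on branches incompatible with the winner (neither ancestors nor
#' descendants) are reported as conflicts; a residual tie between
#' incompatible branches yields an undetermined call with all conflicting
#' branches listed.
#'
#' @param genotypes Named character vector: names are rCRS positions (as
#'   integers or strings), values are uppercase alleles in A/C/G/T.
#' @param panel Marker panel data.frame; see [default_marker_panel()].
#' @return An object of class `haplogroup_call`: list with `label` (NA when
#'   undetermined), `super_label`, `matched_markers` (character vector like
#'   "2706A"), `conflicts`, and logical `undetermined`.
#' @examples
#' g <- c(`11467` = "G", `16270` = "T", `3197` = "C",
#'        `14793` = "G", `16256` = "T")
#' classify_from_markers(g)$label  # "U5a"
#' @export
classify_from_markers <- function(genotypes, panel = default_marker_panel()) {
  validate_marker_panel(panel)
  if (length(genotypes)) {
    if (is.null(names(genotypes)) || any(!nzchar(names(genotypes))))
      stop("genotypes must be a named vector (names = rCRS positions)")
    alleles <- toupper(as.character(genotypes))
    if (any(!alleles %in% c("A", "C", "G", "T")))
      stop("genotype alleles must be one of A/C/G/T; got: ",
           paste(unique(alleles[!alleles %in% c("A", "C", "G", "T")]),
                 collapse = ", "))
    genotypes <- stats::setNames(alleles, names(genotypes))
  }
  typed_pos <- suppressWarnings(as.integer(names(genotypes)))
  if (length(genotypes) && any(is.na(typed_pos)))
    stop("genotype names must be integer rCRS positions")

  labels <- unique(panel$label)
  node_state <- function(lab) {
    rows <- panel[panel$label == lab, , drop = FALSE]
    idx <- match(rows$position, typed_pos)
    typed <- !is.na(idx)
    agree <- typed & genotypes[idx] == rows$marker_allele
    list(matched = all(typed) && all(agree),
         blocked = any(typed & !agree),
         n_markers = nrow(rows),
         markers = paste0(rows$position, rows$marker_allele))
  }
  states <- lapply(labels, node_state)
  names(states) <- labels
  ctx <- stats::setNames(vapply(labels, function(l)
    any(panel$context_dependent[panel$label == l]), logical(1)), labels)

  paths <- lapply(labels, panel_path, panel = panel)
  names(paths) <- labels

  candidate <- function(lab) {
    st <- states[[lab]]
    if (!st$matched) return(NULL)
    path <- paths[[lab]]
    anc <- path[-1]
    if (length(anc) && any(vapply(anc, function(a) states[[a]]$blocked,
                                  logical(1))))
      return(NULL)
    if (ctx[[lab]]) {
      parent <- path[2]
      if (is.na(parent) || !states[[parent]]$matched) return(NULL)
    }
    matched_nodes <- path[vapply(path, function(a) states[[a]]$matched,
                                 logical(1))]
    list(label = lab,
         n_marker = sum(vapply(matched_nodes, function(a)
           states[[a]]$n_markers, integer(1))),
         n_node = length(matched_nodes),
         context = ctx[[lab]],
         markers = unlist(lapply(matched_nodes, function(a)
           states[[a]]$markers), use.names = FALSE))
  }
  cands <- Filter(Negate(is.null), lapply(labels, candidate))

  undetermined_call <- function(conflicts = character(0)) {
    structure(list(label = NA_character_, super_label = NA_character_,
                   matched_markers = character(0), conflicts = conflicts,
                   undetermined = TRUE), class = "haplogroup_call")
  }
  if (!length(cands)) return(undetermined_call())

  score <- vapply(cands, function(cd)
    cd$n_marker * 1e6 + cd$n_node * 1e3 + as.integer(cd$context), numeric(1))
  ord <- order(-score, vapply(cands, `[[`, character(1), "label"))
  cands <- cands[ord]
  best <- cands[[1]]

  incompatible <- function(a, b) {
    !(a %in% paths[[b]]) && !(b %in% paths[[a]])
  }
  top_score <- score[ord][1]
  ties <- cands[score[ord] == top_score]
  tie_labels <- vapply(ties, `[[`, character(1), "label")
  if (length(ties) > 1 &&
      any(vapply(tie_labels[-1], incompatible, logical(1), b = best$label)))
    return(undetermined_call(conflicts = tie_labels))

  # context-dependent nodes only count as evidence under a matched parent
  evidential <- vapply(labels, function(l) {
    if (!states[[l]]$matched) return(FALSE)
    if (!ctx[[l]]) return(TRUE)
    parent <- paths[[l]][2]
    !is.na(parent) && states[[parent]]$matched
  }, logical(1))
  other_matched <- setdiff(labels[evidential], paths[[best$label]])
  conflicts <- other_matched[vapply(other_matched, incompatible, logical(1),
                                    b = best$label)]

  structure(list(label = best$label,
                 super_label = super_haplogroup(best$label),
                 matched_markers = best$markers,
                 conflicts = unname(conflicts),
                 undetermined = FALSE),
            class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  if (x$undetermined) {
    cat("Haplogroup call: undetermined")
    if (length(x$conflicts))
      cat(" (conflicting branches: ", paste(x$conflicts, collapse = ", "), ")",
          sep = "")
    cat("\n")
  } else {
    cat("Haplogroup call:", x$label, "(super-haplogroup", x$super_label, ")\n")
    cat("  markers:", paste(x$matched_markers, collapse = " "), "\n")
    if (length(x$conflicts))
      cat("  conflicts:", paste(x$conflicts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Classify every sample in a long-format genotype table
#'
#' @param genotype_table data.frame with columns `sample_id`, `position`,
#'   `allele` (one row per typed panel position).
#' @param panel Marker panel; see [default_marker_panel()].
#' @return data.frame with one row per sample: `sample_id`, `label`,
#'   `super_label`, `conflicts` (comma-separated), `undetermined`.
#' @export
classify_cohort <- function(genotype_table, panel = default_marker_panel()) {
  stopifnot(all(c("sample_id", "position", "allele") %in%
                  names(genotype_table)))
  ids <- unique(genotype_table$sample_id)
  calls <- lapply(ids, function(id) {
    g <- genotype_table[genotype_table$sample_id == id, ]
    classify_from_markers(stats::setNames(g$allele, g$position), panel)
  })
  data.frame(
    sample_id = ids,
    label = vapply(calls, function(cl) cl$label, character(1)),
    super_label = vapply(calls, function(cl) cl$super_label, character(1)),
    conflicts = vapply(calls, function(cl)
      paste(cl$conflicts, collapse = ","), character(1)),
    undetermined = vapply(calls, function(cl) cl$undetermined, logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Marker genotype backbone for a haplogroup
#'
#' Full typing of every panel position for a sample of the given haplogroup:
#' positions on the label's marker path carry the marker allele, all other
#' panel positions carry the ancestral allele. Used by the synthetic cohort
#' generator and by classifier round-trip tests.
#'
#' @param label Haplogroup label present in the panel.
#' @param panel Marker panel.
#' @return Named character vector (names = positions).
#' @export
haplogroup_backbone <- function(label, panel = default_marker_panel()) {
  if (!label %in% panel$label)
    stop("unknown haplogroup label: ", label)
  path <- panel_path(label, panel)
  on_path <- panel$label %in% path
  g <- ifelse(on_path, panel$marker_allele, panel$ancestral_allele)
  # a position can appear under several labels (3010A): marker allele wins
  # when any of its rows is on the path
  out <- stats::setNames(g, panel$position)
  for (pos in unique(panel$position[duplicated(panel$position)])) {
    rows <- panel$position == pos
    out[as.character(pos)] <-
      if (any(rows & on_path)) panel$marker_allele[rows][1] else
        panel$ancestral_allele[rows][1]
  }
  out[!duplicated(names(out))]
}
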