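# Label-set algebra, enrichment ratios, ROC scans, filter overlap and GO
# fold enrichment.

#' Subset counts from a protein label table
#'
#' Computes the enzyme/transporter (ET) union by inclusion-exclusion and
#' the complementary NET set.
#'
#' @param labels Tibble with `protein_id` and 0/1 (or logical) columns
#'   `enzyme`, `transporter`, and optionally `ph_dependent`.
#' @return One-row tibble: `n_total`, `n_enzyme`, `n_transporter`, `n_both`,
#'   `n_et`, `n_net`, `n_ph`.
#' @export
subset_algebra <- function(labels) {
  if (anyDuplicated(labels$protein_id) > 0) {
    stop("duplicate protein_id in label table")
  }
  e <- as.logical(labels$enzyme)
  t <- as.logical(labels$transporter)
  ph <- if ("ph_dependent" %in% names(labels)) {
    as.logical(labels$ph_dependent)
  } else rep(FALSE, nrow(labels))
  tibble::tibble(
    n_total = nrow(labels),
    n_enzyme = sum(e), n_transporter = sum(t), n_both = sum(e & t),
    n_et = sum(e) + sum(t) - sum(e & t),
    n_net = nrow(labels) - (sum(e) + sum(t) - sum(e & t)),
    n_ph = sum(ph)
  )
}

#' Enrichment ratio of pass rates between a subset and a reference
#'
#' `ratio = (npass_subset / subset_size) / (npass_reference /
#' reference_size)`. The reference may be the whole collection (as for the
#' pH-labelled subset) or a complement set (ET vs NET); both variants are
#' supported through the explicit reference arguments. A zero reference
#' pass count gives a censored (NA) ratio.
#'
#' @param npass_subset,subset_size Pass count and size of the subset.
#' @param npass_reference,reference_size Pass count and size of the
#'   reference.
#' @return One-row tibble with the four counts, `ratio`, and `censored`.
#' @export
enrichment_ratio <- function(npass_subset, subset_size,
                             npass_reference, reference_size) {
  if (subset_size <= 0 || reference_size <= 0) {
    stop("subset and reference sizes must be positive")
  }
  censored <- npass_reference == 0
  tibble::tibble(
    npass_subset = npass_subset, subset_size = subset_size,
    npass_reference = npass_reference, reference_size = reference_size,
    ratio = if (censored) NA_real_ else
      (npass_subset / subset_size) / (npass_reference / reference_size),
    censored = censored
  )
}

#' ROC scan of pass flags against ET/NET labels
#'
#' For each parameter cell (any grouping columns besides `protein_id` and
#' `pass`), computes the true and false positive rates for predicting the
#' ET subset: TPR = passes among ET / n(ET); FPR = passes among NET /
#' n(NET).
#'
#' @param passes Tibble with `protein_id`, `pass`, and any number of
#'   threshold columns defining the grid cells (e.g. `sasa_max`, `dq_min`).
#' @param labels Label tibble (see [subset_algebra()]).
#' @return Tibble of grid cells with `tpr` and `fpr`.
#' @export
roc_scan <- function(passes, labels) {
  et_ids <- labels$protein_id[as.logical(labels$enzyme) |
                                as.logical(labels$transporter)]
  net_ids <- setdiff(labels$protein_id, et_ids)
  if (length(et_ids) == 0 || length(net_ids) == 0) {
    stop("both ET and NET subsets must be non-empty")
  }
  cell_cols <- setdiff(names(passes), c("protein_id", "pass"))
  passes |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell_cols))) |>
    dplyr::summarise(
      tpr = sum(.data$pass & .data$protein_id %in% et_ids) / length(et_ids),
      fpr = sum(.data$pass & .data$protein_id %in% net_ids) /
        length(net_ids),
      .groups = "drop"
    )
}

#' Observed/expected overlap between filter pass sets
#'
#' For each filter pair, the observed number of proteins passing both is
#' compared with the count expected at random, `|pass_i| * |pass_j| / N`.
#' Filters with zero passes give censored (NA) ratios.
#'
#' @param results Long filter results: `protein_id`, `filter`, `pass`.
#' @param n_total Total number of proteins in the collection (defaults to
#'   the number of distinct `protein_id`s).
#' @return Tibble: `filter_i`, `filter_j`, `observed`, `expected`, `ratio`.
#' @export
filter_overlap_matrix <- function(results, n_total = NULL) {
  if (is.null(n_total)) n_total <- dplyr::n_distinct(results$protein_id)
  fl <- unique(results$filter)
  if (length(fl) < 2) stop("need at least two filters")
  pass_sets <- purrr::map(
    stats::setNames(fl, fl),
    function(f) results$protein_id[results$filter == f & results$pass]
  )
  combos <- utils::combn(fl, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    fi <- combos[1, k]; fj <- combos[2, k]
    ni <- length(pass_sets[[fi]]); nj <- length(pass_sets[[fj]])
    obs <- length(intersect(pass_sets[[fi]], pass_sets[[fj]]))
    expd <- ni * nj / n_total
    tibble::tibble(
      filter_i = fi, filter_j = fj, observed = obs, expected = expd,
      ratio = if (ni == 0 || nj == 0) NA_real_ else obs / expd
    )
  })
}

#' Percent pass/fail per subset per filter (heat-map table)
#'
#' @param results Long filter results: `protein_id`, `filter`, `pass`.
#' @param labels Label tibble (see [subset_algebra()]).
#' @return Tibble: `filter`, `subset` (enzyme/transporter/ph/net),
#'   `pct_pass`, `pct_fail`.
#' @export
subset_pass_table <- function(results, labels) {
  e <- as.logical(labels$enzyme); t <- as.logical(labels$transporter)
  ph <- if ("ph_dependent" %in% names(labels)) {
    as.logical(labels$ph_dependent)
  } else rep(FALSE, nrow(labels))
  subsets <- list(
    enzyme = labels$protein_id[e],
    transporter = labels$protein_id[t],
    ph = labels$protein_id[ph],
    net = labels$protein_id[!(e | t)]
  )
  purrr::imap_dfr(subsets, function(ids, nm) {
    if (length(ids) == 0) return(NULL)
    results |>
      dplyr::filter(.data$protein_id %in% ids) |>
      dplyr::group_by(filter = .data$filter) |>
      dplyr::summarise(
        subset = nm,
        pct_pass = 100 * mean(.data$pass),
        pct_fail = 100 * mean(!.data$pass),
        .groups = "drop"
      )
  })
}

# --- GO fold enrichment ----------------------------------------------------

#' Propagate GO annotations to ancestor terms
#'
#' True-path rule: a protein annotated to a term counts for every ancestor
#' in the hierarchy. Relationship types are not distinguished.
#'
#' @param annotations Tibble: `protein_id`, `term_id`.
#' @param hierarchy Tibble: `term_id`, `parent_id` (acyclic; a cyclic
#'   hierarchy is an error).
#' @return Annotation tibble closed under ancestry.
#' @export
propagate_annotations <- function(annotations, hierarchy) {
  if (nrow(hierarchy) > 0) {
    g <- igraph::graph_from_data_frame(
      hierarchy[, c("term_id", "parent_id")], directed = TRUE
    )
    if (!igraph::is_dag(g)) stop("GO hierarchy contains a cycle")
  }
  ann <- dplyr::distinct(annotations[, c("protein_id", "term_id")])
  repeat {
    up <- ann |>
      dplyr::inner_join(hierarchy, by = "term_id",
                        relationship = "many-to-many") |>
      dplyr::transmute(protein_id = .data$protein_id,
                       term_id = .data$parent_id) |>
      dplyr::distinct()
    new <- dplyr::anti_join(up, ann, by = c("protein_id", "term_id"))
    if (nrow(new) == 0) break
    ann <- dplyr::bind_rows(ann, new)
  }
  ann
}

#' GO fold enrichment of a query set against a reference set
#'
#' After true-path propagation, each term's fold enrichment is
#' `(query hits / |query|) / (reference hits / |reference|)`. When a basis
#' term list is supplied the output covers exactly those terms, with terms
#' absent from the propagated annotations censored (NA fold), enabling
#' cross-filter heat maps on a shared basis hierarchy.
#'
#' @param query Character vector of query protein ids (a subset of
#'   `reference`).
#' @param reference Character vector of reference protein ids.
#' @param annotations,hierarchy GO tables (see [propagate_annotations()]).
#' @param basis Optional character vector of terms to report.
#' @return Tibble: `term_id`, `n_query`, `n_reference`, `fold`, `censored`.
#' @export
go_fold_enrichment <- function(query, reference, annotations, hierarchy,
                               basis = NULL) {
  if (!all(query %in% reference)) {
    stop("query proteins must be a subset of the reference set")
  }
  ann <- propagate_annotations(annotations, hierarchy) |>
    dplyr::filter(.data$protein_id %in% reference)
  counts <- ann |>
    dplyr::group_by(term_id = .data$term_id) |>
    dplyr::summarise(
      n_query = sum(.data$protein_id %in% query),
      n_reference = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      fold = (.data$n_query / length(query)) /
        (.data$n_reference / length(reference)),
      censored = FALSE
    )
  if (!is.null(basis)) {
    counts <- tibble::tibble(term_id = basis) |>
      dplyr::left_join(counts, by = "term_id") |>
      dplyr::mutate(
        n_query = dplyr::coalesce(.data$n_query, 0L),
        n_reference = dplyr::coalesce(.data$n_reference, 0L),
        censored = is.na(.data$fold)
      )
  }
  counts
}

#' Basis term list: terms annotated to any protein of a combined query
#'
#' Builds the shared basis hierarchy used to align per-filter GO results:
#' all terms reached (after propagation) by proteins in `combined_query`.
#'
#' @param combined_query Character vector of protein ids (e.g. the union of
#'   BCOI proteins over all filters).
#' @param annotations,hierarchy GO tables.
#' @return Character vector of term ids.
#' @export
go_basis_terms <- function(combined_query, annotations, hierarchy) {
  ann <- propagate_annotations(annotations, hierarchy)
  sort(unique(ann$term_id[ann$protein_id %in% combined_query]))
}
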