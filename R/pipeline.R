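# Orchestration: scan a set of protomer models through the filter suite
# and the downstream statistics, writing tabular reports.

#' Run the full scan over a set of protomer models
#'
#' For each structure: engine analysis ([analyze_protomer()]) and the
#' canonical filter suite ([run_filter_suite()]). When a label table is
#' supplied, enrichment ratios, the subset heat-map table and the filter
#' overlap matrix are added; with GO tables, per-filter fold enrichment
#' against the supplied reference is added. Unreadable structures are
#' logged and skipped; the scan fails only if nothing can be processed.
#' Results are deterministic for a fixed seed and configuration.
#'
#' @param structures Character vector of structure file paths, or a list
#'   of `protomer` objects.
#' @param labels Optional label tibble (`protein_id`, `enzyme`,
#'   `transporter`, `ph_dependent`).
#' @param go Optional list with `annotations` and `hierarchy` tibbles.
#' @param params A [bc_params()] object.
#' @param out_dir Optional output directory for TSV reports and a config
#'   manifest.
#' @param seed Integer seed for the Monte Carlo engine (one sub-seed per
#'   protein is derived from it).
#' @param quiet Suppress progress messages.
#' @return List: `results` (long filter results), `sites` (per-protein
#'   site tables), `skipped`, and when inputs allow `enrichment`,
#'   `subset_table`, `overlap`, `go_folds`.
#' @export
run_proteome_scan <- function(structures, labels = NULL, go = NULL,
                              params = bc_params(), out_dir = NULL,
                              seed = 1, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  models <- structures
  n <- length(models)
  results <- list()
  site_tables <- list()
  skipped <- character()
  for (i in seq_len(n)) {
    m <- models[[i]]
    label <- if (is.character(m)) m else m$protein_id
    ok <- tryCatch({
      if (is.character(m)) m <- read_protomer(m, radii = params$radii)
      an <- analyze_protomer(m, params = params,
                             seed = (seed + i) %% .Machine$integer.max)
      results[[m$protein_id]] <- run_filter_suite(an)
      site_tables[[m$protein_id]] <- an$sites |>
        dplyr::select(-dplyr::any_of("moiety_idx")) |>
        dplyr::mutate(protein_id = m$protein_id, .before = 1)
      TRUE
    }, error = function(e) {
      say("skipping %s: %s", label, conditionMessage(e))
      FALSE
    })
    if (!ok) skipped <- c(skipped, label)
    if (!quiet && (i %% 10 == 0 || i == n)) {
      say("processed %d/%d structures", i, n)
    }
  }
  if (length(results) == 0) {
    stop("no structures could be processed (", length(skipped), " skipped)")
  }
  results <- dplyr::bind_rows(results)
  out <- list(
    results = results,
    sites = dplyr::bind_rows(site_tables),
    skipped = skipped
  )
  if (!is.null(labels)) {
    counts <- subset_algebra(labels)
    et_ids <- labels$protein_id[as.logical(labels$enzyme) |
                                  as.logical(labels$transporter)]
    enr <- results |>
      dplyr::group_by(filter = .data$filter) |>
      dplyr::summarise(
        enrichment_ratio(
          npass_subset = sum(.data$pass &
                               .data$protein_id %in% et_ids),
          subset_size = max(1L, counts$n_et),
          npass_reference = sum(.data$pass &
                                  !.data$protein_id %in% et_ids),
          reference_size = max(1L, counts$n_net)
        ),
        .groups = "drop"
      )
    out$enrichment <- enr
    out$subset_table <- subset_pass_table(results, labels)
    if (dplyr::n_distinct(results$filter) >= 2) {
      out$overlap <- filter_overlap_matrix(
        results, n_total = dplyr::n_distinct(results$protein_id)
      )
    }
  }
  if (!is.null(go)) {
    reference <- unique(results$protein_id)
    out$go_folds <- results |>
      dplyr::filter(.data$pass) |>
      dplyr::group_by(filter = .data$filter) |>
      dplyr::group_modify(function(df, key) {
        go_fold_enrichment(unique(df$protein_id), reference,
                           go$annotations, go$hierarchy)
      }) |>
      dplyr::ungroup()
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_filter_table(results, file.path(out_dir, "filter_results.tsv"))
    readr::write_tsv(out$sites, file.path(out_dir, "sites.tsv"))
    for (nm in c("enrichment", "subset_table", "overlap", "go_folds")) {
      if (!is.null(out[[nm]])) {
        readr::write_tsv(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
      }
    }
    manifest <- list(
      package = "buriedcharge",
      version = as.character(utils::packageVersion("buriedcharge")),
      seed = seed,
      n_structures = n,
      n_processed = dplyr::n_distinct(results$protein_id),
      n_skipped = length(skipped),
      params = params[setdiff(names(params),
                              c("model_pkas", "radii", "ph_grid"))]
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
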