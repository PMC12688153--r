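# Benchmark scoring against literature pH-sensor residues.

#' The packaged benchmark fixture
#'
#' Encodes the 23-protein pH-dependence benchmark as stated in the source
#' text: the protein list with review provenance and per-protein filter
#' pass counts (`n_pass`, 0-10, NA where not reported), and the sensor
#' residue table (26 residues across 15 entries) with the reported
#' predicted/not-predicted mark, moiety SASA and AM-avg conservation score.
#'
#' @return List of two tibbles: `proteins` and `sensors`.
#' @export
benchmark_fixture <- function() {
  dir <- system.file("extdata", package = "buriedcharge")
  proteins <- readr::read_tsv(
    file.path(dir, "benchmark_proteins.tsv"),
    col_types = readr::cols(
      protein = readr::col_character(),
      from_review = readr::col_integer(),
      n_pass = readr::col_integer()
    ),
    na = "NA", progress = FALSE
  )
  sensors <- readr::read_tsv(
    file.path(dir, "benchmark_sensor_residues.tsv"),
    col_types = readr::cols(
      protein = readr::col_character(),
      residue = readr::col_character(),
      predicted = readr::col_integer(),
      sasa = readr::col_double(),
      am_avg = readr::col_double()
    ),
    progress = FALSE
  )
  list(proteins = proteins, sensors = sensors)
}

# "D205" -> list(aa = "D", resnum = 205)
parse_residue_label <- function(label) {
  list(aa = substr(label, 1, 1),
       resnum = as.integer(substring(label, 2)))
}

#' Score filter predictions against the benchmark
#'
#' In fixture mode (no `predictions`), a sensor residue counts as recovered
#' when the fixture marks it predicted. When per-protein filter results are
#' supplied, a residue is recovered when it appears in any filter's BCOI
#' list for its protein, and per-filter protein recovery fractions are also
#' computed.
#'
#' @param entries Sensor table as in [benchmark_fixture()]`$sensors`.
#' @param predictions Optional row-bound [run_filter_suite()] results
#'   covering the benchmark proteins.
#' @return A `benchmark_report` list: `residues` (per-residue tibble with
#'   `recovered`), `n_recovered`, `n_total`, and (with predictions)
#'   `per_filter` fractions and their `mean_fraction`.
#' @export
score_benchmark <- function(entries, predictions = NULL) {
  if (nrow(entries) == 0) {
    return(structure(
      list(residues = entries, n_recovered = 0L, n_total = 0L,
           per_filter = NULL, mean_fraction = NA_real_, empty = TRUE),
      class = "benchmark_report"
    ))
  }
  per_filter <- NULL
  mean_fraction <- NA_real_
  if (is.null(predictions)) {
    entries$recovered <- entries$predicted == 1L
  } else {
    aa1 <- stats::setNames(names(AA3TO1), AA3TO1)  # one -> three letter
    entries$recovered <- purrr::map2_lgl(
      entries$protein, entries$residue,
      function(prot, lab) {
        parts <- strsplit(prot, "/", fixed = TRUE)[[1]]
        pred <- predictions[predictions$protein_id %in% parts &
                              predictions$pass, , drop = FALSE]
        if (nrow(pred) == 0) return(FALSE)
        r <- parse_residue_label(lab)
        any(purrr::map_lgl(pred$bcoi, function(b) {
          any(b$resnum == r$resnum & b$group == aa1[[r$aa]])
        }))
      }
    )
    bench_prots <- unique(unlist(strsplit(entries$protein, "/",
                                          fixed = TRUE)))
    missing <- setdiff(bench_prots, unique(predictions$protein_id))
    if (length(missing) > 0) {
      stop("no prediction source for benchmark protein(s): ",
           paste(missing, collapse = ", "))
    }
    per_filter <- predictions |>
      dplyr::filter(.data$protein_id %in% bench_prots) |>
      dplyr::group_by(filter = .data$filter) |>
      dplyr::summarise(fraction = mean(.data$pass), .groups = "drop")
    mean_fraction <- mean(per_filter$fraction)
  }
  structure(
    list(
      residues = entries,
      n_recovered = sum(entries$recovered),
      n_total = nrow(entries),
      per_filter = per_filter,
      mean_fraction = mean_fraction,
      empty = FALSE
    ),
    class = "benchmark_report"
  )
}

#' @export
print.benchmark_report <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<benchmark_report> empty entry list\n")
    return(invisible(x))
  }
  cat(sprintf("<benchmark_report> %d of %d sensor residues recovered\n",
              x$n_recovered, x$n_total))
  if (!is.null(x$per_filter)) {
    cat(sprintf("  mean protein recovery over %d filters: %.1f%%\n",
                nrow(x$per_filter), 100 * x$mean_fraction))
  }
  invisible(x)
}

#' Tidy a benchmark report
#'
#' @param x A `benchmark_report`.
#' @param ... Unused.
#' @return The per-residue tibble with `recovered`.
#' @export
tidy.benchmark_report <- function(x, ...) tibble::as_tibble(x$residues)

#' @export
glance.benchmark_report <- function(x, ...) {
  tibble::tibble(
    n_recovered = x$n_recovered, n_total = x$n_total,
    mean_fraction = x$mean_fraction
  )
}

#' Average a 19-substitution score vector
#'
#' Pathogenicity-style scores for mutating one residue to each of the 19
#' other amino acids are summarised by their arithmetic mean (the AM-avg
#' aggregation).
#'
#' @param scores Numeric vector of exactly 19 values in `[0, 1]`.
#' @return The mean.
#' @export
aggregate_substitution_scores <- function(scores) {
  if (length(scores) != 19 || any(!is.finite(scores))) {
    stop("expected exactly 19 finite substitution scores")
  }
  if (any(scores < 0 | scores > 1)) {
    stop("substitution scores must lie in [0, 1]")
  }
  mean(scores)
}

#' Lowest score threshold returning a given count
#'
#' The smallest threshold t such that exactly `count` values satisfy
#' `value >= t`; NA when ties make that count unattainable.
#'
#' @param values Numeric scores.
#' @param count Target count.
#' @return The threshold, or NA.
#' @export
score_threshold_for_count <- function(values, count) {
  stopifnot(count >= 1, count <= length(values))
  thr <- sort(values, decreasing = TRUE)[count]
  if (sum(values >= thr) != count) NA_real_ else thr
}
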