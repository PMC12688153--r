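# The ten canonical burial-conditioned BCOI filters and the per-protein
# filter suite.

#' The canonical filter set
#'
#' The ten named filters, in canonical order. `pkcalc-*` filters are driven
#' by the titration (enumeration / Monte Carlo) engine, `propka-range-*` by
#' the fast empirical range engine; intersections require a protein to pass
#' both components at the matched SASA threshold; `pkcalc-deltaQ-10` uses
#' the protonation difference to the free model compound.
#'
#' @return Tibble: `name`, `method`, `sasa_max` (NA for the rotamer-based
#'   nodh burial), `min_dekrh`, `range_sasa`, `network_sasa`,
#'   `network_min_dekrh`.
#' @export
canonical_filters <- function() {
  tibble::tribble(
    ~name,                    ~method,        ~sasa_max, ~min_dekrh,
    "pkcalc-int-nodh-3",      "network",      NA,        3L,
    "pkcalc-int-5-2",         "network",      5,         2L,
    "pkcalc-int-15-2",        "network",      15,        2L,
    "pkcalc-int-15-3",        "network",      15,        3L,
    "propka-range-15",        "range",        15,        NA_integer_,
    "propka-range-5",         "range",        5,         NA_integer_,
    "pkcalc-15-3-propka-15",  "intersection", 15,        3L,
    "pkcalc-15-2-propka-15",  "intersection", 15,        2L,
    "pkcalc-5-2-propka-5",    "intersection", 5,         2L,
    "pkcalc-deltaQ-10",       "deltaq",       10,        NA_integer_
  )
}

bcoi_tbl <- function(sites, which) {
  sites[which, c("chain", "resnum", "group"), drop = FALSE] |>
    tibble::as_tibble() |>
    dplyr::distinct() |>
    dplyr::arrange(.data$chain, .data$resnum)
}

#' pKa-range filter
#'
#' D/E/K/R/H sites with predicted pKa in `[pka_lo, pka_hi]` and moiety SASA
#' at or below `sasa_max`. Censored pKas (curves never crossing
#' half-ionisation) are excluded: they cannot verifiably lie in the range.
#'
#' @param sites Site tibble carrying `moiety_sasa` and the pKa column.
#' @param pka_col Name of the pKa column to threshold (e.g. `"pka_emp"` for
#'   the empirical range engine, `"apparent_pka"` for the titration engine).
#' @param sasa_max Moiety SASA threshold, A^2.
#' @param pka_lo,pka_hi pKa window (default 5.5-8.5, around neutral pH).
#' @return Tibble of qualifying residues: `chain`, `resnum`, `group`.
#' @export
pka_range_filter <- function(sites, pka_col = "pka_emp", sasa_max = 15,
                             pka_lo = 5.5, pka_hi = 8.5) {
  pka <- sites[[pka_col]]
  cens <- if ("censored" %in% names(sites) && pka_col == "apparent_pka") {
    sites$censored
  } else rep(FALSE, nrow(sites))
  hit <- sites$group %in% DEKRH & !cens & !is.na(pka) &
    pka >= pka_lo & pka <= pka_hi & sites$moiety_sasa <= sasa_max
  bcoi_tbl(sites, hit)
}

#' Charge-network filter
#'
#' Union of D/E/K/R/H members over qualifying networks.
#'
#' @param networks Output of [charge_networks()].
#' @param sites Site tibble.
#' @return Tibble of qualifying residues: `chain`, `resnum`, `group`.
#' @export
network_filter <- function(networks, sites) {
  ids <- unique(unlist(networks$dekrh_members))
  bcoi_tbl(sites, sites$site_id %in% ids)
}

#' Intersection filter
#'
#' A protein passes when it passes both the pKa-range and the network
#' component at the matched SASA threshold; the reported residues are the
#' union of the two component lists (protein-level intersection,
#' residue-level union).
#'
#' @param range_result,network_result Residue tibbles from the components.
#' @param range_sasa,network_sasa SASA thresholds the components were run
#'   at; a mismatch is an error.
#' @return List with `pass` (logical) and `bcoi` (residue tibble; empty
#'   when the protein fails).
#' @export
intersection_filter <- function(range_result, network_result,
                                range_sasa, network_sasa) {
  if (!isTRUE(all.equal(range_sasa, network_sasa))) {
    stop(sprintf(
      "intersection components use mismatched SASA thresholds (%g vs %g)",
      range_sasa, network_sasa
    ))
  }
  pass <- nrow(range_result) > 0 && nrow(network_result) > 0
  bcoi <- if (pass) {
    dplyr::distinct(dplyr::bind_rows(range_result, network_result)) |>
      dplyr::arrange(.data$chain, .data$resnum)
  } else {
    range_result[0, ]
  }
  list(pass = pass, bcoi = bcoi)
}

#' Protonation-difference (delta Q) filter
#'
#' D/E/K/R/H sites with moiety SASA at or below `sasa_max` and a predicted
#' protonation difference to the free model compound of at least `dq_min`
#' at the evaluation pH. Histidine additionally requires a predicted pKa of
#' at least `his_pka_min`, which avoids passing buried imidazoles lacking
#' compensating protein solvation.
#'
#' @param sites Site tibble carrying `moiety_sasa`, `delta_q` and
#'   `apparent_pka`.
#' @param sasa_max Moiety SASA threshold, A^2 (default 10).
#' @param dq_min Minimum protonation difference (default 0.2).
#' @param his_pka_min Histidine pKa floor (default 5.5).
#' @return Tibble of qualifying residues: `chain`, `resnum`, `group`.
#' @export
deltaq_filter <- function(sites, sasa_max = 10, dq_min = 0.2,
                          his_pka_min = 5.5) {
  hit <- sites$group %in% DEKRH & sites$moiety_sasa <= sasa_max &
    !is.na(sites$delta_q) & sites$delta_q >= dq_min
  his_fail <- sites$group == "HIS" &
    (is.na(sites$apparent_pka) | sites$apparent_pka < his_pka_min)
  bcoi_tbl(sites, hit & !his_fail)
}

#' Full per-protein engine analysis
#'
#' Runs the whole per-protein stack: optional confidence filtering, site
#' extraction, SASA, desolvation, rotamer DH-access, pairwise couplings,
#' empirical pKas, coupled titration (exact enumeration up to
#' `params$enumerate_max` sites, Monte Carlo beyond), apparent pKas and
#' delta Q, and the strong-coupling graph.
#'
#' @param model A `protomer`.
#' @param params A [bc_params()] object.
#' @param seed RNG seed for the Monte Carlo engine.
#' @return A `bc_analysis` list: `model`, `sites` (with all per-site
#'   quantities), `W`, `graph`, `curves`.
#' @export
analyze_protomer <- function(model, params = bc_params(), seed = 1) {
  if (!is.null(params$plddt_min) && "plddt" %in% names(model$atoms) &&
      any(!is.na(model$atoms$plddt)) &&
      any(model$atoms$plddt < params$plddt_min, na.rm = TRUE)) {
    model <- filter_by_plddt(model, params$plddt_min)
  }
  sites <- extract_ionizable_sites(
    model, include_termini = params$include_termini,
    include_cys_tyr = params$include_cys_tyr,
    model_pkas = params$model_pkas
  )
  if (nrow(sites) == 0) {
    return(structure(list(model = model, sites = sites, W = NULL,
                          graph = NULL, curves = NULL),
                     class = "bc_analysis"))
  }
  sites <- add_moiety_sasa(sites, model, params$probe_radius,
                           params$n_sphere_points)
  sites <- desolvation_shift(sites, params)
  sites <- dh_access(sites, model, params)
  W <- pairwise_interactions(sites, model, params)
  sites <- empirical_pka(sites, W, params)
  system <- titration_system(sites, W, params$temperature)
  curves <- if (nrow(sites) <= params$enumerate_max) {
    enumerate_titration(system, params$ph_grid)
  } else {
    mc_titration(system, params$ph_grid, n_sweeps = params$mc_sweeps,
                 n_burnin = round(params$mc_burnin_frac * params$mc_sweeps),
                 seed = seed,
                 coupling_threshold = params$coupling_threshold)
  }
  summ <- tidy.titration_curves(curves, ph = params$dq_ph)
  sites <- dplyr::left_join(sites, summ, by = "site_id")
  graph <- coupling_graph(W, params$coupling_threshold)
  structure(
    list(model = model, sites = sites, W = W, graph = graph,
         curves = curves),
    class = "bc_analysis"
  )
}

#' @export
print.bc_analysis <- function(x, ...) {
  cat(sprintf("<bc_analysis> %s: %d ionisable sites, %d strong couplings\n",
              x$model$protein_id, nrow(x$sites),
              if (is.null(x$graph)) 0L else nrow(x$graph$edges)))
  invisible(x)
}

#' Evaluate the canonical filter suite for one protein
#'
#' Applies the ten canonical filters to a per-protein analysis. A protein
#' passes a filter when at least one qualifying residue is found.
#'
#' @param analysis A `bc_analysis` from [analyze_protomer()].
#' @param filters Filter table (default [canonical_filters()]).
#' @return A `filter_result` tibble: `protein_id`, `filter`, `pass`,
#'   `bcoi` (list column of residue tibbles), in canonical filter order.
#' @export
run_filter_suite <- function(analysis, filters = canonical_filters()) {
  sites <- analysis$sites
  pid <- analysis$model$protein_id
  empty <- tibble::tibble(chain = character(), resnum = integer(),
                          group = character())
  need_cols <- function(fname, cols) {
    miss <- setdiff(cols, names(sites))
    if (length(miss) > 0) {
      stop(sprintf("filter %s: missing engine output column(s) %s",
                   fname, paste(miss, collapse = ", ")))
    }
  }
  eval_one <- function(fname, method, sasa_max, min_dekrh) {
    if (nrow(sites) == 0) return(list(pass = FALSE, bcoi = empty))
    need_cols(fname, switch(method,
      range = c("pka_emp", "moiety_sasa"),
      network = if (is.na(sasa_max)) "dh_access" else "moiety_sasa",
      intersection = c("pka_emp", "moiety_sasa"),
      deltaq = c("delta_q", "apparent_pka", "moiety_sasa")
    ))
    if (method == "range") {
      b <- pka_range_filter(sites, "pka_emp", sasa_max)
      list(pass = nrow(b) > 0, bcoi = b)
    } else if (method == "network") {
      burial <- if (is.na(sasa_max)) list(mode = "nodh") else
        list(sasa_max = sasa_max)
      nets <- charge_networks(analysis$graph, sites, burial, min_dekrh)
      b <- network_filter(nets, sites)
      list(pass = nrow(b) > 0, bcoi = b)
    } else if (method == "intersection") {
      rng <- pka_range_filter(sites, "pka_emp", sasa_max)
      nets <- charge_networks(analysis$graph, sites,
                              list(sasa_max = sasa_max), min_dekrh)
      intersection_filter(rng, network_filter(nets, sites),
                          sasa_max, sasa_max)
    } else if (method == "deltaq") {
      b <- deltaq_filter(sites, sasa_max = sasa_max)
      list(pass = nrow(b) > 0, bcoi = b)
    } else {
      stop("unknown filter method: ", method)
    }
  }
  res <- purrr::pmap(
    list(filters$name, filters$method, filters$sasa_max, filters$min_dekrh),
    eval_one
  )
  out <- tibble::tibble(
    protein_id = pid,
    filter = filters$name,
    pass = purrr::map_lgl(res, "pass"),
    bcoi = purrr::map(res, "bcoi")
  )
  class(out) <- c("filter_result", class(out))
  out
}

format_bcoi <- function(bcoi) {
  if (nrow(bcoi) == 0) return("")
  paste(sprintf("%s:%d:%s", bcoi$chain, bcoi$resnum, bcoi$group),
        collapse = ";")
}

#' One-line summary of a filter run
#'
#' @param x A `filter_result`.
#' @param ... Unused.
#' @return One-row tibble: `protein_id`, `n_pass`, `n_bcoi_residues`.
#' @export
glance.filter_result <- function(x, ...) {
  tibble::tibble(
    protein_id = x$protein_id[1],
    n_pass = sum(x$pass),
    n_bcoi_residues = nrow(dplyr::distinct(dplyr::bind_rows(x$bcoi)))
  )
}

#' Pivot filter results to one row per protein (S1-file style)
#'
#' @param results A `filter_result` or row-bound set of them.
#' @return Tibble: `protein_id`, one pass column per canonical filter name,
#'   then one `<filter>_bcoi` residue-list column (`chain:resnum:GROUP`,
#'   semicolon-separated).
#' @export
filter_results_wide <- function(results) {
  fl <- canonical_filters()$name
  base <- results |>
    dplyr::mutate(bcoi_str = purrr::map_chr(.data$bcoi, format_bcoi))
  pass_w <- base |>
    dplyr::select("protein_id", "filter", "pass") |>
    tidyr::pivot_wider(names_from = "filter", values_from = "pass")
  bcoi_w <- base |>
    dplyr::select("protein_id", "filter", "bcoi_str") |>
    tidyr::pivot_wider(names_from = "filter", values_from = "bcoi_str",
                       names_glue = "{filter}_bcoi")
  dplyr::left_join(pass_w, bcoi_w, by = "protein_id") |>
    dplyr::select("protein_id", dplyr::all_of(fl),
                  dplyr::all_of(paste0(fl, "_bcoi")))
}

#' Write an S1-file-style results table
#'
#' @param results Row-bound `filter_result` rows for a protein set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filter_table <- function(results, path) {
  readr::write_tsv(filter_results_wide(results), path)
  invisible(path)
}
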