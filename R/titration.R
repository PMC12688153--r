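# pH-dependent ionisation of the coupled site system: exact enumeration for
# small systems, Metropolis Monte Carlo otherwise; apparent pKas and
# protonation differences (delta Q).

#' Build a coupled titration system
#'
#' The microstate energy at a given pH is
#' `E(s; pH) = sum_i s_i gamma_i ln10 R T (pH - pKa_int_i)
#'            + sum_{i<j} s_i s_j W_ij`
#' with `s_i = 1` meaning ionised.
#'
#' @param sites Site tibble with `gamma` and `intrinsic_pka`
#'   (see [desolvation_shift()]).
#' @param W An `interaction_matrix` over the same sites.
#' @param temperature Temperature, K.
#' @return An object of class `microstate_system`.
#' @export
titration_system <- function(sites, W, temperature = 300) {
  stopifnot(identical(sites$site_id, W$site_id))
  structure(
    list(
      site_id = sites$site_id, gamma = sites$gamma,
      pka_int = sites$intrinsic_pka, model_pka = sites$model_pka,
      group = sites$group, W = W$W, temperature = temperature
    ),
    class = "microstate_system"
  )
}

#' @export
print.microstate_system <- function(x, ...) {
  cat(sprintf("<microstate_system> %d sites at T = %g K\n",
              length(x$site_id), x$temperature))
  invisible(x)
}

curve_tbl <- function(system, ph_grid, theta, engine) {
  long <- tibble::tibble(
    site_id = rep(system$site_id, each = length(ph_grid)),
    ph = rep(ph_grid, times = length(system$site_id)),
    ionisation = as.vector(theta)
  )
  attr(long, "system") <- system
  attr(long, "engine") <- engine
  class(long) <- c("titration_curves", class(long))
  long
}

#' Exact titration by microstate enumeration
#'
#' Boltzmann averages of each site's ionisation over all `2^N` microstates
#' at every grid pH, computed with log-sum-exp stabilisation. Serves as the
#' exact oracle for the Monte Carlo engine; limited to 20 sites.
#'
#' @param system A [titration_system()].
#' @param ph_grid Ascending pH grid.
#' @return A `titration_curves` tibble: `site_id`, `ph`, `ionisation`.
#' @export
enumerate_titration <- function(system, ph_grid = seq(0, 14, by = 0.25)) {
  n <- length(system$site_id)
  if (n > 20) {
    stop("enumeration is limited to 20 sites; use mc_titration()")
  }
  rt <- R_GAS * system$temperature
  k10 <- kln10rt(system$temperature)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))  # 2^n x n
  pairE <- 0.5 * rowSums((states %*% system$W) * states)
  theta <- matrix(NA_real_, length(ph_grid), n)
  for (p in seq_along(ph_grid)) {
    h <- system$gamma * k10 * (ph_grid[p] - system$pka_int)
    logw <- -(drop(states %*% h) + pairE) / rt
    logw <- logw - max(logw)
    w <- exp(logw)
    theta[p, ] <- colSums(states * w) / sum(w)
  }
  curve_tbl(system, ph_grid, theta, engine = "enumerate")
}

# Strongly coupled pairs proposed as joint flips in the MC sampler.
strong_pairs <- function(W, threshold) {
  ut <- which(abs(W) >= threshold & upper.tri(W), arr.ind = TRUE)
  matrix(as.integer(ut - 1L), ncol = 2)
}

#' Metropolis Monte Carlo titration
#'
#' Single-site flips, plus joint flips for strongly coupled pairs
#' (|W| at or above `coupling_threshold`) so the sampler can cross
#' correlated-state barriers. One sweep is N single-flip attempts plus one
#' attempt per strongly coupled pair; mean ionisation is averaged after
#' burn-in. Identical seeds give identical output.
#'
#' @inheritParams enumerate_titration
#' @param n_sweeps Number of sweeps (at least 1000).
#' @param n_burnin Burn-in sweeps (default 20% of `n_sweeps`).
#' @param seed Integer RNG seed.
#' @param coupling_threshold kJ/mol threshold for paired flips.
#' @return A `titration_curves` tibble.
#' @export
mc_titration <- function(system, ph_grid = seq(0, 14, by = 0.25),
                         n_sweeps = 20000, n_burnin = round(0.2 * n_sweeps),
                         seed = 1, coupling_threshold = 11.5) {
  if (n_sweeps < 1000) stop("n_sweeps must be >= 1000")
  rt <- R_GAS * system$temperature
  pairs <- strong_pairs(system$W, coupling_threshold)
  theta <- withr::with_seed(seed, cpp_mc_titration(
    system$gamma, system$pka_int, system$W, kln10rt(system$temperature), rt,
    ph_grid, as.integer(n_sweeps), as.integer(n_burnin), pairs
  ))
  curve_tbl(system, ph_grid, theta, engine = "mc")
}

#' Closed-form single-site ionisation
#'
#' Henderson-Hasselbalch limit of an uncoupled, unshifted site:
#' `1 / (1 + 10^(gamma (pH - pKa)))`.
#'
#' @param pka Site pKa.
#' @param gamma +1 for bases, -1 for acids.
#' @param ph pH value(s).
#' @return Mean ionisation in `[0, 1]`.
#' @export
closed_form_ionisation <- function(pka, gamma, ph) {
  1 / (1 + 10^(gamma * (ph - pka)))
}

# Fraction protonated of a model compound with the given pKa (acids and
# bases alike: proton bound below the pKa).
hh_protonation <- function(pka, ph) 1 / (1 + 10^(ph - pka))

#' Apparent pKa from a titration curve
#'
#' The pH of half-ionisation, linearly interpolated between the bracketing
#' grid points. With multiple crossings the one nearest the site's model
#' pKa is taken; a curve that never crosses 0.5 is censored at the grid
#' boundary nearest 0.5.
#'
#' @param curves A `titration_curves` tibble (any number of sites).
#' @return Tibble: `site_id`, `apparent_pka`, `censored`.
#' @export
pka_from_curve <- function(curves) {
  system <- attr(curves, "system")
  curves |>
    dplyr::group_by(.data$site_id) |>
    dplyr::group_modify(function(df, key) {
      ph <- df$ph
      if (length(ph) < 2) stop("titration grid must have >= 2 points")
      if (is.unsorted(ph)) stop("titration grid must be ascending")
      y <- df$ionisation - 0.5
      cross <- which(y[-length(y)] * y[-1] <= 0 &
                       (y[-length(y)] != 0 | y[-1] != 0))
      exact <- which(y == 0)
      cand <- numeric(0)
      for (k in cross) {
        cand <- c(cand, ph[k] + (ph[k + 1] - ph[k]) * (-y[k]) /
                    (y[k + 1] - y[k]))
      }
      cand <- unique(c(cand, ph[exact]))
      if (length(cand) == 0) {
        boundary <- if (abs(y[1]) < abs(y[length(y)])) ph[1] else
          ph[length(ph)]
        return(tibble::tibble(apparent_pka = boundary, censored = TRUE))
      }
      mp <- if (!is.null(system)) {
        system$model_pka[match(key$site_id, system$site_id)]
      } else NA_real_
      pick <- if (is.na(mp)) cand[1] else cand[which.min(abs(cand - mp))]
      tibble::tibble(apparent_pka = pick, censored = FALSE)
    }) |>
    dplyr::ungroup()
}

#' Protonation difference to the free model compound
#'
#' delta Q at a stated pH: the absolute difference between the site's
#' protonation in the protein (from the coupled titration curve) and the
#' free model compound's closed-form protonation. Protonation is
#' `1 - <s>` for acids and `<s>` for bases.
#'
#' @param curves A `titration_curves` tibble.
#' @param ph pH at which to evaluate (must be a grid point).
#' @return Tibble: `site_id`, `ph`, `protonation`, `delta_q`.
#' @export
delta_q_at_ph <- function(curves, ph = 7.0) {
  system <- attr(curves, "system")
  if (is.null(system)) stop("curves lack their system attribute")
  at <- curves |> dplyr::filter(abs(.data$ph - !!ph) < 1e-9)
  if (nrow(at) == 0) stop("pH ", ph, " is not on the titration grid")
  idx <- match(at$site_id, system$site_id)
  gam <- system$gamma[idx]
  prot <- ifelse(gam < 0, 1 - at$ionisation, at$ionisation)
  prot_model <- hh_protonation(system$model_pka[idx], ph)
  tibble::tibble(
    site_id = at$site_id, ph = ph, protonation = prot,
    delta_q = abs(prot - prot_model)
  )
}

#' Tidy per-site summary of a titration run
#'
#' @param x A `titration_curves` tibble.
#' @param ph pH at which delta Q is evaluated.
#' @param ... Unused.
#' @return Tibble: `site_id`, `apparent_pka`, `censored`, `delta_q`.
#' @export
tidy.titration_curves <- function(x, ph = 7.0, ...) {
  dplyr::left_join(
    pka_from_curve(x),
    delta_q_at_ph(x, ph)[, c("site_id", "delta_q")],
    by = "site_id"
  )
}

#' One-line summary of a titration run
#'
#' @param x A `titration_curves` tibble.
#' @param ... Unused.
#' @return One-row tibble: `n_sites`, `n_ph`, `engine`, `n_censored`.
#' @export
glance.titration_curves <- function(x, ...) {
  pk <- pka_from_curve(x)
  tibble::tibble(
    n_sites = dplyr::n_distinct(x$site_id),
    n_ph = dplyr::n_distinct(x$ph),
    engine = attr(x, "engine") %||% NA_character_,
    n_censored = sum(pk$censored)
  )
}

#' Write a per-site titration summary TSV
#'
#' @param curves A `titration_curves` tibble.
#' @param path Output path.
#' @param ph delta Q evaluation pH.
#' @return `path`, invisibly.
#' @export
write_titration_table <- function(curves, path, ph = 7.0) {
  readr::write_tsv(tidy.titration_curves(curves, ph = ph), path)
  invisible(path)
}
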