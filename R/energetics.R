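# Pairwise couplings, desolvation shifts, rotamer DH-access, and the fast
# empirical pKa estimator.

moiety_centroid <- function(model, idx) {
  colMeans(as.matrix(model$atoms[idx, c("x", "y", "z")]))
}

#' Pairwise electrostatic couplings between ionisable sites
#'
#' Simplified continuum model: the coupling between two sites, defined as
#' the energy of having both simultaneously ionised relative to either
#' alone, is a screened Coulomb term between the moiety charge centroids,
#' `W_ij = gamma_i * gamma_j * k_e / (eps_eff * r_ij)` with
#' `k_e = 1389.35 kJ A/mol`. The effective dielectric interpolates between
#' `eps_min` (both sites buried) and `eps_max` (either site fully exposed)
#' on the smaller of the two exposure fractions. Pairs beyond
#' `dist_cutoff` get zero coupling.
#'
#' @param sites Site tibble with `moiety_sasa` (see [add_moiety_sasa()]).
#' @param model The source `protomer`.
#' @param params A [bc_params()] object.
#' @return An `interaction_matrix`: list with `site_id` and symmetric `W`
#'   (kJ/mol, zero diagonal).
#' @export
pairwise_interactions <- function(sites, model, params = bc_params()) {
  n <- nrow(sites)
  W <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  if (n >= 2) {
    cent <- t(vapply(sites$moiety_idx, function(i) moiety_centroid(model, i),
                     numeric(3)))
    f <- exposure_fraction(sites, params)
    d <- as.matrix(stats::dist(cent))
    too_close <- which(d < 0.5 & upper.tri(d), arr.ind = TRUE)
    if (nrow(too_close) > 0) {
      stop(sprintf(
        "coincident moiety centroids (< 0.5 A) between sites %s and %s",
        sites$site_id[too_close[1, 1]], sites$site_id[too_close[1, 2]]
      ))
    }
    fpair <- outer(f, f, pmin)
    eps <- params$eps_min + (params$eps_max - params$eps_min) * fpair
    gg <- outer(sites$gamma, sites$gamma)
    W <- gg * K_COULOMB / (eps * d)
    W[d > params$dist_cutoff] <- 0
    diag(W) <- 0
    dimnames(W) <- list(sites$site_id, sites$site_id)
  }
  structure(list(site_id = sites$site_id, W = W),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  nz <- sum(x$W[upper.tri(x$W)] != 0)
  cat(sprintf("<interaction_matrix> %d sites, %d non-zero pairs\n",
              length(x$site_id), nz))
  invisible(x)
}

#' Tidy an interaction matrix into a pair table
#'
#' @param x An `interaction_matrix`.
#' @param ... Unused.
#' @return Tibble with one row per site pair (`i < j`): `site_i`, `site_j`,
#'   `w_ij` (kJ/mol).
#' @export
tidy.interaction_matrix <- function(x, ...) {
  n <- length(x$site_id)
  if (n < 2) {
    return(tibble::tibble(site_i = character(), site_j = character(),
                          w_ij = numeric()))
  }
  ut <- which(upper.tri(x$W), arr.ind = TRUE)
  tibble::tibble(
    site_i = x$site_id[ut[, 1]],
    site_j = x$site_id[ut[, 2]],
    w_ij = x$W[ut]
  )
}

#' Desolvation shifts and intrinsic pKas
#'
#' Burial of a charge carries a desolvation penalty on the ionised form,
#' modelled as `B * (1 - f)^2` for exposure fraction `f`. The intrinsic pKa
#' is the model-compound value shifted by the penalty: acids shift up,
#' bases down (`pKa_int = pKa_model - gamma * shift / (ln10 R T)`).
#'
#' @inheritParams pairwise_interactions
#' @return `sites` with added `exposure`, `desolv_shift` (kJ/mol) and
#'   `intrinsic_pka` columns.
#' @export
desolvation_shift <- function(sites, params = bc_params()) {
  f <- exposure_fraction(sites, params)
  shift <- params$b_desolv * (1 - f)^2
  sites$exposure <- f
  sites$desolv_shift <- shift
  sites$intrinsic_pka <- sites$model_pka -
    sites$gamma * shift / kln10rt(params$temperature)
  sites
}

# Rotate points about the axis through `origin` with direction `axis` by
# `theta` radians (Rodrigues).
rotate_about_axis <- function(xyz, origin, axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(xyz, 2, origin)
  cosv <- cos(theta); sinv <- sin(theta)
  dotp <- drop(p %*% u)
  crossp <- cbind(
    u[2] * p[, 3] - u[3] * p[, 2],
    u[3] * p[, 1] - u[1] * p[, 3],
    u[1] * p[, 2] - u[2] * p[, 1]
  )
  rot <- p * cosv + crossp * sinv + outer(dotp * (1 - cosv), u)
  sweep(rot, 2, origin, `+`)
}

#' Rotamer-based solvent (Debye-Hueckel) accessibility
#'
#' A buried side chain may still reach a water-dominated interaction scheme
#' by rotating away from the protein body. Side-chain atoms beyond CB are
#' rotated about the CA-CB axis in 120-degree steps (native pose included);
#' rotamers placing a moiety heavy atom within `clash_dist` of a non-bonded
#' heavy atom are discarded, and the site is DH-accessible if any surviving
#' rotamer's moiety SASA reaches `dh_sasa_min`. Sites that are not
#' accessible in any rotamer are "nodh" (relatively buried). Terminal sites
#' and residues lacking CA or CB fall back to the native-pose SASA test.
#'
#' @inheritParams pairwise_interactions
#' @return `sites` with an added logical `dh_access` column.
#' @export
dh_access <- function(sites, model, params = bc_params()) {
  atoms <- model$atoms
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  sites$dh_access <- purrr::pmap_lgl(
    list(sites$chain, sites$resnum, sites$group, sites$moiety_idx),
    function(ch, rn, grp, midx) {
      res_idx <- which(atoms$chain == ch & atoms$resnum == rn)
      ca <- res_idx[atoms$atom[res_idx] == "CA"]
      cb <- res_idx[atoms$atom[res_idx] == "CB"]
      native_ok <- function(xyz) {
        tmp <- atoms
        tmp[, c("x", "y", "z")] <- as.data.frame(xyz)
        at <- compute_sasa(tmp, params$probe_radius, params$n_sphere_points)
        sum(at$sasa[midx]) >= params$dh_sasa_min
      }
      if (grp %in% c("NTERM", "CTERM") || length(ca) != 1 ||
          length(cb) != 1) {
        return(native_ok(coords))
      }
      # side-chain atoms beyond CB rotate; backbone + CB stay fixed
      side_idx <- res_idx[!atoms$atom[res_idx] %in%
                            c("N", "CA", "C", "O", "OXT", "CB")]
      if (length(side_idx) == 0) return(native_ok(coords))
      other_idx <- setdiff(seq_len(nrow(atoms)), res_idx)
      for (theta in c(0, 2 * pi / 3, 4 * pi / 3)) {
        xyz <- coords
        if (theta != 0) {
          xyz[side_idx, ] <- rotate_about_axis(
            coords[side_idx, , drop = FALSE],
            coords[ca, ], coords[cb, ] - coords[ca, ], theta
          )
        }
        if (length(other_idx) > 0) {
          dmin <- min(proxy_min_dist(xyz[midx, , drop = FALSE],
                                     xyz[other_idx, , drop = FALSE]))
          if (dmin < params$clash_dist) next
        }
        if (native_ok(xyz)) return(TRUE)
      }
      FALSE
    }
  )
  sites
}

# Smallest pairwise distance between two point sets.
proxy_min_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  sqrt(max(0, min(d2)))
}

#' Fast empirical pKa estimate
#'
#' A single-pass estimator in the spirit of empirical-rule predictors: the
#' model pKa shifted by the desolvation penalty plus the summed couplings
#' to all other sites, each taken as ionised,
#' `pKa_emp = pKa_model - gamma * (desolv + sum_j W_ij) / (ln10 R T)`.
#' It is exact for an isolated site and serves as the fast range engine
#' behind the "propka-range" style filters.
#'
#' @param sites Site tibble with desolvation columns
#'   (see [desolvation_shift()]).
#' @param W An `interaction_matrix` over the same sites.
#' @param params A [bc_params()] object.
#' @return `sites` with an added `pka_emp` column.
#' @export
empirical_pka <- function(sites, W, params = bc_params()) {
  stopifnot(identical(sites$site_id, W$site_id))
  coup <- unname(rowSums(W$W))
  sites$pka_emp <- sites$model_pka -
    sites$gamma * (sites$desolv_shift + coup) / kln10rt(params$temperature)
  sites
}

#' Write site energetics and interaction tables as TSV
#'
#' @param sites Site tibble with energetics columns.
#' @param W An `interaction_matrix`.
#' @param model Source `protomer`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_energetics_tables <- function(sites, W, model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cent <- t(vapply(sites$moiety_idx, function(i) moiety_centroid(model, i),
                   numeric(3)))
  pair <- tidy.interaction_matrix(W)
  if (nrow(pair) > 0) {
    ij <- cbind(match(pair$site_i, sites$site_id),
                match(pair$site_j, sites$site_id))
    pair$r_ij <- sqrt(rowSums((cent[ij[, 1], , drop = FALSE] -
                                 cent[ij[, 2], , drop = FALSE])^2))
    pair <- pair[, c("site_i", "site_j", "r_ij", "w_ij")]
  }
  readr::write_tsv(pair, file.path(dir, "interactions.tsv"))
  readr::write_tsv(
    sites |> dplyr::select(-dplyr::any_of("moiety_idx")),
    file.path(dir, "site_energetics.tsv")
  )
  invisible(dir)
}
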