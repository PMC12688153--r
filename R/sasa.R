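# Shrake-Rupley solvent-accessible surface area.

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley: for each atom, test points are placed quasi-uniformly on
#' its solvent-expanded sphere (radius + probe) and the exposed fraction
#' (points not inside any other expanded sphere) is multiplied by the
#' expanded-sphere area.
#'
#' @param model A `protomer`, or a tibble/data frame of atoms with columns
#'   `x`, `y`, `z`, `radius`.
#' @param probe_radius Probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Test points per atom (default 960). Fewer than 16
#'   points cannot meet the accuracy contract and is an error.
#' @return The atom tibble with an added `sasa` column (A^2).
#' @export
compute_sasa <- function(model, probe_radius = 1.4, n_sphere_points = 960) {
  if (n_sphere_points < 16) {
    stop("n_sphere_points must be >= 16 for a meaningful SASA estimate")
  }
  atoms <- if (inherits(model, "protomer")) model$atoms else
    tibble::as_tibble(model)
  if (any(atoms$radius <= 0)) stop("all atoms must have positive radii")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  atoms$sasa <- cpp_sasa(coords, atoms$radius, probe_radius,
                         as.integer(n_sphere_points))
  atoms
}

#' Moiety SASA per ionisable site
#'
#' Sums the per-atom SASA over each site's charged-moiety atoms, the burial
#' measure every filter thresholds.
#'
#' @param sites Site tibble from [extract_ionizable_sites()].
#' @param model The source `protomer`.
#' @inheritParams compute_sasa
#' @return `sites` with an added `moiety_sasa` column (A^2).
#' @export
add_moiety_sasa <- function(sites, model, probe_radius = 1.4,
                            n_sphere_points = 960) {
  atoms <- compute_sasa(model, probe_radius, n_sphere_points)
  sites$moiety_sasa <- purrr::map_dbl(sites$moiety_idx,
                                      function(i) sum(atoms$sasa[i]))
  sites
}

# Reference moiety SASA of each fully exposed group, from an isolated-residue
# template (the model compound). Computed once per (probe, n_points) and
# memoised; used to convert moiety SASA into an exposure fraction.
ref_sasa_env <- new.env(parent = emptyenv())

moiety_template <- function(group) {
  # Minimal idealised geometry: attachment atom(s) plus the charged moiety.
  # Bond lengths in Angstrom; only the moiety atoms contribute to the
  # reference value, the attachment atom supplies realistic occlusion.
  carboxylate <- function(c1, c2, o1, o2) {
    tibble::tibble(
      atom = c(c1, c2, o1, o2),
      element = c("C", "C", "O", "O"),
      x = c(0, 0, 1.10, -1.10),
      y = c(0, 0, 0, 0),
      z = c(0, 1.52, 2.12, 2.12)
    )
  }
  switch(group,
    ASP = carboxylate("CB", "CG", "OD1", "OD2"),
    GLU = carboxylate("CG", "CD", "OE1", "OE2"),
    CTERM = carboxylate("CA", "C", "O", "OXT"),
    LYS = tibble::tibble(atom = c("CE", "NZ"), element = c("C", "N"),
                         x = 0, y = 0, z = c(0, 1.49)),
    CYS = tibble::tibble(atom = c("CB", "SG"), element = c("C", "S"),
                         x = 0, y = 0, z = c(0, 1.81)),
    TYR = tibble::tibble(atom = c("CZ", "OH"), element = c("C", "O"),
                         x = 0, y = 0, z = c(0, 1.36)),
    NTERM = tibble::tibble(atom = c("CA", "N"), element = c("C", "N"),
                           x = 0, y = 0, z = c(0, 1.46)),
    ARG = tibble::tibble(
      atom = c("CD", "NE", "CZ", "NH1", "NH2"),
      element = c("C", "N", "C", "N", "N"),
      x = c(0, 0, 0, 1.15, -1.15),
      y = 0,
      z = c(0, 1.46, 2.79, 3.46, 3.46)
    ),
    HIS = {
      # planar imidazole, bond ~1.37, regular pentagon + CB attachment
      ang <- (0:4) * 2 * pi / 5
      rad <- 1.37 / (2 * sin(pi / 5))
      tibble::tibble(
        atom = c("CB", "CG", "ND1", "CE1", "NE2", "CD2"),
        element = c("C", "C", "N", "C", "N", "C"),
        x = c(rad + 1.50, rad * cos(ang)),
        y = c(0, rad * sin(ang)),
        z = rep(0, 6)
      )
    },
    stop("unknown group: ", group)
  )
}

#' Reference (fully exposed) moiety SASA per group
#'
#' Computed once from an isolated-residue template and cached.
#'
#' @inheritParams compute_sasa
#' @param radii Named element radii.
#' @return Named numeric vector of model-compound moiety SASA (A^2).
#' @export
reference_moiety_sasa <- function(probe_radius = 1.4, n_sphere_points = 960,
                                  radii = default_radii()) {
  key <- paste(probe_radius, n_sphere_points, paste(radii, collapse = ","),
               sep = "|")
  if (!is.null(ref_sasa_env[[key]])) return(ref_sasa_env[[key]])
  groups <- names(MOIETY_ATOMS)
  vals <- vapply(groups, function(g) {
    tmpl <- moiety_template(g)
    tmpl$radius <- element_radius(tmpl$element, radii)
    at <- compute_sasa(tmpl, probe_radius, n_sphere_points)
    sum(at$sasa[at$atom %in% MOIETY_ATOMS[[g]]])
  }, numeric(1))
  names(vals) <- groups
  ref_sasa_env[[key]] <- vals
  vals
}

# Exposure fraction f = min(1, moiety_sasa / ref_sasa), per site.
exposure_fraction <- function(sites, params = bc_params()) {
  ref <- reference_moiety_sasa(params$probe_radius, params$n_sphere_points,
                               params$radii)
  pmin(1, sites$moiety_sasa / unname(ref[sites$group]))
}
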