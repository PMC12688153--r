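# Shared fixture builders and independent oracles.

GAMMA <- c(ASP = -1, GLU = -1, CYS = -1, TYR = -1, CTERM = -1,
           LYS = +1, ARG = +1, HIS = +1, NTERM = +1)

# Minimal titration system without going through a structure.
make_system <- function(groups, pka_int, W = NULL, temperature = 300) {
  n <- length(groups)
  if (is.null(W)) W <- matrix(0, n, n)
  sites <- tibble::tibble(
    site_id = paste0("s", seq_len(n)),
    group = groups,
    gamma = unname(GAMMA[groups]),
    model_pka = unname(default_model_pkas()[groups]),
    intrinsic_pka = pka_int
  )
  Wm <- structure(list(site_id = sites$site_id, W = W),
                  class = "interaction_matrix")
  titration_system(sites, Wm, temperature)
}

# Brute-force Boltzmann average over explicitly listed microstates:
# independent oracle for the enumeration engine (no log-sum-exp, direct
# formula on a hand-built state list).
brute_titration <- function(system, ph) {
  n <- length(system$site_id)
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  rt <- 8.31446e-3 * system$temperature
  k10 <- log(10) * rt
  h <- system$gamma * k10 * (ph - system$pka_int)
  E <- drop(states %*% h) + 0.5 * rowSums((states %*% system$W) * states)
  w <- exp(-(E - min(E)) / rt)
  colSums(states * w) / sum(w)
}

# Bare model with one moiety atom per ionisable residue at exact
# positions: lets tests pin inter-site distances without full geometry.
point_charge_model <- function(groups, centers, protein_id = "pts") {
  one_atom <- c(ASP = "OD1", GLU = "OE1", LYS = "NZ", ARG = "CZ",
                HIS = "NE2", CYS = "SG", TYR = "OH")
  elem <- c(ASP = "O", GLU = "O", LYS = "N", ARG = "C", HIS = "N",
            CYS = "S", TYR = "O")
  radii <- default_radii()
  atoms <- tibble::tibble(
    chain = "A", resnum = seq_along(groups), resname = groups,
    aa = NA_character_,
    atom = unname(one_atom[groups]), element = unname(elem[groups]),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    radius = unname(radii[elem[groups]])
  )
  model <- new_protomer(atoms, protein_id)
  sites <- extract_ionizable_sites(model)
  list(model = model, sites = sites)
}

# Dense-grid numerical integration of the accessible area of sphere 1 in
# the presence of sphere 2: oracle for the Shrake-Rupley implementation.
grid_sasa_two_spheres <- function(c1, r1, c2, r2, probe, n_theta = 400) {
  R1 <- r1 + probe
  R2 <- r2 + probe
  theta <- (seq_len(n_theta) - 0.5) * pi / n_theta
  nphi <- 2 * n_theta
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  area <- 0
  for (t in theta) {
    pts <- cbind(R1 * sin(t) * cos(phi), R1 * sin(t) * sin(phi),
                 R1 * cos(t))
    pts <- sweep(pts, 2, c1, `+`)
    d2 <- rowSums(sweep(pts, 2, c2)^2)
    frac <- mean(d2 >= R2^2)
    area <- area + frac * sin(t) * (pi / n_theta) * 2 * pi / nphi *
      nphi * R1^2
  }
  area
}

# Brute-force connected components by reachability closure.
brute_components <- function(nodes, edges) {
  comp <- stats::setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$site_i[k]; b <- edges$site_j[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[comp == comp[a] | comp == comp[b]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# The standard planted toy protomer, analysed once and cached.
.fixture_env <- new.env(parent = emptyenv())

toy_fixture <- function() {
  if (is.null(.fixture_env$toy)) {
    toy <- make_toy_protomer(list(
      buried_cluster(c("ASP", "LYS", "ASP"), distance = 7),
      surface_singleton("LYS"),
      rotamer_gate("LYS")
    ))
    toy$analysis <- analyze_protomer(toy$model)
    toy$suite <- run_filter_suite(toy$analysis)
    .fixture_env$toy <- toy
  }
  .fixture_env$toy
}

# Surface-placed variant of the same triad (no cage).
toy_surface_fixture <- function() {
  if (is.null(.fixture_env$toysurf)) {
    toy <- make_toy_protomer(list(
      buried_cluster(c("ASP", "LYS", "ASP"), distance = 7, cage = FALSE)
    ), protein_id = "toysurf")
    toy$analysis <- analyze_protomer(toy$model)
    toy$suite <- run_filter_suite(toy$analysis)
    .fixture_env$toysurf <- toy
  }
  .fixture_env$toysurf
}
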