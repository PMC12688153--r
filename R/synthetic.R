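# Synthetic inputs: toy protomers with controlled charge burial, and
# cohorts with planted enrichment.

# Local residue templates: backbone in the xz-plane, side chain leaving CB
# along a direction tilted 30 degrees off the CA-CB (+z) axis so that
# chi-axis rotamers sweep distinct positions.
toy_residue_template <- function(type) {
  u <- c(0.5, 0, sqrt(3) / 2)     # side-chain growth direction
  v2 <- c(0, 1, 0)                # branch direction
  cb <- c(0, 0, 1.53)
  at <- function(atom, element, pos) {
    tibble::tibble(atom = atom, element = element,
                   x = pos[1], y = pos[2], z = pos[3])
  }
  bb <- dplyr::bind_rows(
    at("N", "N", c(-1.20, 0.77, -0.40)),
    at("CA", "C", c(0, 0, 0)),
    at("C", "C", c(1.25, 0.88, -0.40)),
    at("O", "O", c(1.30, 2.11, -0.45)),
    at("CB", "C", cb)
  )
  grow <- function(from, dist) from + dist * u
  side <- switch(type,
    GLY = NULL,
    ASP = {
      cg <- grow(cb, 1.52)
      dplyr::bind_rows(
        at("CG", "C", cg),
        at("OD1", "O", cg + 0.63 * u + 1.08 * v2),
        at("OD2", "O", cg + 0.63 * u - 1.08 * v2)
      )
    },
    GLU = {
      cg <- grow(cb, 1.52); cd <- grow(cg, 1.52)
      dplyr::bind_rows(
        at("CG", "C", cg), at("CD", "C", cd),
        at("OE1", "O", cd + 0.63 * u + 1.08 * v2),
        at("OE2", "O", cd + 0.63 * u - 1.08 * v2)
      )
    },
    LYS = {
      cg <- grow(cb, 1.52); cd <- grow(cg, 1.52); ce <- grow(cd, 1.52)
      dplyr::bind_rows(
        at("CG", "C", cg), at("CD", "C", cd), at("CE", "C", ce),
        at("NZ", "N", grow(ce, 1.49))
      )
    },
    ARG = {
      cg <- grow(cb, 1.52); cd <- grow(cg, 1.52); ne <- grow(cd, 1.46)
      cz <- grow(ne, 1.33)
      dplyr::bind_rows(
        at("CG", "C", cg), at("CD", "C", cd), at("NE", "N", ne),
        at("CZ", "C", cz),
        at("NH1", "N", cz + 0.65 * u + 1.15 * v2),
        at("NH2", "N", cz + 0.65 * u - 1.15 * v2)
      )
    },
    HIS = {
      cg <- grow(cb, 1.50)
      dplyr::bind_rows(
        at("CG", "C", cg),
        at("ND1", "N", cg + 0.76 * u + 1.14 * v2),
        at("CD2", "C", cg + 0.76 * u - 1.14 * v2),
        at("CE1", "C", cg + 2.05 * u + 0.65 * v2),
        at("NE2", "N", cg + 2.05 * u - 0.65 * v2)
      )
    },
    CYS = at("SG", "S", grow(cb, 1.81)),
    TYR = {
      cg <- grow(cb, 1.50); cz <- grow(cg, 2.80)
      dplyr::bind_rows(at("CG", "C", cg), at("CZ", "C", cz),
                       at("OH", "O", grow(cz, 1.36)))
    },
    stop("unsupported toy residue type: ", type)
  )
  dplyr::bind_rows(bb, side)
}

toy_moiety_centroid <- function(tmpl, type) {
  m <- tmpl[tmpl$atom %in% MOIETY_ATOMS[[type]], c("x", "y", "z")]
  colMeans(as.matrix(m))
}

# Cubic grid of occluding pseudo-atoms within `radius` of `center`,
# excluding nodes within `clearance` of any coordinate in `avoid` (n x 3).
occluding_grid <- function(center, radius, avoid, clearance = 2.8,
                           spacing = 2.2) {
  s <- seq(-radius, radius, by = spacing)
  g <- as.matrix(expand.grid(x = s, y = s, z = s))
  g <- g[rowSums(g^2) <= radius^2, , drop = FALSE]
  g <- sweep(g, 2, center, `+`)
  if (nrow(avoid) > 0 && nrow(g) > 0) {
    d2 <- outer(rowSums(g^2), rowSums(avoid^2), `+`) -
      2 * g %*% t(avoid)
    g <- g[apply(d2, 1, min) > clearance^2, , drop = FALSE]
  }
  g
}

#' Planted feature constructors for toy protomers
#'
#' `buried_cluster()` plants ionisable residues with moiety centroids at
#' the requested pairwise distance, enclosed in an occluding pseudo-atom
#' cage so every moiety is deeply buried. `surface_singleton()` plants one
#' fully exposed residue. `rotamer_gate()` plants a residue whose native
#' side-chain pose is occluded but whose 120-degree rotamer is open, so the
#' site stays DH-accessible despite native burial.
#'
#' @param types Residue types (three-letter) for the cluster members.
#' @param distance Pairwise moiety-centroid distance, Angstrom (realised
#'   within 0.1 A; all pairs for up to three members).
#' @param cage Enclose the cluster in an occluding cage (default TRUE).
#' @name toy_features
#' @return A feature specification list.
#' @export
buried_cluster <- function(types, distance = 7, cage = TRUE) {
  stopifnot(length(types) >= 1)
  structure(list(kind = "buried_cluster", types = types,
                 distance = distance, cage = cage),
            class = "toy_feature")
}

#' @rdname toy_features
#' @param type Residue type for the single planted residue.
#' @export
surface_singleton <- function(type = "LYS") {
  structure(list(kind = "surface_singleton", types = type),
            class = "toy_feature")
}

#' @rdname toy_features
#' @export
rotamer_gate <- function(type = "LYS") {
  structure(list(kind = "rotamer_gate", types = type),
            class = "toy_feature")
}

place_residue <- function(type, centroid_target) {
  tmpl <- toy_residue_template(type)
  anchor <- if (is.null(MOIETY_ATOMS[[type]])) {
    unlist(tmpl[tmpl$atom == "CB", c("x", "y", "z")])
  } else {
    toy_moiety_centroid(tmpl, type)
  }
  shift <- centroid_target - anchor
  tmpl$x <- tmpl$x + shift[1]
  tmpl$y <- tmpl$y + shift[2]
  tmpl$z <- tmpl$z + shift[3]
  tmpl
}

# Moiety centroid targets for a cluster of k members at pairwise `d`.
cluster_layout <- function(k, d) {
  if (k == 1) return(matrix(0, 1, 3))
  if (k == 2) return(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)))
  if (k == 3) {
    r <- d / sqrt(3)
    ang <- c(90, 210, 330) * pi / 180
    return(cbind(r * cos(ang), r * sin(ang), 0))
  }
  # k > 3: regular polygon with side d (adjacent pairs at d)
  r <- d / (2 * sin(pi / k))
  ang <- 2 * pi * (seq_len(k) - 1) / k
  cbind(r * cos(ang), r * sin(ang), 0)
}

#' Generate a toy protomer with planted burial features
#'
#' Builds a chemically minimal but parseable single-chain structure from a
#' list of planted features (see [toy_features]), spaced far enough apart
#' not to interact, and returns both the model and a ground-truth manifest
#' recording each planted site's intended burial class. The output is
#' deterministic (and byte-identical as PDB) for a given specification.
#'
#' @param features List of feature specifications.
#' @param protein_id Identifier.
#' @param seed Seed recorded for provenance; the construction itself is
#'   deterministic.
#' @param path Optional path; when given, the model is also written as PDB.
#' @return List: `model` (a `protomer`), `manifest` (tibble: `feature`,
#'   `kind`, `chain`, `resnum`, `group`, `burial_class`, `distance`),
#'   `path`.
#' @export
make_toy_protomer <- function(features, protein_id = "toy", seed = 1,
                              path = NULL) {
  stopifnot(length(features) >= 1)
  atoms_all <- list()
  manifest <- list()
  resnum <- 0L
  cage_count <- 0L
  offset_x <- 0
  for (fi in seq_along(features)) {
    ft <- features[[fi]]
    k <- length(ft$types)
    layout <- cluster_layout(k, ft$distance %||% 7)
    layout[, 1] <- layout[, 1] + offset_x
    res_atoms <- list()
    for (j in seq_len(k)) {
      resnum <- resnum + 1L
      tmpl <- place_residue(ft$types[j], layout[j, ])
      tmpl$resnum <- resnum
      tmpl$resname <- ft$types[j]
      res_atoms[[j]] <- tmpl
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        feature = fi, kind = ft$kind, chain = "A", resnum = resnum,
        group = ft$types[j],
        burial_class = switch(ft$kind,
          buried_cluster = "buried",
          surface_singleton = "surface",
          rotamer_gate = "gated"
        ),
        distance = if (ft$kind == "buried_cluster" && k > 1) {
          ft$distance
        } else NA_real_
      )
    }
    planted <- dplyr::bind_rows(res_atoms)
    pl_xyz <- as.matrix(planted[, c("x", "y", "z")])
    # clash check among planted atoms across residues
    if (k > 1) {
      for (a in seq_len(k - 1)) {
        for (b in (a + 1):k) {
          xa <- as.matrix(res_atoms[[a]][, c("x", "y", "z")])
          xb <- as.matrix(res_atoms[[b]][, c("x", "y", "z")])
          if (proxy_min_dist(xa, xb) < 1.8) {
            stop("infeasible geometry: planted residues overlap ",
                 "(increase the cluster distance)")
          }
        }
      }
    }
    cage_xyz <- NULL
    if (ft$kind == "buried_cluster" && isTRUE(ft$cage %||% TRUE)) {
      center <- colMeans(pl_xyz)
      radius <- max(sqrt(rowSums(sweep(pl_xyz, 2, center)^2))) + 4.2
      cage_xyz <- occluding_grid(center, radius, pl_xyz)
    } else if (ft$kind == "rotamer_gate") {
      res <- res_atoms[[1]]
      xyz <- as.matrix(res[, c("x", "y", "z")])
      ca <- xyz[res$atom == "CA", ]
      cbv <- xyz[res$atom == "CB", ] - ca
      midx <- which(res$atom %in% MOIETY_ATOMS[[ft$types[1]]])
      side_idx <- which(!res$atom %in% c("N", "CA", "C", "O", "CB"))
      m0 <- xyz[midx, , drop = FALSE]
      rot_pts <- do.call(rbind, lapply(c(2, 4) * pi / 3, function(th) {
        rotate_about_axis(xyz[side_idx, , drop = FALSE], ca, cbv, th)
      }))
      cage_xyz <- occluding_grid(colMeans(m0), 5.2,
                                 avoid = rbind(xyz, rot_pts),
                                 clearance = 3.0, spacing = 2.0)
    }
    if (!is.null(cage_xyz) && nrow(cage_xyz) > 0) {
      cage_count <- cage_count + 1L
      # chunk the cage into pseudo-residues of <= 100 atoms so PDB atom
      # names stay within 4 characters
      chunk <- (seq_len(nrow(cage_xyz)) - 1L) %/% 100L
      for (cc in unique(chunk)) {
        resnum <- resnum + 1L
        sel <- chunk == cc
        atoms_all[[length(atoms_all) + 1]] <- tibble::tibble(
          atom = sprintf("C%02d", seq_len(sum(sel)) - 1L),
          element = "C",
          x = cage_xyz[sel, 1], y = cage_xyz[sel, 2], z = cage_xyz[sel, 3],
          resnum = resnum, resname = "CAG"
        )
      }
    }
    atoms_all[[length(atoms_all) + 1]] <- planted
    offset_x <- offset_x + 50
  }
  atoms <- dplyr::bind_rows(atoms_all) |>
    dplyr::arrange(.data$resnum) |>
    dplyr::mutate(
      chain = "A",
      aa = unname(AA3TO1[.data$resname]),
      radius = element_radius(.data$element, default_radii()),
      plddt = 90
    )
  model <- new_protomer(atoms, protein_id, source_format = "synthetic")
  if (!is.null(path)) write_protomer(model, path)
  list(model = model, manifest = dplyr::bind_rows(manifest), path = path,
       seed = seed)
}

#' Generate a synthetic protein cohort with planted statistics
#'
#' Emulates a proteome-scale label and result set: enzyme/transporter (ET)
#' labels at a set fraction, Bernoulli per-filter pass flags at
#' class-conditional rates, and GO annotations with a planted per-term
#' fold enrichment in the query class (the proteins passing the first
#' filter). Defaults mirror the proportions of the human-proteome study
#' conditions: an ET fraction of 4810/20503, a pH-dependence label rate of
#' 306/20503, and per-filter pass rates of 0.55 (ET) and 0.24 (NET).
#'
#' @param n_proteins Cohort size.
#' @param fraction_et Probability a protein is labelled ET.
#' @param pass_prob_et,pass_prob_net Per-filter pass probabilities
#'   (recycled over `filters`).
#' @param filters Filter names for the pass table.
#' @param go_terms Tibble of planted terms: `term_id`, `base_prob`,
#'   `fold`. The designated GO query class (a random fraction
#'   `go_query_frac` of the cohort, standing in for the consistently
#'   BCOI-positive minority) is annotated at the rate that makes the
#'   expected measured fold against the full reference equal `fold`;
#'   proteins outside the class are annotated at `base_prob`.
#' @param go_query_frac Fraction of proteins in the designated GO query
#'   class.
#' @param ph_rate Probability of a pH-dependence label.
#' @param seed RNG seed; all randomness flows from it.
#' @return List of tibbles: `labels`, `passes` (long), `annotations`,
#'   `hierarchy`, plus `query` (the designated GO query protein ids).
#' @export
make_cohort <- function(n_proteins = 5000,
                        fraction_et = 4810 / 20503,
                        pass_prob_et = 0.55, pass_prob_net = 0.24,
                        filters = canonical_filters()$name,
                        go_terms = tibble::tibble(
                          term_id = c("GO:PLANT1", "GO:NULL1", "GO:NULL2"),
                          base_prob = c(0.15, 0.10, 0.20),
                          fold = c(3, 1, 1)
                        ),
                        go_query_frac = 0.08,
                        ph_rate = 306 / 20503,
                        seed = 1) {
  stopifnot(fraction_et >= 0, fraction_et <= 1,
            all(go_terms$fold > 0),
            go_query_frac > 0, go_query_frac < 1)
  pe <- rep_len(pass_prob_et, length(filters))
  pn <- rep_len(pass_prob_net, length(filters))
  stopifnot(all(c(pe, pn) >= 0), all(c(pe, pn) <= 1))
  withr::with_seed(seed, {
    ids <- sprintf("P%05d", seq_len(n_proteins))
    is_et <- stats::runif(n_proteins) < fraction_et
    split_t <- stats::runif(n_proteins) < 383 / 4810
    labels <- tibble::tibble(
      protein_id = ids,
      enzyme = as.integer(is_et & !split_t),
      transporter = as.integer(is_et & split_t),
      ph_dependent = as.integer(stats::runif(n_proteins) < ph_rate)
    )
    passes <- tidyr::expand_grid(protein_id = ids, filter = filters) |>
      dplyr::mutate(
        p = ifelse(rep(is_et, each = length(filters)),
                   pe[match(.data$filter, filters)],
                   pn[match(.data$filter, filters)]),
        pass = stats::runif(dplyr::n()) < .data$p
      ) |>
      dplyr::select(-"p")
    query <- ids[stats::runif(n_proteins) < go_query_frac]
    q <- length(query) / n_proteins
    ann <- purrr::pmap_dfr(
      go_terms,
      function(term_id, base_prob, fold) {
        # query-class rate chosen so the expected measured fold against
        # the full reference (query included) equals the planted fold:
        # y / (q y + (1 - q) x) = fold  =>  y = fold (1-q) x / (1 - q fold)
        y <- if (q * fold < 1) {
          fold * (1 - q) * base_prob / (1 - q * fold)
        } else {
          1
        }
        p <- ifelse(ids %in% query, min(1, y), base_prob)
        hit <- stats::runif(n_proteins) < p
        tibble::tibble(protein_id = ids[hit], term_id = term_id)
      }
    )
    hierarchy <- tibble::tibble(term_id = go_terms$term_id,
                                parent_id = "GO:ROOT")
    list(labels = labels, passes = passes, annotations = ann,
         hierarchy = hierarchy, query = query)
  })
}
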