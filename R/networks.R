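# Coupled-charge graphs and buried charge networks.

#' Build the strong-coupling graph
#'
#' Sites are linked when the magnitude of their pairwise coupling reaches
#' `threshold` (default 11.5 kJ/mol, a 2-unit pKa shift at 300 K; the
#' boundary is inclusive). Attractive and repulsive couplings both qualify.
#'
#' @param W An `interaction_matrix`.
#' @param threshold Coupling threshold, kJ/mol (> 0).
#' @return A `coupling_graph`: list with `site_id`, `edges` tibble
#'   (`site_i`, `site_j`, `w_ij`) and `threshold`.
#' @export
coupling_graph <- function(W, threshold = 11.5) {
  if (threshold <= 0) stop("coupling threshold must be positive")
  edges <- tidy.interaction_matrix(W) |>
    dplyr::filter(abs(.data$w_ij) >= threshold)
  structure(
    list(site_id = W$site_id, edges = edges, threshold = threshold),
    class = "coupling_graph"
  )
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf("<coupling_graph> %d sites, %d edges at |W| >= %g kJ/mol\n",
              length(x$site_id), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Extract buried charge networks
#'
#' Restricts the coupling graph to sites passing the burial condition
#' (every network member must be buried, including non-D/E/K/R/H bridges),
#' takes connected components, and keeps those with at least `min_dekrh`
#' members of type D/E/K/R/H. Non-D/E/K/R/H members may bridge components
#' but never count toward the size threshold.
#'
#' @param graph A [coupling_graph()].
#' @param sites Site tibble with `moiety_sasa` and, for `mode = "nodh"`,
#'   `dh_access` (see [dh_access()]).
#' @param burial Either `list(sasa_max = <A^2>)` or `list(mode = "nodh")`.
#' @param min_dekrh Minimum number of coupled D/E/K/R/H members.
#' @return Tibble with one row per qualifying network: `network_id`,
#'   `members` (list of site_ids), `dekrh_members` (list), `size`,
#'   `dekrh_size`.
#' @export
charge_networks <- function(graph, sites, burial, min_dekrh = 2) {
  if (!is.null(burial$sasa_max)) {
    if (!"moiety_sasa" %in% names(sites)) {
      stop("sites need moiety_sasa for SASA-based burial")
    }
    buried_ids <- sites$site_id[sites$moiety_sasa <= burial$sasa_max]
  } else if (identical(burial$mode, "nodh")) {
    if (!"dh_access" %in% names(sites)) {
      stop("sites need dh_access flags for nodh burial")
    }
    buried_ids <- sites$site_id[!sites$dh_access]
  } else {
    stop("unknown burial mode; supply list(sasa_max=) or list(mode='nodh')")
  }
  keep <- intersect(graph$site_id, buried_ids)
  edges <- graph$edges |>
    dplyr::filter(.data$site_i %in% keep & .data$site_j %in% keep)
  empty <- tibble::tibble(
    network_id = integer(), members = list(), dekrh_members = list(),
    size = integer(), dekrh_size = integer()
  )
  if (length(keep) == 0) return(empty)
  g <- igraph::graph_from_data_frame(
    edges[, c("site_i", "site_j")], directed = FALSE,
    vertices = data.frame(name = keep)
  )
  comp <- igraph::components(g)
  grp_of <- sites$group[match(keep, sites$site_id)]
  nets <- tibble::tibble(site_id = keep,
                         comp = comp$membership[keep],
                         dekrh = grp_of %in% DEKRH) |>
    dplyr::group_by(.data$comp) |>
    dplyr::summarise(
      members = list(.data$site_id),
      dekrh_members = list(.data$site_id[.data$dekrh]),
      size = dplyr::n(),
      dekrh_size = sum(.data$dekrh),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$dekrh_size >= min_dekrh) |>
    dplyr::mutate(network_id = dplyr::row_number()) |>
    dplyr::select("network_id", "members", "dekrh_members", "size",
                  "dekrh_size")
  if (nrow(nets) == 0) empty else nets
}

#' Write a charge-network table as TSV
#'
#' @param networks Output of [charge_networks()].
#' @param protein_id Protein identifier.
#' @param burial_mode Label recorded in the output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(networks, protein_id, burial_mode, path) {
  out <- networks |>
    dplyr::transmute(
      protein_id = protein_id,
      network_id = .data$network_id,
      members = purrr::map_chr(.data$members, paste, collapse = ";"),
      dekrh_size = .data$dekrh_size,
      burial_mode = burial_mode
    )
  readr::write_tsv(out, path)
  invisible(path)
}
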