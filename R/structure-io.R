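# Reading/writing protomer models and extracting ionisable sites.

#' Construct a protomer model from an atom table
#'
#' A protomer is a single-polypeptide structure model held as a tidy atom
#' table. Most users will call [read_protomer()] or [make_toy_protomer()]
#' instead.
#'
#' @param atoms Tibble with columns `chain`, `resnum`, `resname` (3-letter),
#'   `aa` (1-letter), `atom`, `element`, `x`, `y`, `z`, `radius` and
#'   optionally `plddt`.
#' @param protein_id Identifier carried through all outputs.
#' @param source_format `"pdb"`, `"cif"` or `"synthetic"`.
#' @return An object of class `protomer`.
#' @export
new_protomer <- function(atoms, protein_id, source_format = "synthetic") {
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) == 0) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("model contains atoms with non-finite coordinates")
  }
  if (any(atoms$radius <= 0)) stop("atom radii must be positive")
  dup <- atoms |>
    dplyr::count(.data$chain, .data$resnum, .data$atom) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop(sprintf(
      "duplicate atom name '%s' in residue %s:%d",
      dup$atom[1], dup$chain[1], dup$resnum[1]
    ))
  }
  # residue numbering must be strictly increasing within each chain
  ord <- atoms |> dplyr::distinct(.data$chain, .data$resnum)
  bad <- ord |>
    dplyr::group_by(.data$chain) |>
    dplyr::summarise(ok = !is.unsorted(.data$resnum, strictly = TRUE)) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    stop(sprintf("residue numbering not strictly increasing in chain %s",
                 bad$chain[1]))
  }
  if ("plddt" %in% names(atoms) && any(!is.na(atoms$plddt))) {
    pl <- atoms$plddt[!is.na(atoms$plddt)]
    if (any(pl < 0 | pl > 100)) stop("plddt values must lie in [0, 100]")
  }
  structure(
    list(protein_id = protein_id, atoms = atoms, source_format = source_format),
    class = "protomer"
  )
}

#' @export
print.protomer <- function(x, ...) {
  res <- dplyr::distinct(x$atoms, .data$chain, .data$resnum)
  cat(sprintf(
    "<protomer> %s: %d atoms, %d residues, %d chain(s) [%s]\n",
    x$protein_id, nrow(x$atoms), nrow(res),
    length(unique(x$atoms$chain)), x$source_format
  ))
  invisible(x)
}

#' @export
as_tibble.protomer <- function(x, ...) x$atoms

#' Residue-level summary of a protomer
#'
#' @param model A `protomer`.
#' @return Tibble with one row per residue: `chain`, `resnum`, `resname`,
#'   `aa`, `n_atoms`, `plddt`.
#' @export
protomer_residues <- function(model) {
  model$atoms |>
    dplyr::group_by(.data$chain, .data$resnum) |>
    dplyr::summarise(
      resname = .data$resname[1], aa = .data$aa[1],
      n_atoms = dplyr::n(),
      plddt = if ("plddt" %in% names(model$atoms)) .data$plddt[1] else NA_real_,
      .groups = "drop"
    )
}

element_radius <- function(element, radii) {
  r <- unname(radii[element])
  r[is.na(r)] <- unname(radii["C"])
  r
}

#' Read a protomer model from a PDB or mmCIF file
#'
#' Heavy (non-hydrogen) `ATOM` records are retained; hetero atoms, hydrogens
#' and non-primary alternate locations are dropped. The B-factor column is
#' mapped to per-residue pLDDT (AlphaFold convention). Radii are assigned
#' per element from `radii`.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @param radii Named element radii, see [default_radii()].
#' @param protein_id Identifier; defaults to the file base name.
#' @return A `protomer`.
#' @export
read_protomer <- function(path, format = c("auto", "pdb", "cif"),
                          radii = default_radii(), protein_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop(sprintf("cannot parse %s file '%s': %s",
                                     format, path, conditionMessage(e)))
  )
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!is.null(at$alt)) at <- at[is.na(at$alt) | at$alt %in% c("", "A"), ,
                                 drop = FALSE]
  ele <- at$elesy
  if (is.null(ele) || all(is.na(ele) | ele == "")) {
    ele <- substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)
  }
  ele <- toupper(trimws(ele))
  keep <- !(ele %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  ele <- ele[keep]
  if (nrow(at) == 0) stop("empty model: no heavy ATOM records in ", path)
  chain <- ifelse(is.na(at$chain) | at$chain == "", "A", at$chain)
  atoms <- tibble::tibble(
    chain = chain,
    resnum = as.integer(at$resno),
    resname = toupper(at$resid),
    aa = unname(AA3TO1[toupper(at$resid)]),
    atom = trimws(at$elety),
    element = ele,
    x = at$x, y = at$y, z = at$z,
    radius = element_radius(ele, radii),
    plddt = as.numeric(at$b)
  )
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]+$", "", basename(path))
  }
  new_protomer(atoms, protein_id, source_format = format)
}

#' Write a protomer model as a PDB file
#'
#' Coordinates are written at the PDB format's 3-decimal precision; pLDDT is
#' stored in the B-factor column.
#'
#' @param model A `protomer`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protomer <- function(model, path) {
  a <- model$atoms
  b <- if ("plddt" %in% names(a)) {
    ifelse(is.na(a$plddt), 0, a$plddt)
  } else {
    rep(0, nrow(a))
  }
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resnum, resid = a$resname, chain = a$chain,
    eleno = seq_len(nrow(a)), elety = a$atom, elesy = a$element,
    o = rep(1, nrow(a)), b = b
  )
  invisible(path)
}

#' Drop low-confidence residues from a model
#'
#' Removes residues whose pLDDT (stored in the B-factor field of
#' AlphaFold-style models) falls below `threshold`; the boundary is
#' inclusive (`plddt >= threshold` is kept).
#'
#' @param model A `protomer` with pLDDT values.
#' @param threshold Confidence threshold (default 50).
#' @return A new `protomer`; the input is not modified.
#' @export
filter_by_plddt <- function(model, threshold = 50) {
  if (!"plddt" %in% names(model$atoms) || all(is.na(model$atoms$plddt))) {
    stop("model has no pLDDT values; cannot filter by confidence")
  }
  atoms <- dplyr::filter(model$atoms, .data$plddt >= threshold)
  if (nrow(atoms) == 0) stop("no residues remain at pLDDT >= ", threshold)
  new_protomer(atoms, model$protein_id, model$source_format)
}

#' Identify ionisable sites in a protomer
#'
#' One site per D/E/K/R/H residue always; C and Y sites when
#' `include_cys_tyr`; one N-terminal and one C-terminal site per chain when
#' `include_termini`. Only D/E/K/R/H sites are assessed for buried charge of
#' interest downstream (`assessed` column); other groups still participate
#' in the electrostatic calculations.
#'
#' @param model A `protomer`.
#' @param include_termini Add chain-terminal amine/carboxylate sites
#'   (default FALSE: most native N-termini are chemically modified).
#' @param include_cys_tyr Treat Cys/Tyr side chains as titratable.
#' @param model_pkas Named model-compound pKas.
#' @return Tibble with one row per site: `site_id`, `chain`, `resnum`,
#'   `group`, `gamma`, `model_pka`, `assessed`, and `moiety_idx` (list
#'   column of row indices into `model$atoms`).
#' @export
extract_ionizable_sites <- function(model, include_termini = FALSE,
                                    include_cys_tyr = TRUE,
                                    model_pkas = default_model_pkas()) {
  res <- protomer_residues(model)
  if (nrow(res) == 0) stop("empty model")
  side_groups <- c(DEKRH, if (include_cys_tyr) c("CYS", "TYR"))
  cand <- res |>
    dplyr::filter(.data$resname %in% side_groups) |>
    dplyr::mutate(group = .data$resname)
  if (include_termini) {
    nt <- res |>
      dplyr::group_by(.data$chain) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::mutate(group = "NTERM")
    ct <- res |>
      dplyr::group_by(.data$chain) |>
      dplyr::slice(dplyr::n()) |>
      dplyr::ungroup() |>
      dplyr::mutate(group = "CTERM")
    cand <- dplyr::bind_rows(cand, nt, ct)
  }
  if (nrow(cand) == 0) {
    return(tibble::tibble(
      site_id = character(), chain = character(), resnum = integer(),
      group = character(), gamma = numeric(), model_pka = numeric(),
      assessed = logical(), moiety_idx = list()
    ))
  }
  rows <- purrr::pmap(
    list(cand$chain, cand$resnum, cand$group),
    function(ch, rn, grp) {
      wanted <- MOIETY_ATOMS[[grp]]
      idx <- which(model$atoms$chain == ch & model$atoms$resnum == rn &
                     model$atoms$atom %in% wanted)
      if (length(idx) == 0) {
        warning(sprintf("site %s:%d (%s) lacks all moiety atoms; skipped",
                        ch, rn, grp), call. = FALSE)
        return(NULL)
      }
      tibble::tibble(
        site_id = sprintf("%s:%s:%d:%s", model$protein_id, ch, rn, grp),
        chain = ch, resnum = rn, group = grp,
        gamma = unname(GROUP_GAMMA[grp]),
        model_pka = unname(model_pkas[grp]),
        assessed = grp %in% DEKRH,
        moiety_idx = list(idx)
      )
    }
  )
  dplyr::bind_rows(purrr::compact(rows)) |>
    dplyr::arrange(.data$chain, .data$resnum, .data$group)
}

#' Write a site table as TSV
#'
#' @param sites Site tibble with `moiety_sasa` (see [add_moiety_sasa()]).
#' @param model The source `protomer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, model, path) {
  out <- sites |>
    dplyr::transmute(
      protein_id = model$protein_id, chain = .data$chain,
      resnum = .data$resnum, group = .data$group, gamma = .data$gamma,
      model_pka = .data$model_pka, moiety_sasa = .data$moiety_sasa
    )
  readr::write_tsv(out, path)
  invisible(path)
}
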