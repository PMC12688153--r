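# Physical constants and tunable model parameters.

# Gas constant, kJ/(mol K)
R_GAS <- 8.31446e-3
# Coulomb constant in kJ A / mol (e^2 / (4 pi eps0), molar)
K_COULOMB <- 1389.35

#' Convert an energy in kJ/mol to pKa units
#'
#' A coupling of `ln(10)*R*T` kJ/mol shifts a pKa by one unit; at 300 K a
#' 2-unit shift corresponds to 11.5 kJ/mol, the default coupling threshold
#' used to define strongly coupled charge pairs.
#'
#' @param energy Energy in kJ/mol.
#' @param temperature Temperature in K.
#' @return Energy expressed in pKa units.
#' @export
#' @examples
#' energy_to_pka_units(11.5) # ~2
energy_to_pka_units <- function(energy, temperature = 300) {
  energy / (log(10) * R_GAS * temperature)
}

#' @rdname energy_to_pka_units
#' @param delta_pka Shift in pKa units.
#' @export
pka_units_to_energy <- function(delta_pka, temperature = 300) {
  delta_pka * log(10) * R_GAS * temperature
}

# One <-> three letter residue codes for the types handled here
AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

# Charged/titratable moiety atoms per group: the atom set whose summed SASA
# is thresholded, chosen so burial reflects desolvation of the charge itself.
MOIETY_ATOMS <- list(
  ASP   = c("CG", "OD1", "OD2"),
  GLU   = c("CD", "OE1", "OE2"),
  LYS   = "NZ",
  ARG   = c("CZ", "NE", "NH1", "NH2"),
  HIS   = c("CG", "ND1", "CD2", "CE1", "NE2"),
  CYS   = "SG",
  TYR   = "OH",
  NTERM = "N",
  CTERM = c("C", "O", "OXT")
)

# Ionisation sign: -1 acids (ionised form is deprotonated, negative),
# +1 bases (ionised form is protonated, positive).
GROUP_GAMMA <- c(
  ASP = -1, GLU = -1, CYS = -1, TYR = -1, CTERM = -1,
  LYS = +1, ARG = +1, HIS = +1, NTERM = +1
)

# Groups assessed for buried charge of interest (BCOI); C, Y and termini are
# carried through the calculations but never reported.
DEKRH <- c("ASP", "GLU", "LYS", "ARG", "HIS")

#' Default model-compound pKa values
#'
#' Histidine is fixed at 6.3 (non-perturbed imidazole); the rest are standard
#' model-compound values and can be overridden.
#'
#' @return Named numeric vector keyed by group label.
#' @export
default_model_pkas <- function() {
  c(
    ASP = 4.0, GLU = 4.4, LYS = 10.4, ARG = 12.0, HIS = 6.3,
    CYS = 8.7, TYR = 9.6, NTERM = 8.0, CTERM = 3.6
  )
}

#' Default element radii (Angstrom) for SASA calculations
#'
#' @return Named numeric vector keyed by element symbol; unlisted elements
#'   fall back to the carbon radius.
#' @export
default_radii <- function() {
  c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
}

#' Engine parameters for the charge-burial pipeline
#'
#' Bundles every tunable of the continuum/titration engines. Defaults are the
#' calibration used throughout the package: `eps_min`/`eps_max` bracket the
#' effective dielectric between buried (protein-like) and exposed
#' (water-like) pairs; `b_desolv` scales the desolvation penalty of a fully
#' buried charge; `coupling_threshold` is the strong-coupling cut
#' (11.5 kJ/mol, i.e. a 2-unit pKa shift at 300 K).
#'
#' @param temperature Temperature, K.
#' @param eps_min,eps_max Effective dielectric bounds for fully buried /
#'   fully exposed site pairs.
#' @param dist_cutoff Pairwise interaction distance cutoff, Angstrom.
#' @param b_desolv Desolvation penalty scale B (kJ/mol) applied as
#'   `B * (1 - f)^2` for exposure fraction f.
#' @param coupling_threshold Strong-coupling threshold on |W|, kJ/mol.
#' @param probe_radius Solvent probe radius, Angstrom.
#' @param n_sphere_points Shrake-Rupley sphere points per atom.
#' @param dh_sasa_min Moiety SASA (A^2) a rotamer must reach for a site to
#'   count as able to sample the water-dominated (Debye-Hueckel) scheme.
#' @param clash_dist Heavy-atom clash distance (Angstrom) used to discard
#'   rotamers.
#' @param ph_grid pH grid for titration curves.
#' @param dq_ph pH at which protonation differences (delta Q) are evaluated.
#' @param plddt_min Per-residue confidence threshold; residues below it are
#'   removed before analysis when confidence values are present.
#' @param mc_sweeps,mc_burnin_frac Monte Carlo sweeps and burn-in fraction.
#' @param enumerate_max Largest site count titrated by exact enumeration;
#'   larger systems use Monte Carlo.
#' @param include_termini,include_cys_tyr Site-extraction switches.
#' @param model_pkas Named model-compound pKas (see [default_model_pkas()]).
#' @param radii Named element radii (see [default_radii()]).
#' @return A list with class `"bc_params"`.
#' @export
bc_params <- function(temperature = 300,
                      eps_min = 10, eps_max = 80,
                      dist_cutoff = 12,
                      b_desolv = 12,
                      coupling_threshold = 11.5,
                      probe_radius = 1.4,
                      n_sphere_points = 960,
                      dh_sasa_min = 15,
                      clash_dist = 2.4,
                      ph_grid = seq(0, 14, by = 0.25),
                      dq_ph = 7.0,
                      plddt_min = 50,
                      mc_sweeps = 20000,
                      mc_burnin_frac = 0.2,
                      enumerate_max = 14,
                      include_termini = FALSE,
                      include_cys_tyr = TRUE,
                      model_pkas = default_model_pkas(),
                      radii = default_radii()) {
  stopifnot(eps_min > 0, eps_max >= eps_min, coupling_threshold > 0,
            temperature > 0, b_desolv >= 0)
  structure(
    list(
      temperature = temperature, eps_min = eps_min, eps_max = eps_max,
      dist_cutoff = dist_cutoff, b_desolv = b_desolv,
      coupling_threshold = coupling_threshold, probe_radius = probe_radius,
      n_sphere_points = n_sphere_points, dh_sasa_min = dh_sasa_min,
      clash_dist = clash_dist, ph_grid = ph_grid, dq_ph = dq_ph,
      plddt_min = plddt_min, mc_sweeps = mc_sweeps,
      mc_burnin_frac = mc_burnin_frac, enumerate_max = enumerate_max,
      include_termini = include_termini, include_cys_tyr = include_cys_tyr,
      model_pkas = model_pkas, radii = radii
    ),
    class = "bc_params"
  )
}

# ln(10) R T, the kJ/mol per pKa unit conversion
kln10rt <- function(temperature = 300) log(10) * R_GAS * temperature
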