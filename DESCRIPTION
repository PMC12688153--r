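Package: buriedcharge
Title: Buried Ionisable Charge and pH-Dependence Prediction from Protein
    Protomer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts buried charges of interest (BCOI) in single-chain
    protein structure models: identifies ionisable sites, computes
    solvent-accessible surface area (Shrake-Rupley), estimates pairwise
    electrostatic couplings and desolvation shifts with a simplified
    continuum model, derives apparent pKa values and protonation
    differences by exact enumeration or Metropolis Monte Carlo titration,
    extracts strongly coupled buried charge networks, and applies a
    canonical set of ten burial-conditioned filters. Downstream tooling
    covers enrichment ratios against protein label sets, ROC scans,
    filter-overlap statistics, gene-ontology fold enrichment with
    hierarchy propagation, a benchmark scorer for literature pH-sensor
    residues, and synthetic-structure and synthetic-cohort generators so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
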