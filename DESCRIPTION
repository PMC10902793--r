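Package: cgmab
Title: Coarse-Grained Monte Carlo Models of Monoclonal Antibody Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-scale coarse-grained Monte Carlo toolkit for concentrated
    protein (monoclonal antibody) solutions. Builds amino-acid-level and
    Y-shaped N-bead representations from PDB structures, runs constant-pH
    Metropolis Monte Carlo titration to estimate net charges, performs
    rigid-body many-protein Monte Carlo with screened-Coulomb plus
    Lennard-Jones (or hard-sphere Yukawa) pair potentials and Hamiltonian
    replica exchange over the attraction strength, computes effective
    structure factors S_eff(q) on crystallographic q-grids, and fits
    (Q_eff, eps_ij) against small-angle X-ray scattering curves by
    chi-squared grid scans. Includes a synthetic toy-antibody generator and
    synthetic SAXS targets with known ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
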