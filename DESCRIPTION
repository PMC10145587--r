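Package: quadbind
Title: Absolute Ligand-G-Quadruplex Binding Free Energies from Restraint-Based PMF Protocols
Version: 0.1.0
Authors@R:
    person("quadbind", "developers", email = "quadbind@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for absolute binding free energies of
    ligand-G-quadruplex (and other receptor-ligand) complexes computed with
    a restraint-based potential-of-mean-force protocol. Provides Bennett
    acceptance ratio (BAR) estimation of restraint switching free energies
    over a lambda schedule, weighted histogram analysis (WHAM) reconstruction
    of the dissociation PMF from umbrella-sampling windows with plateau
    detection and block-split error estimates, Boresch-style six-degree-of-
    freedom orientational restraints with the analytic standard-state bulk
    correction, RMSF-based restraint-atom selection on superposed structural
    ensembles, geometric hydrogen-bond and arm-in-groove contact metrics,
    free-energy assembly with error propagation and affinity conversion, and
    a Metropolis Monte Carlo toy sampler that generates Boltzmann-distributed
    synthetic datasets with known ground truth so every estimator is testable
    without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
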