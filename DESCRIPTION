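Package: alsdyn
Title: Adaptive Lambda-Square Dynamics for Coarse-Grained Histone
    Tail-DNA Ensembles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Expanded-ensemble enhanced sampling and ensemble analysis for
    intrinsically disordered histone tails interacting with DNA.  Implements
    adaptive lambda-square dynamics (ALSD): a dynamical scaling variable
    lambda multiplies the tail's internal energy by lambda^2 and the
    tail-environment coupling by lambda, an adaptive umbrella bias
    RT ln P(lambda, T) flattens the lambda marginal, and importance
    reweighting reconstructs the canonical ensemble at lambda = 1.  Ships a
    coarse-grained polyelectrolyte model of a cationic tail tethered to an
    anionic DNA-like scaffold (Debye-Hueckel electrostatics, WCA excluded
    volume), a seeded Langevin (BAOAB) integrator for coordinates and lambda
    jointly, trivial-trajectory-parallelization (TTP) run orchestration, and
    the ensemble statistics used for such systems: Shrake-Rupley solvent
    accessible surface area and tail-DNA contact surface area (CSA), radius
    of gyration, per-position contact probabilities, terminal-atom contact
    and exposure ratios, Kabsch superposition, 3D occupancy and difference
    grids, backbone dihedrals with a dihedral-window helix assignment, and
    site-site distance distributions, applicable to both the coarse-grained
    ensembles and all-atom PDB structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
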