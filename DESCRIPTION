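Package: polybundle
Title: Coarse-Grained Dynamics of Semi-Flexible Polymer Bundles and Fiber Networks
Version: 0.1.0
Authors@R:
    person("Morgan", "Velasco", email = "mvelasco@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of bead-spring semi-flexible polymers
    with attractive lateral interactions: force-shifted Lennard-Jones,
    FENE and angular potentials with cell-list acceleration, velocity
    Verlet integration under Nose-Hoover or Langevin thermostats, linear
    temperature-quench protocols, persistence-length estimation by
    end-to-end projection with crossover and quasi-harmonic fits, bundle
    melting-point detection from cohesive-energy derivative peaks, and
    morphology statistics (chains per fiber, bundle diameter) of quenched
    fiber networks. Trajectories read and write extended XYZ and LAMMPS
    dump formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
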