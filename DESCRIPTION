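Package: polyloopsim
Title: Coupled Loop-Extrusion and Polymer Simulations of Chromosome Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the interplay between loop-extruding SMC complexes
    (cohesin/condensin) and a coarse-grained chromatin fiber. A continuous-time
    (Gillespie) engine propagates loop extruder binding, unbinding, leg
    translocation, directional boundary stalling and inter-extruder collisions
    on a one-dimensional monomer lattice; a Metropolis Monte-Carlo engine
    propagates the three-dimensional bead-spring chain with chain connectivity,
    excluded volume, bending rigidity and extruder-imposed loop bonds. From
    sampled conformations the package derives virtual Hi-C contact maps
    (with a cooler-format converter), virtual ChIP-seq occupancy tracks
    (bedGraph), three-way contact statistics, contact-probability curves, a
    chi-squared comparison score against reference maps, and parameter-grid
    sweeps with heat-map summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml,
    jsonlite,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
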