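Package: torsim
Title: Biophysical Simulation of State-Dependent Firing in CCK+ Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based (Hodgkin-Huxley) modelling of cholecystokinin-
    expressing hippocampal interneurons whose firing phenotype - transient
    outward rectifier (TOR) versus regular spiking (RS) - is set by two
    variants of the subthreshold-activated A-type potassium current (I_SA).
    Provides reduced compartmental cable models with an implicit integrator,
    simulated voltage-clamp and current-clamp protocols (steady-state
    inactivation, recovery from inactivation, activation, membrane-potential
    dependence of firing), Boltzmann and exponential curve fitting of the
    resulting traces, oscillatory synaptic drive with seeded event trains,
    and paired-simulation analysis of band-selective silencing when the RS
    current variant is exchanged for the TOR mixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
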