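Package: purkinje
Title: Multicompartmental Conductance-Based Simulation of Cerebellar Purkinje Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained multicompartmental model of the cerebellar
    Purkinje cell: a branched passive cable with an explicit axon (initial
    segment, paraAIS, myelinated internodes, nodes of Ranvier and a
    collateral), a surrogate dendritic tree calibrated to published passive
    aggregates, fifteen voltage- and calcium-dependent ionic channel models
    (Hodgkin-Huxley gates and Markov schemes, including a thirteen-state
    resurgent Nav1.6), submembrane calcium shells with diffusible buffers and
    an extrusion pump, and a fixed-step implicit integrator over the branched
    tree.  Standard Purkinje-cell experiments (pacemaking, F/I curves,
    complex bursting, axonal transmission, bistability, channel knockouts,
    firing variants and conductance robustness scans) are provided as named,
    scriptable protocols together with spike-train and burst analysis tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Depends: R (>= 4.0)
SystemRequirements: C++17
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
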