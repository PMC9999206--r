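Package: dropsort
Title: Simulation and Evaluation of Impedance-Activated Droplet Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and evaluate label-free sorting of
    cell-encapsulating droplets by electrical impedance screening and
    acoustic actuation. Provides Poisson encapsulation statistics and
    ground-truth droplet stream generation, a single-shell cell dielectric
    model with a 2D complex-conductivity field solver for coplanar
    electrodes, partial-wave acoustic radiation force factors for droplets
    and cells, synthetic differential impedance traces, event detection and
    amplitude gating with trigger timing, and sorting performance metrics
    (purity, recovery, enrichment, throughput).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
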