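Package: mmpdyn
Title: Dynamic Modelling of Mitochondrial Membrane Potential Under
    OXPHOS Inhibition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Kinetic ODE models of mitochondrial membrane potential (MMP)
    dynamics in cells exposed to oxidative-phosphorylation inhibitors
    (electron transport chain inhibitors, ATP synthase inhibitors and
    uncouplers), observed through an MMP-sensitive dye in live-cell
    imaging. Provides four model variants (a basic two-state
    oxygen/MMP model, pharmacokinetic compound decay, decay plus ion
    leakage, and concentration-dependent decay), analytic steady
    states, compiled integration with forward sensitivity equations,
    preprocessing of single-cell intensity tables (geometric means,
    vehicle-control normalisation, replicate aggregation), multi-start
    maximum-likelihood calibration with analytic Jacobians, joint
    fitting with shared parameters across compounds, profile-likelihood
    and hierarchical (inter/intra-plate) bootstrap confidence
    intervals, pharmacokinetic ratio predictions, and a seeded
    synthetic-data generator emulating the imaging study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
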