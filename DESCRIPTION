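Package: rejuvasim
Title: Replicative Ageing, Damage Segregation and Rejuvenation in Yeast Cell Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulator of replicative ageing in budding yeast.
    Single cells accumulate and repair damaged proteins under a nonlinear ODE
    with a saturating or declining repair-capacity term, divide asymmetrically
    with damage retention, and recursively found a pedigree in which per-cell
    ageing metrics (replicative lifespan, rejuvenation index, health span,
    generation times, growth per cycle) and population metrics are computed.
    Includes log-normal mixed-effects cell-to-cell variability, bisection
    calibration of the wildtype parameter grid against a target lifespan,
    lineage export to delimited tables and Newick trees, and scripted drivers
    for retention sweeps, growth-rate, stress and variability experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
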