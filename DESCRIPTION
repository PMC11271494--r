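Package: mtdimer
Title: Mechanics and Kinetics of Multi-Domain Protein Dimers Under Force
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for single-molecule magnetic-tweezers
    experiments on multi-domain protein dimers such as alpha-actinin rod
    dimers. Predicts force-dependent transition step sizes from polymer
    mechanics (single-segment freely-jointed-chain rigid bodies and
    Marko-Siggia worm-like chains), infers force-dependent lifetimes from
    dwell-time tables by censored-exponential and bootstrap estimation with
    Bell slip-bond fitting, detects step transitions in bead-height traces
    by change-point and hidden-Markov fitting, and simulates multivalent
    dimer rupture kinetics (boundary un-pairing, re-pairing gated by domain
    unfolding) with a Gillespie engine under constant-force and force-ramp
    protocols. Includes a synthetic-data generator emulating the
    experimental protocols so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    mclust,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
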