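Package: radnc
Title: Decay-Chain Kinetics, PBPK Modelling and Nanoshell Dosimetry for
    Radium-223 Labeled Gold Nanoclusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for radium-223 based nanocluster
    theranostics. Provides a Bateman solver and activity accounting for the
    Ra-223 decay chain, two-compartment intravenous-bolus blood
    pharmacokinetic fitting, an eight-compartment membrane-limited
    physiologically based pharmacokinetic (PBPK) model with virtual-mouse
    population prediction intervals and mean-fold-error validation, a
    stochastic continuous-slowing-down dosimetry simulator for the full
    decay chain in nested source/shell/water-phantom geometries, cluster
    energetics bookkeeping (formation, relative and binding energies,
    HOMO-LUMO gaps), and synthetic-data generators that emulate blood
    sampling schedules and organ biodistribution measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
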