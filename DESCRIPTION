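Package: lineagerates
Title: Birth-Death Diversification Rates for Lineages from Range and
    Occurrence Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates origination, extinction, and preservation rates of
    lineages through time from either range data (known first/last times of
    existence) or occurrence data (dated finds, optionally with radiocarbon
    calibration uncertainty). Rate variation is modeled with a
    piecewise-constant birth-death process whose number and placement of
    rate shifts are sampled by reversible-jump MCMC; per-bin Bayes factors
    identify strongly supported shifts. Preservation of occurrences is
    modeled as a Poisson process (homogeneous, lifespan-bell-shaped, or
    epoch-piecewise), with optional gamma rate heterogeneity across
    lineages, maximum-likelihood fitting, and AICc model selection.
    Includes radiocarbon calibration against IntCal-format curves with
    weighted resampling into replicate datasets, forward simulators for all
    models, and posterior summaries of rates through time.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
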