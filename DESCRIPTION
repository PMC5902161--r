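Package: synapsim
Title: Symmetric DSB Simulation and Meiotic Asynapsis Modelling in Hybrid Mice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying meiotic chromosome asynapsis in
    intersubspecific mouse hybrids. Provides a Monte-Carlo simulator (with an
    exact analytic counterpart) of the per-chromosome distribution of DNA
    double-strand breaks falling in symmetric PRDM9 hotspots, inference of the
    minimal number of symmetric breaks sufficient for synapsis, segmented
    (change-point) regression of asynapsis rate on the length of consubspecific
    sequence, random-intercept logistic models of per-animal asynapsis counts,
    likelihood-ratio binomial confidence intervals, multiplicative full-synapsis
    expectations with fertility summaries and trans-effect regression, plus a
    synthetic-data generator that emulates the cytological scoring tables such
    studies produce.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4
Config/testthat/edition: 3
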