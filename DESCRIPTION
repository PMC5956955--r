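Package: tipclock
Title: Substitution-Rate Estimation and Temporal-Signal Diagnostics for
    Tip-Dated Sequence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for molecular-clock calibration
    from heterochronous (time-structured) sequence data, such as ancient-DNA
    data sets that mix modern and radiocarbon-dated samples. Simulates
    constant-size serial-coalescent genealogies with configurable
    phylo-temporal clustering and a fixed root age, assigns branch rates
    under a white-noise relaxed clock, and evolves nucleotide alignments
    under HKY+Gamma. Re-implements two fast substitution-rate estimators --
    root-to-tip regression with optimal root placement and strict-clock
    least-squares dating with temporal-precedence constraints -- together
    with temporal-signal diagnostics (date-randomization test with CR1/CR2
    criteria, phylo-temporal clustering permutation test, stemminess) and an
    evaluation layer of standardized errors and their rank-based hypothesis
    tests across a factorial grid of simulation scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    phytools,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
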