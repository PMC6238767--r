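Package: fractalsad
Title: Fractal and Zipf Rank-Abundance Models for Community Ecology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fitting the one-parameter fractal (Zipf-type) model of
    the species abundance distribution, A_r/A_1 = r^-p, to ranked community
    abundance data. Provides the closed-form least-squares estimator of the
    exponent p on log-transformed rank and relative abundance, goodness of
    fit on the log scale, generalized harmonic sums and Riemann zeta limits
    linking the model to effective species numbers (Hill numbers of order
    infinity) and Renyi entropy, seeded synthetic community generators
    (exact power law, multinomial sampling, stepwise fractal accumulation)
    for parameter-recovery validation, readers and writers for long-format
    abundance tables, and a batch survey layer that fits many samples and
    summarizes the frequency distribution of p across datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
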