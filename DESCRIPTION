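Package: aldasplit
Title: Dichotomization of the Alda Lithium-Response Score Under Asymmetric Reliability
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying when a dichotomized ("tail-split")
    representation of an asymmetrically reliable ordinal scale carries more
    usable information than the raw scale, motivated by the 0-10 Alda score
    of lithium responsiveness in bipolar disorder. Implements the
    combinatorics of the scale's item structure, a Dirichlet-multinomial
    model of inter-rater agreement with closed-form MAP smoothing, mutual
    information of raw versus dichotomized score representations as a
    function of prior observation noise (with crossover detection), a
    seeded synthetic-data generator with tunable background noise and
    heteroscedastic (logistic) diagonal spread, kernel-density and 2x2
    histogram mutual-information estimators, and analytic power for the
    Pearson correlation test (Fisher Z) and Fisher's exact test (via the
    noncentral hypergeometric distribution).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
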