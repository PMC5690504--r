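Package: respmark
Title: Optimal External-Marker Placement for Radiotherapy Patient Setup
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ranking candidate skin-marker sites used as respiratory
    surrogates in external beam radiotherapy. Simulates time-synchronized
    external marker and internal reference motion traces for a thoracic
    nine-site layout, scores each site against the internal reference with
    canonical correlation analysis (CCA) and principal component analysis
    (PCA), selects marker subsets by a high-correlation / low-variability
    rule, maps the selected surrogate signals to the internal trajectory with
    an adaptive neuro-fuzzy inference system (Sugeno rules, fuzzy c-means
    initialization, hybrid least-squares/gradient training), and ranks
    thoracic regions by the root-mean-square error of the resulting setup
    prediction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
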