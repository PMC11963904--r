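Package: odcdisc
Title: Model Discrepancy Correction for the Siggaard-Andersen Oxygen
    Dissociation Curve
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying and correcting model discrepancy in the
    Siggaard-Andersen model of the oxygen-haemoglobin dissociation curve
    (ODC). Implements the mechanistic ODC forward model with its displacement
    terms, an additive Gaussian-process discrepancy model with value and
    derivative constraints at the extremes of the partial-pressure range, a
    grey-box hybrid in which a dense neural network replaces the unknown
    2,3-DPG displacement term and is trained end-to-end through the
    mechanistic model, and genetic-programming symbolic regression that
    distils the trained network into an interpretable closed-form
    expression. A synthetic-data generator reproduces the ground-truth
    recovery study used to validate the three approaches, and evaluation
    helpers provide cross-validation splits, absolute-error summaries in
    oxygen-saturation percentage points, and per-patient ODC curve bundles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
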