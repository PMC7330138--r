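Package: mdisten
Title: Modified-Distribution Entropy and Related Complexity Measures for
    EEG Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimators of time-series complexity for single-channel
    electroencephalogram (EEG) records: fuzzy entropy, distribution entropy,
    and a modified-distribution entropy that combines the distance-histogram
    approach of distribution entropy with the (r, n) similarity scaling of
    fuzzy entropy. Includes delay-coordinate state-space embedding,
    Chebyshev and Euclidean inter-vector distance matrices, empirical
    probability density estimation by histogram binning, and an evaluation
    pipeline for epileptic-seizure discrimination: prefix windowing,
    rank-based AUC over window-length sweeps, leave-one-set-out five-fold
    cross-validation with a threshold classifier, and confusion-matrix
    metrics. A seeded surrogate generator produces Bonn-style five-set EEG
    datasets (normal, interictal, ictal) so the whole pipeline runs without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
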