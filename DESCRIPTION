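Package: knnmetrics
Title: Distance-Measure Benchmarking for k-Nearest-Neighbor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking distance measures in k-nearest-neighbor
    classification of biomedical (e.g. cancer) data. Provides twelve distance
    functions, including a Sobolev distance computed through the discrete
    Fourier transform and a Fisher information geodesic on the probability
    simplex, a metric-pluggable kNN classifier with precision, recall, F1 and
    accuracy scoring, best-over-k final scores, tie-aware rankings with
    average-rank and cross-entropy Monte Carlo (Kendall distance) consensus
    aggregation, and k-means clustering of metric performance profiles.
    Synthetic dataset generators emulate common cancer data-set shapes so the
    whole benchmark runs end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    jsonlite
Config/testthat/edition: 3
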