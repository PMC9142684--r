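Package: scoutr
Title: Single-Cell Spatiotemporal Longitudinal Tracking for Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tracks individual neurons across multiple calcium-imaging
    sessions by combining spatial similarity metrics (centroid distance,
    footprint overlap, Jensen-Shannon divergence) with temporal metrics
    (signal-to-noise ratio, fluorescence decay rate, and a link-session
    correlation metric), converting per-metric similarities into
    identification probabilities via percentile, Gaussian-mixture, or
    soft k-means models, and clustering the aggregated similarity graph
    with a session-constrained switch/swap algorithm under
    weight-perturbation consensus. Includes a synthetic-recording
    generator with ground truth, register evaluation metrics (discovery
    and false-discovery rates, F1, Jaccard, cluster-size divergence),
    and linear-track place-field analysis with spatial information
    scores and shuffle percentiles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    data.table,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    tiff
Config/testthat/edition: 3
RoxygenNote: 7.3.3
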