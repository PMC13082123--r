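Package: gliowave
Title: Calcium Co-Activity Network Inference for Glioma Cell Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers functional communication networks from single-cell calcium
    imaging of glioma cultures and slices. Fluorescence traces are normalized
    to dF/F, calcium peaks are detected with a prominence rule, and every pair
    of active cells is scored by the maximum time-lagged Pearson correlation
    (connectivity strength). Pairs are gated by intercellular distance,
    implied propagation speed and activity, and significance is assessed
    against a linear-shift surrogate null model that preserves per-trace
    autocorrelation. The resulting undirected graphs yield communicating-cell
    percentages, degree hubs and periodic (rhythmic) cells. A synthetic
    recording generator with known coupling graphs, propagation delays and
    GCaMP-like transient kinetics supports end-to-end validation, and plate
    Z-scoring utilities cover triple-readout RNAi screens and simple
    morphometric gates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
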