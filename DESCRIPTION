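Package: miniact
Title: Quantitative Analysis of Miniscope Calcium-Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Downstream quantitative analysis of one-photon miniscope
    calcium-imaging recordings after CNMF-style trace extraction.
    Segments per-neuron fluorescence traces into active and inactive
    states with an adaptive derivative threshold (median plus mean
    absolute deviation), computes single-neuron and network activity
    metrics (burst rate, network spike rate, peak and duration),
    pairwise co-activity statistics (Pearson correlation in five modes
    with optional lag, network degree, connectivity, percentile
    clustering, transfer entropy), spatial distance statistics,
    count-preserving activity shuffling for surrogate null models, and
    a PCA embedding of per-recording metric profiles. Reads zarr-style
    labeled-array stores and plain CSV tables; exports spreadsheet and
    CSV reports. Includes a synthetic recording generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    jsonlite,
    yaml,
    xml2,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
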