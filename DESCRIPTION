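Package: calcitrack
Title: Longitudinal Analysis of Awake Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for longitudinal single-cell analysis of awake two-photon
    calcium imaging recordings: neuropil compensation, fluorescence trace
    conditioning (low-pass, percentile detrending, F0 and noise-band
    estimation), calcium-transient detection and activity categorisation,
    cross-session activity dynamics (similarity with shuffle null, category
    transitions, reoccurrence, recruitment of novel highly active neurons),
    pairwise synchrony of binarized activity with circular-shift controls and
    behavioural-epoch restriction, and anisotropic 3D neuron-to-amyloid-plaque
    distance analysis. Includes a synthetic-data generator with full ground
    truth so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    signal,
    data.table,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
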