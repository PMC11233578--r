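Package: stimresp
Title: Stimulus-Evoked Response Analysis for Calcium Imaging and Slice Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for stimulus-aligned two-photon calcium imaging
    and whole-cell patch-clamp data from cortical circuits. Converts extracted
    ROI fluorescence to dF/F0 with a running-percentile slow baseline, labels
    stimulus-responsive neurons with a circular-shift bootstrap, discovers
    stimulus-activated and -inactivated ensembles by PCA and k-means with
    silhouette-based model selection, extracts intrinsic electrophysiology
    features (input resistance, membrane time constant, sag ratio, action
    potential threshold and afterhyperpolarization metrics) with layer-1
    interneuron classification, isolates feedforward inhibitory postsynaptic
    currents by initial-slope scaled subtraction, and orchestrates the
    accompanying nonparametric statistics. Includes forward-model simulators
    for all three data modalities with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    cluster,
    data.table,
    jsonlite,
    mclust,
    pracma,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
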