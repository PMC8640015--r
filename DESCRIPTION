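Package: toxelhmm
Title: Temporal Refinement of 4D Segmentation Labels with Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines 4D (time-series of 3D) semantic segmentation label volumes
    produced by applying a per-timepoint 3D segmenter, by decoding each spatial
    site's label sequence through time with a hidden Markov model. Two model
    families are provided: HMM-T, whose observables are the predicted classes,
    and HMM-TC, whose observables additionally encode the segmenter's
    leading-class confidence quantized into bins. Transition matrices encode
    expected physical behaviour (e.g. irreversible dissolution of one phase
    into another), emission matrices are derived from a segmenter's testing
    confusion matrix, and decoding uses the Viterbi algorithm with a
    constant-observation shortcut. Includes naive-transition and temporal
    median-filter baselines, per-class and mean intersection-over-union
    evaluation, confusion-matrix tallying (square and confidence-binned
    rectangular), a synthetic 4D phantom generator with known hidden truth for
    end-to-end testing, TIFF/CSV/JSON input-output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
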