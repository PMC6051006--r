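Package: eegsubband
Title: EEG Subband Energies, Denoising and Encephalopathy Screening
Version: 0.1.0
Authors@R:
    person("EEG Subband", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for screening diffuse encephalopathy from scalp EEG epochs:
    combined low-pass-filter / total-variation denoising solved by
    majorization-minimization, six-level Daubechies-4 discrete wavelet
    decomposition into the clinical delta/theta/alpha/beta subbands, relative
    subband-energy features, Welch two-sample t screening (including from
    printed summary statistics), and linear support-vector-machine
    classification with sensitivity/specificity/accuracy reporting. Includes a
    synthetic band-structured EEG cohort generator emulating published group
    statistics so the full pipeline is testable without patient data, plus
    EDF and delimited-text epoch I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
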