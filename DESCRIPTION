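Package: spinecorr
Title: Resting-State Functional Connectivity Analysis of the Cervical Spinal Cord
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing resting-state functional MRI of the cervical
    spinal cord: a synthetic "butterfly" cord phantom with planted inter-horn
    connectivity and realistic physiological confounds; slice-wise denoising
    (not-spine and CSF principal-component nuisance regression, RETROICOR
    cardiac/respiratory correction, white-matter eigenvector regression);
    weighted slice-wise in-plane motion correction; zero-phase Chebyshev
    Type II band-pass filtering; Fisher r-to-z connectivity with
    autocorrelation-corrected degrees of freedom, seed maps with
    cluster-extent thresholds, per-slice region-of-interest connectivity
    matrices; and nonparametric group inference (exact Wilcoxon signed-rank
    tests with Bonferroni correction and box-whisker summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
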