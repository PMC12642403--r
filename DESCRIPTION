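Package: speechtrf
Title: Temporal Response Functions for Prediction Signatures in Continuous Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates multivariate temporal response functions (mTRFs) from
    continuous multi-channel neural responses to speech, using boosting
    (steepest l1 coordinate descent with validation-based early stopping and
    per-predictor freezing) on a basis of Hamming windows. Builds linguistic
    predictor time series from time-aligned phoneme/word event tables:
    phoneme surprisal and entropy under sublexical (phoneme n-gram), lexical
    (cohort model with frequency prior), and sentence (cohort model with
    word n-gram prior) context models, plus acoustic gammatone envelope and
    onset bands and word/phoneme onset impulses. Quantifies the unique
    contribution of each predictor by cross-validated full-versus-reduced
    model comparison, and provides the group-level statistical layer:
    Gaussian-smoothed mass-univariate t-tests with threshold-free cluster
    enhancement (TFCE) and sign-flip permutation, hemispheric lateralization
    indices and paired tests, region-of-interest summaries, group
    regressions and pairwise t-tests, spatiotemporal cluster permutation
    tests on response functions, and peak analysis. A synthetic-data module
    generates lexicons, corpora, event tables, and source-space responses
    with known ground-truth kernels so that the entire pipeline can be
    validated against simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
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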