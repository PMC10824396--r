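Package: sleepenergy
Title: Energy-Based Post-Processing of Automatically Scored Hypnograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Improves sleep-stage sequences (hypnograms) produced by any
    automatic sleep-staging classifier that emits per-epoch stage
    probabilities. A candidate hypnogram is scored with a nonnegative energy
    built from reciprocal-error terms on the classifier's predicted
    probabilities, a column-normalized confusion matrix, and a row-stochastic
    stage-transition matrix; the energy is minimized by stochastic single-site
    simulated annealing with Boltzmann position selection and Gibbs-style
    stage proposals. Includes estimators for the transition and confusion
    matrices, a Viterbi and a median-filter baseline decoder, a synthetic
    night generator for benchmarking, sequence-labeling evaluation metrics,
    and paired Wilcoxon signed-rank testing with Holm-Bonferroni correction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
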