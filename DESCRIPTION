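Package: repsim
Title: Representational Similarity Analysis with Nonparametric Inference
Version: 0.1.0
Authors@R:
    person("RSA", "Maintainers", email = "maintainers@repsim.org", role = c("aut", "cre"))
Description: Characterizes multichannel activity patterns by representational
    dissimilarity matrices (RDMs), summarizes representational geometry by
    multidimensional scaling and hierarchical clustering, and statistically
    relates brain RDMs to candidate model RDMs. Supports correlation,
    Euclidean, and Mahalanobis pattern dissimilarities, Kendall's tau-a rank
    correlation for tie-predicting models, noise-ceiling estimation,
    signed-rank / stimulus-label randomization / bootstrap inference with
    false-discovery-rate control, searchlight mapping through masked volumes,
    the crossvalidated linear-discriminant t statistic, and a simulation
    suite that generates all inputs (pattern sets, noisy subjects, GLM-style
    fMRI time series) so analyses run without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
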