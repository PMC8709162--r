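Package: degrootfit
Title: Genetic-Algorithm Estimation of DeGroot Opinion-Diffusion Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the DeGroot opinion-diffusion model to ordinal opinion
    panels observed on partially sampled social networks. Influence weights
    are estimated with a genetic algorithm whose chromosome is the
    row-stochastic weight matrix and whose gene is a single row, minimising
    an objective that penalises continuous deviations only when the modeled
    opinion lands in the wrong ordinal bin. Includes forward simulation of
    plain DeGroot dynamics and bounded-confidence and decay extensions,
    generators for ground-truth networks and two-wave snowball samples,
    the correct/build/remove/complete adjacency-matrix varieties for
    unknown links, recovery/modeling/prediction/ordinal-fit RMSE metrics,
    and a factorial simulation-study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
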