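Package: chordwalk
Title: Markov Chain Monte Carlo Sampling on Convex Polytopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sampling of probability densities supported on convex polytopes
    given in half-space representation. Provides polytope preprocessing
    (feasibility certification via Chebyshev centers, redundant-constraint
    removal, null-space embedding of equality systems, rounding), a family of
    interchangeable Hit-and-Run Markov chain proposals behind one minimal
    contract, Metropolis-Hastings filtering, parallel tempering for
    multimodal targets, acceptance-rate tuning, reproducible multi-chain
    execution with checkpointing, and convergence diagnostics (split R-hat,
    autocorrelation-based effective sample size). Includes a command-line
    interface and a synthetic fixture generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
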