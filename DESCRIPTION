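Package: promnoise
Title: Stochastic Kinetics of Promoter Architecture and Gene Expression Noise
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact steady-state moments of mRNA and protein copy number for
    arbitrary multi-state bacterial promoters, computed from the chemical
    master equation by linear matrix equations; full steady-state copy-number
    distributions by null-space solution of the truncated joint generator;
    statistically exact Gillespie simulation of promoter-state, mRNA and
    protein trajectories; and parameterized builders for the canonical
    prokaryotic architectures (simple and dual repression and activation,
    with independent or cooperative operator binding, and repression by DNA
    looping). Includes titration scans, matched-mean architecture
    comparisons, inter-operator distance scans and randomized
    kinetic-parameter robustness studies of the Fano factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
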