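Package: abhumanize
Title: Antibody Humanness Scoring and Greedy Framework Humanization
Version: 0.1.0
Authors@R:
    person("Ab", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the humanness of IMGT-numbered antibody variable-domain
    sequences with per-V-gene random-forest classifiers calibrated by Youden's
    J statistic, and humanizes non-human precursors by greedy single-site
    framework substitution until a target humanness score is reached. Includes
    a synthetic repertoire simulator with region-dependent somatic
    hypermutation for end-to-end testing without large repertoire downloads,
    overlap-ratio and mutation-ratio metrics for comparing suggested and
    experimental humanizing mutations, and a command-line interface covering
    simulation, training, scoring, humanization and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
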