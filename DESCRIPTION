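Package: setoccupancy
Title: Occupancy Times in Sets of States for Markov Chain Demographic Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of the time an individual spends in an arbitrary set of
    states of an absorbing Markov chain demographic model. From a transient
    transition matrix U and a target set B, constructs the killed, conditional,
    and sub-Markov chains and computes the probability distribution, mean,
    variance, and higher moments of the set occupancy time, the probability of
    reaching the set and the distribution of the reaching time, the probability
    of returning to the set and the distribution of the return time, and the
    covariance and correlation between the occupancy times of two sets
    (including longevity). Includes a seeded path simulator for Monte-Carlo
    verification of every analytic quantity, labelled CSV/JSON input/output,
    and the Southern Fulmar worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
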