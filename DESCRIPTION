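Package: crowdwise
Title: Inner- and Outer-Crowd Wisdom Analysis for Numerosity Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates numerosity-estimation experiments with novice and
    trained participants, constructs inner crowds (repeated estimates within
    a person) and outer crowds (first estimates across people), decomposes
    crowd error into bias, mean squared error and variance via the diversity
    prediction theorem, fits the hierarchical parabolic crowd-wisdom model
    MSE_P = a/t + b by MCMC with half-normal priors, and tests the crowd
    wisdom (a) and bias (b) parameters against zero with Savage-Dickey
    density-ratio Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    mgcv,
    coda,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
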