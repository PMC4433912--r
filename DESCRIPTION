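Package: nfnferm
Title: Neuro-Fuzzy Network Modelling of Batch Fermentation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time modelling of batch fermentation state variables
    (cell mass, lactose, dissolved oxygen) with a three-layer neuro-fuzzy
    network: a fixed random sigmoid hidden layer and a piece-wise linear
    output layer trained non-iteratively by a time-weighted fuzzy
    least-squares criterion solved through a rank-revealing normal system.
    Includes a Monod-type batch fermentation simulator used both as a
    synthetic data generator and as the conventional mass-balance baseline,
    hidden-layer size selection by fuzzy degree of satisfaction,
    recursive trajectory simulation, and model-adequacy statistics
    (correlation quotient, experimental Fisher ratio, relative error)
    with theoretical F thresholds for model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
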