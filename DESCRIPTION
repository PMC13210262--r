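Package: pedallo
Title: Simulation-Estimation Studies of Allometric Scaling Exponents in
    Pediatric Monoclonal-Antibody Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for parameter-recovery studies of allometric scaling in
    pediatric population pharmacokinetics. Generates virtual pediatric weight
    populations from LMS (Box-Cox power, median, coefficient of variation)
    growth-chart parameters and virtual adult populations from a truncated
    normal; simulates concentration-time data for a subcutaneously dosed
    monoclonal antibody under a one-compartment allometric population model
    with correlated log-normal inter-individual variability and proportional
    residual error; re-estimates the population parameters, including the
    allometric exponents of apparent volume and clearance, with a first-order
    conditional (with interaction) approximate marginal likelihood; and drives
    design grids over sample size, sampling scheme, age range and adult-data
    pooling, summarizing exponent recovery with quartile, bias and
    distribution-separation statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
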