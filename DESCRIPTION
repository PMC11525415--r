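Package: mspepower
Title: Simulation-Based Power Analysis for Latent Interaction and Quadratic
    Structural Equation Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Model-implied simulation-based power estimation (MSPE) for
    structural equation models with latent interaction and quadratic effects.
    Data are simulated equation by equation from a population model written in
    a lavaan-dialect syntax, fitted by scale regression, factor score
    regression, or the unconstrained product indicator approach, and the
    per-replication significance decisions are modelled by a probit (or logit)
    regression on the square root of the sample size. Inverting the fitted
    power curve yields the required sample size for a target power, with a
    confidence-bound variant that guards against underpowered recommendations.
    Sample sizes for the replications are chosen either on a user-given grid
    or by an adaptive wide-to-narrow search. Includes a closed-form Gaussian
    product-moment engine for variance decompositions and a Monte-Carlo
    harness for evaluating search and estimator performance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    sandwich,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
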