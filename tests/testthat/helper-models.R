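# shared fixtures: small population models built in code

minimal_model <- function() {
  "F =~ 1*y1 \n y1~~0.5*y1 \n F~~1*F"
}

# two correlated exogenous latents, one endogenous, single perfect indicator
perfect_moderation_model <- function(gamma_int = 0.3) {
  paste(
    "Xi1 =~ 1*a1", "Xi2 =~ 1*a2", "Eta1 =~ 1*b1",
    sprintf("Eta1 ~ 0.4*Xi1 + 0.3*Xi2 + %s*Xi1:Xi2", gamma_int),
    "Xi1 ~~ 1*Xi1", "Xi2 ~~ 1*Xi2", "Xi1 ~~ 0.5*Xi2",
    "Eta1 ~~ 0.5*Eta1",
    "a1 ~~ 0*a1", "a2 ~~ 0*a2", "b1 ~~ 0*b1",
    sep = "\n")
}

modmed_spec <- local({
  spec <- NULL
  function() {
    if (is.null(spec)) spec <<- parse_model(moderated_mediation_model())
    spec
  }
})

# artificial decision records drawn straight from a probit power curve
probit_records <- function(beta0, beta1, n_range, R, seed) {
  set.seed(seed)
  n <- sample(n_range[1]:n_range[2], R, replace = TRUE)
  s <- rbinom(R, 1, pnorm(beta0 + beta1 * sqrt(n)))
  data.frame(n = n, converged = TRUE, poi = s)
}
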