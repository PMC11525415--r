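test_that("all estimators recover the truth under perfect measurement", {
  spec <- parse_model(moderated_mediation_model_perfect())
  x <- simulate_dataset(spec, 5e4, seed = 101)
  truth <- c("Eta1~Xi1" = .2, "Eta1~Xi2" = .5, "Eta2~Eta1" = .2,
             "Eta2~Xi1:Eta1" = .1, "Eta2~Xi1" = .2, "Eta2~Xi2" = .3,
             "Eta2~Xi1:Xi2" = .1)
  for (m in c("SR", "FSR", "UPI")) {
    fit <- fit_qisem(x, spec, m)
    expect_true(fit$converged, label = paste(m, "converged"))
    for (k in names(truth)) {
      expect_lt(abs(fit$estimates[[k]] - truth[[k]]), 3 * fit$se[[k]],
                label = paste(m, k))
    }
  }
})

test_that("LMS is rejected with an informative error", {
  spec <- parse_model(example_moderation_model())
  x <- simulate_dataset(spec, 100, seed = 1)
  expect_error(fit_qisem(x, spec, "LMS"), "Mplus")
})

test_that("SR attenuates the interaction under fallible indicators", {
  spec <- parse_model(example_moderation_model())   # item reliability .8
  seeds <- derive_seeds(55, 200)
  est <- vapply(seeds, function(s) {
    f <- fit_sr(simulate_dataset(spec, 400, s), spec)
    if (f$converged) f$estimates[["Eta1~Xi1:Xi2"]] else NA_real_
  }, 0)
  est <- est[!is.na(est)]
  expect_gt(length(est), 190)
  # strictly below the population value .1 (one-sided t-test)
  tt <- t.test(est, mu = 0.1, alternative = "less")
  expect_lt(tt$p.value, 1e-6)
})

test_that("SR flags degenerate input instead of raising", {
  spec <- parse_model(perfect_moderation_model())
  x <- simulate_dataset(spec, 100, seed = 2)
  x[, "a1"] <- 1                              # constant indicator column
  fit <- fit_sr(x, spec)
  expect_false(fit$converged)
})

test_that("FSR scores reduce to indicators for fixed single-indicator latents", {
  # one fallible single-indicator latent with theta fixed at its population
  # value: the Bartlett/regression weights make scores proportional to x
  spec <- parse_model(paste(
    "A =~ 1*a1", "B =~ 1*b1",
    "B ~ 0.4*A",
    "A ~~ 1*A", "B ~~ 0.84*B",
    "a1 ~~ 0.25*a1", "b1 ~~ 0.25*b1", sep = "\n"))
  x <- simulate_dataset(spec, 2000, seed = 31)
  fit <- fit_fsr(x, spec)
  expect_true(fit$converged)
  # with a single indicator the score is a scalar multiple of the indicator,
  # so the fitted slope equals a rescaled regression of b1 on a1
  expect_true(is.finite(fit$estimates[["B~A"]]))
})

test_that("FSR interaction estimate is close to truth at high reliability", {
  spec <- parse_model(example_moderation_model())
  x <- simulate_dataset(spec, 5e4, seed = 77)
  fit <- fit_fsr(x, spec)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["Eta1~Xi1:Xi2"]] - 0.1), 0.015)
})

test_that("product indicators support matching, cross products and centering", {
  spec <- parse_model(example_moderation_model())
  x <- simulate_dataset(spec, 300, seed = 9)
  m <- build_product_indicators(x, spec, matching = "matched")
  expect_length(attr(m, "product_info")[["Xi1:Xi2"]], 3L)
  a <- build_product_indicators(x, spec, matching = "all")
  expect_length(attr(a, "product_info")[["Xi1:Xi2"]], 9L)
  pis <- attr(m, "product_info")[["Xi1:Xi2"]]
  expect_true(all(abs(colMeans(m[, pis, drop = FALSE])) < 1e-12))
  raw <- build_product_indicators(x, spec, centering = "none")
  expect_equal(unname(raw[, "x1.x4"]), unname(x[, "x1"] * x[, "x4"]))
  # quadratic terms square the matched indicators
  qspec <- parse_model(paste(
    "A =~ 1*a1 + 1*a2", "C =~ 1*c1",
    "C ~ 0.2*A + 0.1*A:A",
    "A ~~ 1*A", "C ~~ 0.9*C",
    "a1 ~~ 0.3*a1", "a2 ~~ 0.3*a2", "c1 ~~ 0*c1", sep = "\n"))
  xq <- simulate_dataset(qspec, 100, seed = 4)
  mq <- build_product_indicators(xq, qspec, centering = "none")
  expect_equal(attr(mq, "product_info")[["A:A"]], c("a1.a1", "a2.a2"))
  expect_equal(unname(mq[, "a1.a1"]), unname(xq[, "a1"]^2))
})

test_that("UPI interaction bias is small at high reliability and large n", {
  spec <- parse_model(example_moderation_model())
  x <- simulate_dataset(spec, 5e4, seed = 13)
  fit <- fit_upi(x, spec)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["Eta1~Xi1:Xi2"]] - 0.1), 0.02)
  expect_true(all(fit$se[structural_parameters(spec)] > 0))
})

test_that("path-model sandwich SEs calibrate against the replication SD", {
  spec <- parse_model(example_moderation_model())
  seeds <- derive_seeds(321, 400)
  est <- se <- numeric(0)
  for (s in seeds) {
    f <- fit_sr(simulate_dataset(spec, 300, s), spec)
    if (f$converged) {
      est <- c(est, f$estimates[["Eta1~Xi1:Xi2"]])
      se <- c(se, f$se[["Eta1~Xi1:Xi2"]])
    }
  }
  expect_lt(abs(sd(est) / mean(se) - 1), 0.1)
})
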