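fake_fit <- function(est, se, n = 200, keys = "Eta1~Xi1:Xi2",
                     converged = TRUE) {
  structure(list(method = "SR",
                 estimates = stats::setNames(est, keys),
                 se = stats::setNames(se, keys),
                 converged = converged, n = n),
            class = "qisem_fit")
}

test_that("significance decisions implement directional and two-sided tests", {
  spec <- parse_model(perfect_moderation_model())      # population gamma > 0
  fits <- list(fake_fit(0.25, 0.1), fake_fit(-0.30, 0.1),
               fake_fit(0.18, 0.1), fake_fit(0.25, 0.1, converged = FALSE))
  rec1 <- significance_decisions(fits, "Eta1 ~ Xi1:Xi2", alpha = 0.05,
                                 test = "onesided", spec = spec)
  expect_equal(rec1[["Eta1~Xi1:Xi2"]], c(1L, 0L, 1L, NA))  # z: 2.5, -3, 1.8
  rec2 <- significance_decisions(fits, "Eta1 ~ Xi1:Xi2", alpha = 0.05,
                                 test = "twosided", spec = spec)
  expect_equal(rec2[["Eta1~Xi1:Xi2"]], c(1L, 1L, 0L, NA))  # |z| vs 1.96
})

test_that("power-curve fit recovers the generating coefficients", {
  rec <- probit_records(-1.64, 0.2, c(25, 600), 1e5, seed = 8)
  fit <- fit_power_model(rec, "poi")
  # 1e5 records: estimates should sit well within 3 SEs of truth
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta[1] - (-1.64)), 3 * se[1])
  expect_lt(abs(fit$beta[2] - 0.2), 3 * se[2])
})

test_that("generator coverage: the 95% CI contains the truth ~95% of time", {
  hits <- 0L
  for (s in 1:60) {
    rec <- probit_records(-1.64, 0.2, c(25, 600), 3000, seed = 1000 + s)
    fit <- fit_power_model(rec, "poi")
    se <- sqrt(diag(fit$vcov))
    if (abs(fit$beta[2] - 0.2) < 1.96 * se[2]) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.85)
})

test_that("complete separation raises an actionable error", {
  rec <- data.frame(n = rep(c(5000, 6000), 50), converged = TRUE, poi = 1L)
  expect_error(fit_power_model(rec, "poi"), "separation")
})

test_that("predict_power is monotone with a well-ordered band", {
  fit <- structure(list(link = "probit", beta = c(-1.64, 0.1),
                        vcov = matrix(c(4e-3, -1e-4, -1e-4, 4e-6), 2)),
                   class = "power_fit")
  pp <- predict_power(fit, c(100, 616, 1000))
  expect_equal(pp$power[2], 0.8, tolerance = 5e-3)
  expect_true(all(diff(pp$power) > 0))
  expect_true(all(pp$lower <= pp$power & pp$power <= pp$upper))
  expect_true(all(pp$lower > 0 & pp$upper < 1))
  fit0 <- fit; fit0$vcov <- matrix(0, 2, 2)
  pp0 <- predict_power(fit0, 616)
  expect_equal(pp0$lower, pp0$power)
  expect_equal(pp0$upper, pp0$power)
})

test_that("required_n inverts the power curve", {
  expect_identical(required_n(c(-1.64, 0.1), 0.8), 616L)
  expect_identical(required_n(c(-1.64, 0.2), 0.8), 154L)
  # inversion identity at an interior point
  rho <- pnorm(-1.64 + 0.1 * sqrt(400))
  expect_identical(required_n(c(-1.64, 0.1), rho), 400L)
  expect_error(required_n(c(-1.64, -0.1), 0.8), "slope")
})

test_that("required_n_lb dominates required_n and degenerates correctly", {
  rec <- probit_records(-1.64, 0.2, c(25, 600), 5000, seed = 12)
  fit <- fit_power_model(rec, "poi")
  na <- required_n(fit, 0.8)
  nlb <- required_n_lb(fit, 0.8, 0.05)
  expect_gte(nlb, na)
  fit0 <- fit; fit0$vcov <- matrix(0, 2, 2)
  expect_identical(required_n_lb(fit0, 0.8, 0.05), required_n(fit0, 0.8))
  # smaller alpha_rho widens the band and cannot shrink N_lb
  expect_gte(required_n_lb(fit, 0.8, 0.01), nlb)
})

test_that("z-test decisions recover the closed-form probit limits", {
  # one-sample z test of mu = .2 (sd 1), one-sided alpha = .05:
  # P(significant | n) = Phi(sqrt(n) * mu - q95), so beta0 = -1.6449,
  # beta1 = mu = 0.2 exactly
  set.seed(99)
  R <- 1e5
  n <- sample(5:400, R, replace = TRUE)
  z <- rnorm(R, mean = sqrt(n) * 0.2, sd = 1)
  rec <- data.frame(n = n, converged = TRUE, poi = as.integer(z > qnorm(.95)))
  fit <- fit_power_model(rec, "poi")
  expect_lt(abs(fit$beta[1] / (-qnorm(.95)) - 1), 0.02)
  expect_lt(abs(fit$beta[2] / 0.2 - 1), 0.02)
})

test_that("probit and logit inversions agree near the target power", {
  rec <- probit_records(-1.64, 0.2, c(25, 600), 2e4, seed = 77)
  np <- required_n(fit_power_model(rec, "poi", "probit"), 0.8)
  nl <- required_n(fit_power_model(rec, "poi", "logit"), 0.8)
  expect_lt(abs(np - nl) / np, 0.1)
})
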