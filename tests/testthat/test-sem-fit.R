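# direct checks of the covariance-structure ML fitter

saturated_template <- function(obs) {
  p <- length(obs)
  lambda <- diag(1, p); dimnames(lambda) <- list(obs, obs)
  sem_template(obs, obs,
               lambda, matrix(FALSE, p, p),
               matrix(0, p, p), matrix(FALSE, p, p),
               diag(1, p), matrix(TRUE, p, p),
               rep(0, p), rep(FALSE, p))
}

one_factor_template <- function(obs) {
  p <- length(obs)
  lambda <- matrix(1, p, 1); lambda_free <- matrix(c(FALSE, rep(TRUE, p - 1)))
  sem_template(obs, "F", lambda, lambda_free,
               matrix(0, 1, 1), matrix(FALSE, 1, 1),
               matrix(1, 1, 1), matrix(TRUE, 1, 1),
               rep(0.5, p), rep(TRUE, p))
}

test_that("a saturated model reproduces the sample covariance exactly", {
  set.seed(42)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  fit <- fit_linear_sem(x, saturated_template(c("a", "b", "c")))
  expect_true(fit$converged)
  expect_equal(fit$fmin, 0, tolerance = 1e-8)
  S <- crossprod(scale(x, scale = FALSE)) / nrow(x)
  expect_equal(unname(fit$mats$psi), unname(S), tolerance = 1e-6)
})

test_that("analytic gradient matches a numerical gradient", {
  set.seed(7)
  lam <- c(1, .8, 1.2)
  f <- rnorm(200)
  x <- outer(f, lam) + matrix(rnorm(600, sd = sqrt(.5)), 200, 3)
  colnames(x) <- c("a", "b", "c")
  tpl <- one_factor_template(c("a", "b", "c"))
  Z <- scale(x, scale = FALSE)
  S <- crossprod(Z) / nrow(Z)
  attr(S, "logdet") <- determinant(S)$modulus[1]
  ft <- mspepower:::.free_table(tpl)
  par <- c(0.9, 1.1, 0.8, 0.4, 0.6, 0.5)
  ga <- mspepower:::.sem_gradient(par, tpl, ft, S)
  fn <- function(p) mspepower:::.sem_objective(p, tpl, ft, S)$f
  gn <- vapply(seq_along(par), function(j) {
    h <- 1e-6
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    (fn(pp) - fn(pm)) / (2 * h)
  }, 0)
  expect_equal(ga, gn, tolerance = 1e-5)
})

test_that("single-factor ML estimates are consistent with sensible SEs", {
  spec <- parse_model(paste(
    "F =~ 1*y1 + 0.8*y2 + 1.2*y3",
    "F ~~ 1*F",
    "y1 ~~ 0.5*y1", "y2 ~~ 0.5*y2", "y3 ~~ 0.5*y3", sep = "\n"))
  x <- simulate_dataset(spec, 5e4, seed = 11)
  fit <- fit_linear_sem(x, one_factor_template(c("y1", "y2", "y3")))
  expect_true(fit$converged)
  truth <- c("F=~y2" = 0.8, "F=~y3" = 1.2, "F~~F" = 1,
             "y1~~y1" = 0.5, "y2~~y2" = 0.5, "y3~~y3" = 0.5)
  for (k in names(truth)) {
    expect_lt(abs(fit$estimates[[k]] - truth[[k]]), 3 * fit$se[[k]])
  }
  # under correct specification with normal data, sandwich SEs are close to
  # the usual ML standard errors; check the loading SE against the known
  # asymptotic order (finite, small)
  expect_true(all(fit$se[names(truth)] > 0))
  expect_true(all(fit$se[names(truth)] < 0.05))
})

test_that("sandwich SEs calibrate against the replication SD", {
  spec <- parse_model(paste(
    "F =~ 1*y1 + 0.8*y2 + 1.2*y3",
    "F ~~ 1*F",
    "y1 ~~ 0.5*y1", "y2 ~~ 0.5*y2", "y3 ~~ 0.5*y3", sep = "\n"))
  tpl <- one_factor_template(c("y1", "y2", "y3"))
  seeds <- derive_seeds(2024, 300)
  est <- se <- numeric(0)
  for (s in seeds) {
    fit <- fit_linear_sem(simulate_dataset(spec, 500, s), tpl)
    if (fit$converged) {
      est <- c(est, fit$estimates[["F=~y2"]])
      se <- c(se, fit$se[["F=~y2"]])
    }
  }
  expect_gt(length(est), 280)
  expect_lt(abs(sd(est) / mean(se) - 1), 0.15)
})

test_that("degenerate inputs are flagged, not raised", {
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  x[, 2] <- x[, 1]                       # singular sample covariance
  fit <- fit_linear_sem(x, one_factor_template(c("a", "b", "c")))
  expect_false(fit$converged)
  expect_error(sem_template(letters[1:3], "F",
                            matrix(1, 3, 1), matrix(TRUE, 3, 1),
                            matrix(0, 1, 1), matrix(FALSE, 1, 1),
                            matrix(1, 1, 1), matrix(TRUE, 1, 1),
                            rep(0, 3), rep(TRUE, 3)),
               "not identified")
})
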