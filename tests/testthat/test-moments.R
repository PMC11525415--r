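test_that("linear latent covariances match hand expansion", {
  spec <- modmed_spec()
  lc <- linear_latent_cov(spec)
  # Cov(eta1, xi1) = .2*1 + .5*.5, Cov(eta1, xi2) = .2*.5 + .5
  expect_equal(lc["Eta1", "Xi1"], 0.45)
  expect_equal(lc["Eta1", "Xi2"], 0.60)
  expect_equal(lc["Eta1", "Eta1"], 1)
  # eta2 has a product term in its own equation: excluded from the normal set
  expect_false("Eta2" %in% rownames(lc))
})

test_that("declared covariances pass through for purely exogenous models", {
  spec <- parse_model(paste(
    "A =~ 1*a1", "B =~ 1*b1",
    "A ~~ 1.5*A", "B ~~ 2*B", "A ~~ 0.3*B",
    "a1 ~~ 0.1*a1", "b1 ~~ 0.1*b1", sep = "\n"))
  lc <- linear_latent_cov(spec)
  expect_equal(lc["A", "A"], 1.5)
  expect_equal(lc["B", "B"], 2)
  expect_equal(lc["A", "B"], 0.3)
})

test_that("product moments follow the Isserlis identities", {
  spec <- modmed_spec()
  pm <- product_moments(spec, list(c("Xi1", "Xi2"), c("Eta1", "Xi1")))
  # Var(xi1 xi2) = 1 + .5^2; Cov(eta1 xi1, xi1 xi2) = .45*.5 + .6*1
  expect_equal(unname(pm$cov["Xi1:Xi2", "Xi1:Xi2"]), 1.25)
  expect_equal(unname(pm$cov["Xi1:Eta1", "Xi1:Xi2"]), 0.825)
  expect_equal(unname(pm$mean["Xi1:Xi2"]), 0.5)
  # independent squares are uncorrelated
  ind <- parse_model(paste(
    "A =~ 1*a1", "B =~ 1*b1", "A ~~ 1*A", "B ~~ 1*B",
    "a1 ~~ 0*a1", "b1 ~~ 0*b1", sep = "\n"))
  pmi <- product_moments(ind, list(c("A", "A"), c("B", "B")))
  expect_equal(unname(pmi$cov["A:A", "B:B"]), 0)
  expect_equal(unname(pmi$cov["A:A", "A:A"]), 2)  # Var(Z^2) for Z ~ N(0,1)
})

test_that("endogenous variances and standardizing residuals are exact", {
  spec <- modmed_spec()
  expect_equal(endogenous_variance(spec, "Eta1"), 1)
  expect_equal(endogenous_variance(spec, "Eta2"), 1)
  expect_equal(residual_variance_for_unit_variance(spec, "Eta1"), 0.61)
  expect_equal(residual_variance_for_unit_variance(spec, "Eta2"), 0.620975)
})

test_that("sequential variance increments reproduce the decomposition", {
  spec <- modmed_spec()
  i1 <- variance_increment(spec, "Eta2", c("Xi1", "Xi2"))
  i2 <- variance_increment(spec, "Eta2", c("Eta1", "Xi1"),
                           prior_terms = list(c("Xi1", "Xi2")))
  expect_equal(i1, 0.0125)
  expect_equal(i2, 0.028525)
  # the other ordering differs per term but totals the same nonlinear share
  j1 <- variance_increment(spec, "Eta2", c("Eta1", "Xi1"))
  j2 <- variance_increment(spec, "Eta2", c("Xi1", "Xi2"),
                           prior_terms = list(c("Eta1", "Xi1")))
  expect_equal(i1 + i2, j1 + j2)
  expect_false(isTRUE(all.equal(i1, j2)))
  # a zero coefficient contributes a zero increment
  z <- parse_model(paste(
    "A =~ 1*a1", "B =~ 1*b1", "C =~ 1*c1",
    "C ~ 0.3*A + 0*A:B",
    "A ~~ 1*A", "B ~~ 1*B", "C ~~ 0.91*C",
    "a1 ~~ 0*a1", "b1 ~~ 0*b1", "c1 ~~ 0*c1", sep = "\n"))
  expect_equal(variance_increment(z, "C", c("A", "B")), 0)
})

test_that("scale reliability follows the composite formula", {
  txt <- function(theta) paste(
    "F =~ 1*y1 + 1*y2 + 1*y3",
    sprintf("y1 ~~ %s*y1 \n y2 ~~ %s*y2 \n y3 ~~ %s*y3", theta, theta, theta),
    "F ~~ 1*F", sep = "\n")
  expect_equal(scale_reliability(parse_model(txt(0)), "F"), 1)
  expect_equal(scale_reliability(parse_model(txt(1)), "F"), 0.75)
  one <- parse_model("F =~ 1*y1 \n y1 ~~ 0.5*y1 \n F ~~ 1*F")
  expect_equal(scale_reliability(one, "F"), 2 / 3)
})

test_that("analytic moments agree with Monte-Carlo at large n", {
  spec <- modmed_spec()
  x <- simulate_dataset(spec, 2e5, seed = 314, return_latents = TRUE)
  lat <- attr(x, "latents")
  lc <- linear_latent_cov(spec)
  n <- nrow(lat)
  # variances: MC standard error of a variance is ~ sqrt(Var(z^2)/n)
  for (v in c("Xi1", "Xi2", "Eta1")) {
    mc_se <- sd(scale(lat[, v], scale = FALSE)^2) / sqrt(n)
    expect_lt(abs(var(lat[, v]) - lc[v, v]), 3 * mc_se)
  }
  v2 <- endogenous_variance(spec, "Eta2")
  mc_se <- sd(scale(lat[, "Eta2"], scale = FALSE)^2) / sqrt(n)
  expect_lt(abs(var(lat[, "Eta2"]) - v2), 3 * mc_se)
  # a product moment
  p <- lat[, "Xi1"] * lat[, "Xi2"]
  pm <- product_moments(spec, c("Xi1", "Xi2"))
  expect_lt(abs(mean(p) - pm$mean), 3 * sd(p) / sqrt(n))
  expect_lt(abs(var(p) - pm$cov[1, 1]),
            3 * sd(scale(p, scale = FALSE)^2) / sqrt(n))
})

test_that("moment engine refuses products of non-normal latents", {
  spec <- modmed_spec()
  expect_error(product_moments(spec, c("Eta2", "Xi1")), "not jointly normal")
})
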