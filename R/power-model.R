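#' Turn fitted replications into significance decisions
#'
#' For each converged fit, the z statistic `estimate / SE` of every
#' parameter of interest is compared to the standard-normal quantile.
#' One-sided tests are directional in the sign of the population
#' coefficient: `S = 1` iff `sign(population) * z > q(1 - alpha)`.
#' Two-sided tests use `|z| > q(1 - alpha/2)`. Nonconverged fits carry no
#' decisions.
#'
#' @param fits List of `qisem_fit` objects.
#' @param pois Character vector of parameter-of-interest strings
#'   (`"Eta1 ~ Xi1:Xi2"`).
#' @param alpha Type I error rate of the significance test.
#' @param test `"onesided"` (default) or `"twosided"`.
#' @param spec The population `qisem_model` (supplies the directions).
#' @return A data frame with columns `n`, `converged` and one 0/1 column per
#'   POI (`NA` where nonconverged).
#' @export
significance_decisions <- function(fits, pois, alpha = 0.05,
                                   test = c("onesided", "twosided"), spec) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  refs <- lapply(pois, resolve_poi, spec = spec)
  keys <- vapply(refs, `[[`, "", "key")
  popsign <- vapply(refs, function(r) {
    e <- spec$equations[[r$lhs]]
    lbls <- vapply(seq_len(nrow(e)),
                   function(i) term_label(e$v1[i], e$v2[i], spec), "")
    sign(e$coef[match(r$term, lbls)])
  }, 0)
  q1 <- stats::qnorm(1 - alpha)
  q2 <- stats::qnorm(1 - alpha / 2)
  out <- data.frame(n = vapply(fits, `[[`, 0, "n"),
                    converged = vapply(fits, `[[`, TRUE, "converged"))
  for (j in seq_along(keys)) {
    dec <- rep(NA_integer_, length(fits))
    for (i in seq_along(fits)) {
      f <- fits[[i]]
      if (!isTRUE(f$converged)) next
      if (!(keys[j] %in% names(f$estimates)))
        stop("POI '", keys[j], "' missing from a converged fit")
      z <- f$estimates[[keys[j]]] / f$se[[keys[j]]]
      dec[i] <- if (test == "onesided") as.integer(popsign[j] * z > q1)
                else as.integer(abs(z) > q2)
    }
    out[[keys[j]]] <- dec
  }
  out
}

#' Fit the power curve to significance decisions
#'
#' Maximum-likelihood binary regression of the significance decisions on the
#' square root of the sample size,
#' `P(S = 1 | n) = linkinv(beta0 + beta1 sqrt(n))`,
#' with the coefficient covariance taken from the observed information.
#' Nonconverged replications are excluded.
#'
#' @param records Data frame from [significance_decisions()] (columns `n`,
#'   `converged`, plus decision columns).
#' @param poi Name of the decision column to model (default: the first).
#' @param link `"probit"` (default) or `"logit"`.
#' @param start Optional starting coefficients (e.g. from a previous fit on
#'   a subset of the records).
#' @return An object of class `power_fit`: `link`, `beta` (intercept and
#'   slope on `sqrt(n)`), `vcov` (2 x 2), `n_records`.
#' @export
fit_power_model <- function(records, poi = NULL, link = c("probit", "logit"),
                            start = NULL) {
  link <- match.arg(link)
  if (is.null(poi)) {
    cand <- setdiff(names(records), c("n", "converged", "step"))
    if (!length(cand)) stop("no decision columns in records")
    poi <- cand[1]
  }
  ok <- records$converged & !is.na(records[[poi]])
  s <- records[[poi]][ok]
  n <- records$n[ok]
  if (length(unique(n)) < 2L)
    stop("need decisions at >= 2 distinct sample sizes")
  if (all(s == 1) || all(s == 0))
    stop("complete separation: all decisions are ", s[1],
         "; widen the range of sample sizes")
  X <- cbind(1, sqrt(n))
  fam <- stats::binomial(link = link)
  fit <- suppressWarnings(stats::glm.fit(X, s, family = fam, start = start))
  if (!fit$converged) stop("power-curve fit did not converge")
  vcov <- .binary_vcov_observed(X, s, fit$coefficients, link)
  if (is.null(vcov)) {           # fall back to the expected information
    R <- qr.R(structure(fit$qr, class = "qr"))
    vcov <- chol2inv(R)
  }
  structure(list(link = link,
                 beta = stats::setNames(fit$coefficients, c("beta0", "beta1")),
                 vcov = vcov, n_records = length(s), poi = poi,
                 n_range = range(n)),
            class = "power_fit")
}

#' @export
print.power_fit <- function(x, ...) {
  cat("Power curve (", x$link, "): linkinv(", signif(x$beta[1], 5), " + ",
      signif(x$beta[2], 5), " * sqrt(n)), ", x$n_records, " decisions\n",
      sep = "")
  invisible(x)
}

## coefficient covariance from the observed information (negative Hessian of
## the Bernoulli log likelihood); for logit observed equals expected, for
## probit the residual term matters. NULL when not positive definite.
.binary_vcov_observed <- function(X, s, beta, link) {
  eta <- drop(X %*% beta)
  if (link == "logit") {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
  } else {
    mu <- stats::pnorm(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    phi <- stats::dnorm(eta)
    v <- mu * (1 - mu)
    r <- s - mu
    w <- phi^2 / v + eta * phi * r / v + phi^2 * r * (1 - 2 * mu) / v^2
  }
  H <- crossprod(X * w, X)
  out <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (!is.null(out) && any(diag(out) <= 0)) out <- NULL
  out
}

.linkfun <- function(link) {
  if (link == "probit") list(inv = stats::pnorm, q = stats::qnorm)
  else list(inv = stats::plogis, q = stats::qlogis)
}

#' Predicted power with a confidence band
#'
#' The band is computed on the linear-predictor scale from
#' `se^2 = [1, sqrt(n)] V [1, sqrt(n)]'` with the `1 - alpha_rho/2` normal
#' quantile and transformed through the link, so both endpoints stay inside
#' (0, 1).
#'
#' @param fit A `power_fit` (or a list with `beta`, `vcov`, `link`).
#' @param n Vector of sample sizes (>= 1).
#' @param alpha_rho Type I error rate for the band (default 0.05).
#' @return A data frame with columns `n`, `power`, `lower`, `upper`.
#' @export
predict_power <- function(fit, n, alpha_rho = 0.05) {
  stopifnot(all(n >= 1))
  lk <- .linkfun(fit$link)
  r <- sqrt(n)
  eta <- fit$beta[1] + fit$beta[2] * r
  v <- fit$vcov[1, 1] + 2 * r * fit$vcov[1, 2] + r^2 * fit$vcov[2, 2]
  zq <- stats::qnorm(1 - alpha_rho / 2)
  half <- zq * sqrt(pmax(v, 0))
  data.frame(n = n, power = lk$inv(eta),
             lower = lk$inv(eta - half), upper = lk$inv(eta + half))
}

#' Required sample size for a target power
#'
#' Inverts the fitted power curve:
#' `N = ceiling(((qlink(rho) - beta0) / beta1)^2)`.
#'
#' @param fit A `power_fit`, or a numeric vector `c(beta0, beta1)`.
#' @param rho Target power in (0, 1).
#' @param link Link function when coefficients are passed directly.
#' @return Integer required sample size.
#' @examples
#' required_n(c(-1.64, 0.1), rho = 0.8)   # 616
#' required_n(c(-1.64, 0.2), rho = 0.8)   # 154
#' @export
required_n <- function(fit, rho = 0.8, link = "probit") {
  stopifnot(rho > 0, rho < 1)
  if (is.numeric(fit)) fit <- list(beta = fit, link = link)
  b0 <- fit$beta[1]; b1 <- fit$beta[2]
  if (!is.finite(b1) || b1 <= 0)
    stop("power curve has nonpositive slope; no finite required sample size")
  lk <- .linkfun(fit$link)
  as.integer(ceiling(((lk$q(rho) - b0) / b1)^2))
}

#' Required sample size from the lower confidence bound of the power curve
#'
#' The smallest integer sample size whose lower `1 - alpha_rho` confidence
#' bound on the power reaches the target `rho`; always at least
#' [required_n()], and equal to it in the degenerate zero-variance case.
#' Found by root search on the monotone lower band, with an explicit error
#' if the band never reaches `rho` below the documented ceiling of 1e7.
#'
#' @inheritParams predict_power
#' @param rho Target power.
#' @return Integer sample size.
#' @export
required_n_lb <- function(fit, rho = 0.8, alpha_rho = 0.05) {
  n_alpha <- required_n(fit, rho)
  if (max(abs(fit$vcov)) == 0) return(n_alpha)
  lk <- .linkfun(fit$link)
  zq <- stats::qnorm(1 - alpha_rho / 2)
  target <- lk$q(rho)
  f <- function(n) {
    r <- sqrt(n)
    v <- fit$vcov[1, 1] + 2 * r * fit$vcov[1, 2] + r^2 * fit$vcov[2, 2]
    fit$beta[1] + fit$beta[2] * r - zq * sqrt(pmax(v, 0)) - target
  }
  lo <- n_alpha
  hi <- max(2 * n_alpha, 4)
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e7)
      stop("lower confidence band never reaches the target power below 1e7; ",
           "increase the number of replications")
  }
  if (f(lo) >= 0) return(n_alpha)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
  max(n_alpha, as.integer(ceiling(root)))
}

## upper-band crossing: smallest n where the *upper* bound reaches rho —
## the optimistic end of the plausible range for the required sample size
.required_n_ub_band <- function(fit, rho, alpha_rho) {
  lk <- .linkfun(fit$link)
  zq <- stats::qnorm(1 - alpha_rho / 2)
  target <- lk$q(rho)
  f <- function(n) {
    r <- sqrt(n)
    v <- fit$vcov[1, 1] + 2 * r * fit$vcov[1, 2] + r^2 * fit$vcov[2, 2]
    fit$beta[1] + fit$beta[2] * r + zq * sqrt(pmax(v, 0)) - target
  }
  if (f(1) >= 0) return(1L)
  hi <- 4
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e7) return(NA_integer_)
  }
  as.integer(ceiling(stats::uniroot(f, c(1, hi), tol = 1e-6)$root))
}
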