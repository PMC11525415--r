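#' Fit a QISEM to one dataset
#'
#' Dispatches to the scale-regression ([fit_sr()]), factor-score-regression
#' ([fit_fsr()]) or unconstrained-product-indicator ([fit_upi()]) estimator.
#' `LMS` (the distribution-analytic maximum-likelihood estimator) is named
#' but unavailable: it requires the external Mplus program and is out of
#' scope here.
#'
#' @param sample Numeric matrix of indicator data.
#' @param spec A `qisem_model`.
#' @param method One of `"SR"`, `"FSR"`, `"UPI"`, `"LMS"`.
#' @return A `qisem_fit`: named `estimates` and `se` (structural keys have
#'   the form `"Eta~Xi1"` / `"Eta~Xi1:Xi2"`), a `converged` flag and `n`.
#' @export
fit_qisem <- function(sample, spec, method = c("SR", "FSR", "UPI", "LMS")) {
  method <- match.arg(method)
  switch(method,
         SR  = fit_sr(sample, spec),
         FSR = fit_fsr(sample, spec),
         UPI = fit_upi(sample, spec),
         LMS = stop("method 'LMS' requires the external Mplus program and ",
                    "is out of scope; use 'UPI', 'FSR' or 'SR'"))
}

## recursive path model on latent proxies: equation-wise least squares with
## HC1 sandwich standard errors; product regressors from centered proxies
.fit_path_model <- function(scores, spec, method) {
  n <- nrow(scores)
  scores <- scale(scores, center = TRUE, scale = FALSE)
  est <- numeric(0); se <- numeric(0)
  converged <- TRUE
  for (l in spec$endogenous) {
    e <- spec$equations[[l]]
    X <- matrix(1, n, 1L)
    labs <- paste0(l, "~1")
    for (i in seq_len(nrow(e))) {
      x <- if (is.na(e$v2[i])) scores[, e$v1[i]]
           else scores[, e$v1[i]] * scores[, e$v2[i]]
      X <- cbind(X, x)
      labs <- c(labs, paste0(l, "~", term_label(e$v1[i], e$v2[i], spec)))
    }
    y <- scores[, l]
    if (n <= ncol(X) || qr(X)$rank < ncol(X)) {
      est[labs] <- NA_real_; se[labs] <- NA_real_
      est[paste0(l, "~~", l)] <- NA_real_; se[paste0(l, "~~", l)] <- NA_real_
      converged <- FALSE
      next
    }
    colnames(X) <- labs
    lmobj <- stats::lm(y ~ X - 1)
    vc <- sandwich::vcovHC(lmobj, type = "HC1")
    b <- unname(stats::coef(lmobj))
    est[labs] <- b
    se[labs] <- sqrt(diag(vc))
    rv <- sum(stats::residuals(lmobj)^2) / (n - ncol(X))
    est[paste0(l, "~~", l)] <- rv
    se[paste0(l, "~~", l)] <- NA_real_
    if (any(!is.finite(b)) || any(!is.finite(se[labs]))) converged <- FALSE
  }
  structure(list(method = method, estimates = est, se = se,
                 converged = converged, n = n),
            class = "qisem_fit")
}

#' Scale regression (SR)
#'
#' Uses the scale mean over each latent's indicators as a single-indicator
#' proxy, centers the scale means, forms product regressors from the
#' centered means, and fits the recursive path model equation by equation by
#' least squares with heteroskedasticity-robust (HC1) standard errors.
#' Measurement error is not modelled, so product-term coefficients are
#' attenuated whenever indicators are fallible.
#'
#' @inheritParams fit_qisem
#' @return A `qisem_fit`.
#' @export
fit_sr <- function(sample, spec) {
  sm <- vapply(spec$latents, function(l) {
    idx <- spec$measurement[[l]]$indicator
    rowMeans(sample[, idx, drop = FALSE])
  }, numeric(nrow(sample)))
  if (any(apply(sm, 2, stats::sd) == 0)) {
    labs <- c(structural_parameters(spec))
    return(structure(list(method = "SR",
      estimates = stats::setNames(rep(NA_real_, length(labs)), labs),
      se = stats::setNames(rep(NA_real_, length(labs)), labs),
      converged = FALSE, n = nrow(sample)), class = "qisem_fit"))
  }
  fit <- .fit_path_model(sm, spec, "SR")
  fit
}

## CFA template of the linear measurement model: loadings free with the first
## indicator anchored at its population loading; latent covariances all free;
## single-indicator latents have loading and error variance fixed at the
## declared population values (a free pair is not identified)
.cfa_template <- function(spec) {
  obs <- spec$indicators
  lat <- spec$latents
  p <- length(obs); m <- length(lat)
  lambda <- matrix(0, p, m, dimnames = list(obs, lat))
  lambda_free <- matrix(FALSE, p, m)
  theta <- vapply(obs, function(i)
    spec$variances[.vkey(i, i, c(lat, obs))], 0)
  theta_free <- rep(TRUE, p)
  for (j in seq_len(m)) {
    mm <- spec$measurement[[lat[j]]]
    rows <- match(mm$indicator, obs)
    if (nrow(mm) == 1L) {
      lambda[rows, j] <- mm$loading      # fixed at population
      theta_free[rows] <- FALSE          # theta fixed at population
    } else {
      lambda[rows[1], j] <- mm$loading[1]
      lambda[rows[-1], j] <- 1
      lambda_free[rows[-1], j] <- TRUE
    }
  }
  psi <- diag(1, m); dimnames(psi) <- list(lat, lat)
  psi_free <- matrix(TRUE, m, m)
  b <- matrix(0, m, m); b_free <- matrix(FALSE, m, m)
  theta <- ifelse(theta_free, 0, theta)  # values retained only where fixed
  sem_template(obs, lat, lambda, lambda_free, b, b_free, psi, psi_free,
               theta, theta_free)
}

#' Factor score regression (FSR, SL method)
#'
#' Fits the linear confirmatory factor model by maximum likelihood, computes
#' regression (Thomson) factor scores `Phi L' Sigma^-1 x` for the exogenous
#' latents and Bartlett scores `(L' Th^-1 L)^-1 L' Th^-1 x` for the
#' endogenous latents, and enters the centered scores and their products
#' into the recursive path model with HC1 robust standard errors.
#'
#' @inheritParams fit_qisem
#' @return A `qisem_fit`; a nonconverged or improper CFA solution (e.g. a
#'   negative error variance) is flagged, not raised.
#' @export
fit_fsr <- function(sample, spec) {
  tpl <- .cfa_template(spec)
  cfa <- fit_linear_sem(sample, tpl)
  if (!cfa$converged) {
    labs <- structural_parameters(spec)
    return(structure(list(method = "FSR",
      estimates = stats::setNames(rep(NA_real_, length(labs)), labs),
      se = stats::setNames(rep(NA_real_, length(labs)), labs),
      converged = FALSE, n = nrow(sample)), class = "qisem_fit"))
  }
  L <- cfa$mats$lambda
  Phi <- cfa$mats$psi
  th <- pmax(cfa$mats$theta, 1e-10)      # guard exact-zero error variances
  X <- scale(sample[, spec$indicators, drop = FALSE], center = TRUE,
             scale = FALSE)
  SigL <- L %*% Phi %*% t(L); diag(SigL) <- diag(SigL) + cfa$mats$theta
  reg_w <- Phi %*% t(L) %*% solve(SigL)                  # regression scores
  LtTi <- t(L) / rep(th, each = ncol(L))
  bar_w <- solve(LtTi %*% L) %*% LtTi                    # Bartlett scores
  scores <- matrix(0, nrow(X), length(spec$latents),
                   dimnames = list(NULL, spec$latents))
  for (l in spec$latents) {
    w <- if (l %in% spec$exogenous) reg_w[l, ] else bar_w[l, ]
    scores[, l] <- X %*% w
  }
  fit <- .fit_path_model(scores, spec, "FSR")
  fit$cfa <- cfa
  fit
}

#' Build product indicators for the UPI approach
#'
#' For each distinct product term, indicator products are formed either by
#' matching (the i-th indicator of one latent with the i-th of the other, up
#' to the smaller indicator count; squares of each indicator for quadratic
#' terms) or as the full cross product. Centering `"double_mean"` centers the
#' two components, forms the product, and re-centers the product;
#' `"mean"` centers the components only; `"none"` uses raw columns.
#'
#' @param sample Indicator data matrix.
#' @param spec A `qisem_model`.
#' @param matching `"matched"` (default) or `"all"`.
#' @param centering `"double_mean"` (default), `"mean"` or `"none"`.
#' @return The sample with product-indicator columns appended; attribute
#'   `"product_info"` maps each product-term label to its indicator names.
#' @export
build_product_indicators <- function(sample, spec,
                                     matching = c("matched", "all"),
                                     centering = c("double_mean", "mean", "none")) {
  matching <- match.arg(matching)
  centering <- match.arg(centering)
  prods <- .product_terms(spec)
  info <- list()
  out <- sample
  for (lbl in names(prods)) {
    pr <- prods[[lbl]]
    ia <- spec$measurement[[pr[1]]]$indicator
    ib <- spec$measurement[[pr[2]]]$indicator
    pairs <- if (pr[1] == pr[2]) {
      if (matching == "matched") cbind(ia, ia)
      else { g <- expand.grid(ia, ia, stringsAsFactors = FALSE)
             as.matrix(g[as.integer(factor(g[[1]], ia)) <=
                         as.integer(factor(g[[2]], ia)), ]) }
    } else if (matching == "matched") {
      kk <- min(length(ia), length(ib))
      cbind(ia[seq_len(kk)], ib[seq_len(kk)])
    } else {
      as.matrix(expand.grid(ia, ib, stringsAsFactors = FALSE))
    }
    nms <- character(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      a <- sample[, pairs[r, 1]]; b <- sample[, pairs[r, 2]]
      if (centering %in% c("mean", "double_mean")) {
        a <- a - mean(a); b <- b - mean(b)
      }
      prod <- a * b
      if (centering == "double_mean") prod <- prod - mean(prod)
      nm <- paste0(pairs[r, 1], ".", pairs[r, 2])
      nms[r] <- nm
      out <- cbind(out, prod)
      colnames(out)[ncol(out)] <- nm
    }
    info[[lbl]] <- nms
  }
  attr(out, "product_info") <- info
  out
}

## augmented-model template for UPI: product latents measured by product
## indicators, all loadings/variances free (first product indicator anchored
## at 1), exogenous block incl. product latents fully covarying
.upi_template <- function(spec, product_info) {
  obs <- c(spec$indicators, unlist(product_info, use.names = FALSE))
  plats <- names(product_info)
  lat <- c(spec$latents, plats)
  p <- length(obs); m <- length(lat)
  allv <- c(spec$latents, spec$indicators)
  lambda <- matrix(0, p, m, dimnames = list(obs, lat))
  lambda_free <- matrix(FALSE, p, m, dimnames = list(obs, lat))
  theta <- stats::setNames(rep(0, p), obs)
  theta_free <- stats::setNames(rep(TRUE, p), obs)
  for (l in spec$latents) {
    mm <- spec$measurement[[l]]
    if (nrow(mm) == 1L) {
      lambda[mm$indicator, l] <- mm$loading
      theta[mm$indicator] <- spec$variances[.vkey(mm$indicator, mm$indicator, allv)]
      theta_free[mm$indicator] <- FALSE
    } else {
      lambda[mm$indicator[1], l] <- mm$loading[1]
      lambda[mm$indicator[-1], l] <- 1
      lambda_free[mm$indicator[-1], l] <- TRUE
    }
  }
  for (pl in plats) {
    pis <- product_info[[pl]]
    lambda[pis[1], pl] <- 1
    if (length(pis) > 1L) {
      lambda[pis[-1], pl] <- 1
      lambda_free[pis[-1], pl] <- TRUE
    } else {
      theta[pis] <- 0                   # single product indicator: error-free
      theta_free[pis] <- FALSE
    }
  }
  b <- matrix(0, m, m, dimnames = list(lat, lat))
  b_free <- matrix(FALSE, m, m, dimnames = list(lat, lat))
  for (l in spec$endogenous) {
    e <- spec$equations[[l]]
    for (i in seq_len(nrow(e))) {
      target <- if (is.na(e$v2[i])) e$v1[i]
                else term_label(e$v1[i], e$v2[i], spec)
      b_free[l, target] <- TRUE
    }
  }
  psi <- diag(1, m); dimnames(psi) <- list(lat, lat)
  psi_free <- matrix(FALSE, m, m, dimnames = list(lat, lat))
  exo_all <- c(spec$exogenous, plats)
  psi_free[exo_all, exo_all] <- TRUE
  for (l in spec$endogenous) psi_free[l, l] <- TRUE
  for (kk in names(spec$variances)) {
    pair <- strsplit(kk, "~~", fixed = TRUE)[[1]]
    if (pair[1] != pair[2] && all(pair %in% spec$endogenous)) {
      psi_free[pair[1], pair[2]] <- TRUE
      psi_free[pair[2], pair[1]] <- TRUE
    }
  }
  sem_template(obs, lat, lambda, lambda_free, b, b_free, psi, psi_free,
               theta, theta_free)
}

#' Unconstrained product indicator approach (UPI)
#'
#' Builds matched, double-mean-centered product indicators, augments the
#' linear SEM with one latent product factor per product term (all loadings,
#' error variances and latent (co)variances free; the first product
#' indicator anchors each product factor), and fits the augmented model by
#' maximum likelihood via [fit_linear_sem()] with sandwich standard errors.
#'
#' @inheritParams fit_qisem
#' @param matching,centering Passed to [build_product_indicators()].
#' @return A `qisem_fit`; structural coefficients carry keys matching the
#'   parameter-of-interest syntax (e.g. `"Eta1~Xi1:Xi2"`).
#' @export
fit_upi <- function(sample, spec, matching = "matched",
                    centering = "double_mean") {
  aug <- build_product_indicators(sample, spec, matching, centering)
  tpl <- .upi_template(spec, attr(aug, "product_info"))
  fit <- fit_linear_sem(aug, tpl)
  fit$method <- "UPI"
  fit
}
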