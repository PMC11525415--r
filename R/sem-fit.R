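#' Construct a linear SEM template
#'
#' A template fixes the free-parameter layout of a linear covariance-structure
#' model with implied covariance
#' `Sigma = Lambda (I - B)^-1 Psi (I - B)^-T Lambda' + Theta`,
#' where `Lambda` holds loadings of `p` observed on `m` latent variables,
#' `B` the recursive structural coefficients among latents, `Psi` the latent
#' (co)variances/residual variances and `Theta` the diagonal
#' measurement-error variances.
#'
#' @param obs Observed variable names (order fixes the rows of `Sigma`).
#' @param lat Latent names.
#' @param lambda,lambda_free Numeric p x m matrix of fixed values / logical
#'   matrix marking free entries.
#' @param b,b_free m x m structural pattern (entry (i, j): coefficient of
#'   latent j in the equation of latent i).
#' @param psi,psi_free Symmetric m x m latent covariance pattern.
#' @param theta,theta_free Length-p error-variance pattern (diagonal).
#' @return An object of class `sem_template`.
#' @keywords internal
sem_template <- function(obs, lat, lambda, lambda_free, b, b_free,
                         psi, psi_free, theta, theta_free) {
  p <- length(obs); m <- length(lat)
  stopifnot(all(dim(lambda) == c(p, m)), all(dim(b) == c(m, m)),
            all(dim(psi) == c(m, m)), length(theta) == p)
  n_free <- sum(lambda_free) + sum(b_free) +
    sum(psi_free[lower.tri(psi_free, diag = TRUE)]) + sum(theta_free)
  if (n_free > p * (p + 1) / 2)
    stop("template is not identified: ", n_free, " free parameters exceed ",
         p * (p + 1) / 2, " observed moments")
  structure(list(obs = obs, lat = lat,
                 lambda = lambda, lambda_free = lambda_free,
                 b = b, b_free = b_free, psi = psi, psi_free = psi_free,
                 theta = theta, theta_free = theta_free),
            class = "sem_template")
}

## index table of free parameters: matrix block, row, col, label
.free_table <- function(tpl) {
  out <- list()
  lf <- which(tpl$lambda_free, arr.ind = TRUE)
  for (r in seq_len(nrow(lf)))
    out[[length(out) + 1L]] <- list(block = "lambda", i = lf[r, 1], j = lf[r, 2],
      label = paste0(tpl$lat[lf[r, 2]], "=~", tpl$obs[lf[r, 1]]))
  bf <- which(tpl$b_free, arr.ind = TRUE)
  for (r in seq_len(nrow(bf)))
    out[[length(out) + 1L]] <- list(block = "b", i = bf[r, 1], j = bf[r, 2],
      label = paste0(tpl$lat[bf[r, 1]], "~", tpl$lat[bf[r, 2]]))
  pf <- which(tpl$psi_free & lower.tri(tpl$psi_free, diag = TRUE), arr.ind = TRUE)
  for (r in seq_len(nrow(pf)))
    out[[length(out) + 1L]] <- list(block = "psi", i = pf[r, 1], j = pf[r, 2],
      label = paste0(tpl$lat[pf[r, 2]], "~~", tpl$lat[pf[r, 1]]))
  tf <- which(tpl$theta_free)
  for (i in tf)
    out[[length(out) + 1L]] <- list(block = "theta", i = i, j = i,
      label = paste0(tpl$obs[i], "~~", tpl$obs[i]))
  out
}

## fill template matrices from a free-parameter vector
.fill <- function(tpl, ft, par) {
  lambda <- tpl$lambda; b <- tpl$b; psi <- tpl$psi; theta <- tpl$theta
  for (k in seq_along(ft)) {
    f <- ft[[k]]
    switch(f$block,
      lambda = lambda[f$i, f$j] <- par[k],
      b      = b[f$i, f$j] <- par[k],
      psi    = { psi[f$i, f$j] <- par[k]; psi[f$j, f$i] <- par[k] },
      theta  = theta[f$i] <- par[k])
  }
  list(lambda = lambda, b = b, psi = psi, theta = theta)
}

## implied Sigma and reusable intermediates; NULL if (I-B) singular
.implied <- function(mats, m) {
  IB <- diag(m) - mats$b
  C <- tryCatch(solve(IB), error = function(e) NULL)
  if (is.null(C)) return(NULL)
  LC <- mats$lambda %*% C
  LCP <- LC %*% mats$psi
  sigma <- LCP %*% t(LC)
  diag(sigma) <- diag(sigma) + mats$theta
  list(sigma = sigma, LC = LC, LCP = LCP, LM = LCP %*% t(C))
}

## derivative vectors (u, w, c) per free parameter: dSigma = c*(u w' + w u')*2c?
## Convention: dSigma = u w' + w u' scaled so that rank-1 blocks use c = 1/2.
.deriv_vectors <- function(tpl, ft, imp) {
  p <- length(tpl$obs)
  k <- length(ft)
  U <- matrix(0, p, k); W <- matrix(0, p, k); cc <- rep(1, k)
  for (q in seq_along(ft)) {
    f <- ft[[q]]
    if (f$block == "lambda") {
      U[f$i, q] <- 1
      W[, q] <- imp$LM[, f$j]
    } else if (f$block == "b") {
      ## dSigma/dB_ij = (LC)_.i (LM)_.j' + transpose, from dC = C E_ij C
      U[, q] <- imp$LC[, f$i]
      W[, q] <- imp$LM[, f$j]
    } else if (f$block == "psi") {
      U[, q] <- imp$LC[, f$i]
      W[, q] <- imp$LC[, f$j]
      if (f$i == f$j) cc[q] <- 0.5
    } else {
      U[f$i, q] <- 1
      W[f$i, q] <- 1
      cc[q] <- 0.5
    }
  }
  list(U = U, W = W, c = cc)
}

## ML discrepancy and analytic gradient machinery
.sem_objective <- function(par, tpl, ft, S) {
  mats <- .fill(tpl, ft, par)
  imp <- .implied(mats, length(tpl$lat))
  if (is.null(imp)) return(list(f = 1e10))
  R <- tryCatch(chol(imp$sigma), error = function(e) NULL)
  if (is.null(R)) return(list(f = 1e10))
  siginv <- chol2inv(R)
  p <- length(tpl$obs)
  f <- 2 * sum(log(diag(R))) + sum(siginv * S) -
    attr(S, "logdet") - p
  list(f = f, imp = imp, siginv = siginv)
}

.sem_gradient <- function(par, tpl, ft, S) {
  ev <- .sem_objective(par, tpl, ft, S)
  if (is.null(ev$imp)) return(rep(0, length(par)))
  A <- ev$siginv - ev$siginv %*% S %*% ev$siginv
  dv <- .deriv_vectors(tpl, ft, ev$imp)
  2 * dv$c * colSums(dv$U * (A %*% dv$W))
}

#' Fit a linear SEM by maximum likelihood with sandwich standard errors
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma^-1) - log|S| - p`
#' by BFGS from documented start values (free loadings 1, error variances at
#' half the indicator variance, structural coefficients 0, latent variances
#' at half the anchor-indicator variance, covariances 0), followed by damped
#' Newton polishing. Standard errors are the sandwich `H^-1 I H^-1 / n`,
#' where `H` is the Hessian of the mean discrepancy and `I` the empirical
#' covariance of the per-observation score. The data are centered; no mean
#' structure is estimated.
#'
#' @param data Numeric matrix with columns (at least) the template's observed
#'   variables.
#' @param template An [sem_template()].
#' @param max_iter Iteration cap for the optimizer.
#' @return A list of class `qisem_fit` with `estimates`, `se` (named by
#'   parameter labels), `converged`, `n`, `fmin`, and the filled model
#'   matrices in `mats`.
#' @export
fit_linear_sem <- function(data, template, max_iter = 500L) {
  obs <- template$obs
  if (!all(obs %in% colnames(data)))
    stop("data lacks observed variables: ",
         paste(setdiff(obs, colnames(data)), collapse = ", "))
  Z <- scale(data[, obs, drop = FALSE], center = TRUE, scale = FALSE)
  n <- nrow(Z)
  p <- length(obs)
  ft <- .free_table(template)
  k <- length(ft)
  labels <- vapply(ft, `[[`, "", "label")
  bad <- function(msg) structure(list(
    method = "SEM", estimates = stats::setNames(rep(NA_real_, k), labels),
    se = stats::setNames(rep(NA_real_, k), labels),
    converged = FALSE, n = n, fmin = NA_real_, message = msg),
    class = "qisem_fit")
  if (n <= k) return(bad("sample smaller than number of free parameters"))
  S <- crossprod(Z) / n
  Rs <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(Rs)) return(bad("sample covariance not positive definite"))
  attr(S, "logdet") <- 2 * sum(log(diag(Rs)))

  ## start values
  vobs <- diag(S)
  start <- numeric(k)
  anchor <- integer(length(template$lat))      # anchor row per latent
  for (j in seq_along(template$lat)) {
    rows <- which(template$lambda[, j] != 0 | template$lambda_free[, j])
    anchor[j] <- if (length(rows)) rows[1] else 1L
  }
  for (q in seq_len(k)) {
    f <- ft[[q]]
    start[q] <- switch(f$block,
      lambda = 1,
      b = 0,
      psi = if (f$i == f$j) vobs[anchor[f$i]] / 2 else 0,
      theta = vobs[f$i] / 2)
  }

  fn <- function(par) .sem_objective(par, template, ft, S)$f
  gr <- function(par) .sem_gradient(par, template, ft, S)
  opt <- tryCatch(
    stats::optim(start, fn, gr, method = "BFGS",
                 control = list(maxit = max_iter, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt)) return(bad("optimizer failure"))
  par <- opt$par

  ## Newton polish toward a tight gradient norm
  for (it in 1:15) {
    g <- gr(par)
    if (max(abs(g)) < 1e-8) break
    H <- .num_hessian(gr, par)
    step <- tryCatch(solve(H + diag(1e-8, k), g), error = function(e) NULL)
    if (is.null(step)) break
    f0 <- fn(par)
    damp <- 1
    repeat {
      cand <- par - damp * step
      if (fn(cand) <= f0 + 1e-12) { par <- cand; break }
      damp <- damp / 2
      if (damp < 1e-4) break
    }
    if (damp < 1e-4) break
  }
  g <- gr(par)
  ev <- .sem_objective(par, template, ft, S)
  if (is.null(ev$imp)) return(bad("implied covariance degenerate at solution"))
  converged <- max(abs(g)) < 1e-6

  ## improper solutions: negative variances
  mats <- .fill(template, ft, par)
  if (any(mats$theta < -1e-8) || any(diag(mats$psi) < -1e-8))
    converged <- FALSE

  ## sandwich standard errors
  H <- .num_hessian(gr, par)
  dv <- .deriv_vectors(template, ft, ev$imp)
  Tm <- Z %*% ev$siginv
  base <- 2 * dv$c * colSums(dv$U * (ev$siginv %*% dv$W))
  SC <- (Tm %*% dv$U) * (Tm %*% dv$W)          # (t_i'u)(t_i'w) per obs/param
  SC <- sweep(SC, 2, 2 * dv$c, `*`)
  SC <- sweep(-SC, 2, base, `+`)               # score_ij = 2c(u'Sig^-1 w - ..)
  Imat <- crossprod(SC) / n
  Hinv <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(Hinv)) {
    se <- rep(NA_real_, k)
    converged <- FALSE
  } else {
    acov <- Hinv %*% Imat %*% Hinv / n
    se <- sqrt(pmax(diag(acov), 0))
  }
  structure(list(
    method = "SEM",
    estimates = stats::setNames(par, labels),
    se = stats::setNames(se, labels),
    converged = converged, n = n, fmin = ev$f,
    gradient_norm = max(abs(g)),
    mats = mats),
    class = "qisem_fit")
}

.num_hessian <- function(gr, par) {
  k <- length(par)
  H <- matrix(0, k, k)
  g0 <- gr(par)
  for (j in seq_len(k)) {
    h <- 1e-6 * (1 + abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    H[, j] <- (gr(pj) - g0) / h
  }
  (H + t(H)) / 2
}

#' @export
print.qisem_fit <- function(x, ...) {
  cat("Model fit (", x$method, "), n = ", x$n,
      ", converged: ", x$converged, "\n", sep = "")
  est <- data.frame(estimate = x$estimates, se = x$se)
  print(utils::head(est, 20))
  if (length(x$estimates) > 20) cat("  ...\n")
  invisible(x)
}
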