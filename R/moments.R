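#' Model-implied covariances of the jointly normal latent variables
#'
#' Solves the recursive linear part of the structural system exactly.
#' A latent is *normal* if it is exogenous, or if its defining equation is
#' purely linear and all of its predictors are themselves normal. Latents
#' whose own equation contains a product term are model-implied non-normal
#' and are excluded (their moments are available by simulation only).
#'
#' @param spec A `qisem_model`.
#' @return A symmetric covariance matrix over the normal latents,
#'   in topological order.
#' @export
linear_latent_cov <- function(spec) {
  normal <- character(0)
  cov <- matrix(0, 0, 0)
  allv <- c(spec$latents, spec$indicators)
  for (l in spec$order) {
    if (l %in% spec$exogenous) {
      normal <- c(normal, l)
      k <- length(normal)
      new <- matrix(0, k, k, dimnames = list(normal, normal))
      if (k > 1L) new[seq_len(k - 1L), seq_len(k - 1L)] <- cov
      new[k, k] <- spec$variances[.vkey(l, l, allv)]
      for (o in normal[normal %in% spec$exogenous & normal != l]) {
        v <- spec$variances[.vkey(l, o, allv)]
        if (!is.na(v)) new[l, o] <- new[o, l] <- v
      }
      cov <- new
      next
    }
    e <- spec$equations[[l]]
    if (any(!is.na(e$v2))) next                 # non-normal: own product term
    if (!all(e$v1 %in% normal)) next            # non-normal ancestor
    gam <- e$coef
    prd <- e$v1
    k <- length(normal) + 1L
    new <- matrix(0, k, k, dimnames = list(c(normal, l), c(normal, l)))
    new[seq_len(k - 1L), seq_len(k - 1L)] <- cov
    ## Cov(l, u) = sum_k gamma_k Cov(pred_k, u); residual orthogonal to ancestors
    for (u in normal) new[l, u] <- new[u, l] <- sum(gam * cov[prd, u])
    psi <- spec$variances[.vkey(l, l, allv)]
    new[l, l] <- drop(t(gam) %*% cov[prd, prd, drop = FALSE] %*% gam) + psi
    ## declared residual covariances with other endogenous normals
    for (o in normal[normal %in% spec$endogenous]) {
      v <- spec$variances[.vkey(l, o, allv)]
      if (!is.na(v)) {
        new[l, o] <- new[l, o] + v
        new[o, l] <- new[l, o]
      }
    }
    normal <- c(normal, l)
    cov <- new
  }
  cov
}

#' Means and covariances of latent product terms
#'
#' Applies the Isserlis (Wick) identities for centered jointly normal
#' variables: `E[AB] = Cov(A,B)`, `Cov(AB, CD) = Cov(A,C)Cov(B,D) +
#' Cov(A,D)Cov(B,C)`, and `Cov(AB, C) = 0`. All component latents must be
#' jointly normal with mean zero (see [linear_latent_cov()]).
#'
#' @param spec A `qisem_model`.
#' @param terms A list of character pairs (or a single pair), each naming the
#'   two factors of a product term; identical names give a quadratic term.
#' @return A list with `mean` (named numeric, one entry per product term,
#'   names are canonical term labels) and `cov` (covariance matrix of the
#'   product terms).
#' @export
product_moments <- function(spec, terms) {
  if (is.character(terms)) terms <- list(terms)
  lcov <- linear_latent_cov(spec)
  comp <- unique(unlist(terms))
  miss <- setdiff(comp, rownames(lcov))
  if (length(miss))
    stop("analytic product moments unavailable: ", paste(miss, collapse = ", "),
         " is not jointly normal (its equation contains a product term); ",
         "use simulation instead")
  if (any(vapply(comp, function(v) {
    mv <- spec$means[v]; !is.na(mv) && mv != 0
  }, TRUE)))
    stop("product moments assume centered (zero-mean) component latents")
  labs <- vapply(terms, function(p) term_label(p[1], p[2], spec), "")
  k <- length(terms)
  mn <- stats::setNames(vapply(terms, function(p) lcov[p[1], p[2]], 0), labs)
  cv <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) for (j in seq_len(i)) {
    a <- terms[[i]]; b <- terms[[j]]
    cv[i, j] <- cv[j, i] <- lcov[a[1], b[1]] * lcov[a[2], b[2]] +
      lcov[a[1], b[2]] * lcov[a[2], b[1]]
  }
  list(mean = mn, cov = cv)
}

## split an equation into linear / product parts with canonical labels
.equation_parts <- function(spec, latent) {
  e <- spec$equations[[latent]]
  if (is.null(e)) stop("'", latent, "' has no structural equation")
  lin <- e[is.na(e$v2), , drop = FALSE]
  prd <- e[!is.na(e$v2), , drop = FALSE]
  list(lin = lin, prd = prd,
       prd_terms = lapply(seq_len(nrow(prd)),
                          function(i) c(prd$v1[i], prd$v2[i])))
}

#' Exact model-implied variance of an endogenous latent
#'
#' `Var = gamma' Sigma_terms gamma + psi`, where the term covariance matrix
#' combines the linear-latent covariances with the Isserlis product moments;
#' linear and (centered) product terms of jointly normal variables are
#' uncorrelated, so the two blocks do not interact.
#'
#' @param spec A `qisem_model`.
#' @param latent Name of an endogenous latent.
#' @return The exact variance.
#' @export
endogenous_variance <- function(spec, latent) {
  ep <- .equation_parts(spec, latent)
  allv <- c(spec$latents, spec$indicators)
  psi <- spec$variances[.vkey(latent, latent, allv)]
  v <- psi
  if (nrow(ep$lin)) {
    lcov <- linear_latent_cov(spec)
    miss <- setdiff(ep$lin$v1, rownames(lcov))
    if (length(miss))
      stop("exact variance unavailable: predictor(s) ",
           paste(miss, collapse = ", "), " are not jointly normal")
    g <- ep$lin$coef
    v <- v + drop(t(g) %*% lcov[ep$lin$v1, ep$lin$v1, drop = FALSE] %*% g)
  }
  if (nrow(ep$prd)) {
    pm <- product_moments(spec, ep$prd_terms)
    g <- ep$prd$coef
    v <- v + drop(t(g) %*% pm$cov %*% g)
  }
  unname(v)
}

#' Residual variance that standardizes an endogenous latent
#'
#' Returns `1 - explained variance`, the structural residual variance that
#' makes the latent's total variance exactly 1 given the population
#' coefficients (the declared residual variance is ignored).
#'
#' @inheritParams endogenous_variance
#' @return The residual variance; errors if the explained variance is >= 1.
#' @export
residual_variance_for_unit_variance <- function(spec, latent) {
  allv <- c(spec$latents, spec$indicators)
  psi <- spec$variances[.vkey(latent, latent, allv)]
  explained <- endogenous_variance(spec, latent) - psi
  if (explained >= 1)
    stop("explained variance of '", latent, "' is ", signif(explained, 6),
         " >= 1; no positive residual variance standardizes it")
  unname(1 - explained)
}

#' Sequential explained-variance increment of a product term
#'
#' The share of an endogenous latent's total variance attributable to adding
#' `term` on top of `prior_terms`:
#' `[Var(gamma_t t + sum_prior) - Var(sum_prior)] / Var(latent)`.
#' Individual increments depend on the order in which terms are added
#' (through their covariances); the sum over a full ordering does not.
#'
#' @param spec A `qisem_model`.
#' @param latent Endogenous latent name.
#' @param term Character pair naming the product term's factors.
#' @param prior_terms List of character pairs already in the decomposition
#'   (default none).
#' @return The increment as a proportion of the latent's total variance.
#' @export
variance_increment <- function(spec, latent, term, prior_terms = list()) {
  if (is.character(prior_terms) && length(prior_terms))
    prior_terms <- list(prior_terms)
  ep <- .equation_parts(spec, latent)
  labs <- vapply(ep$prd_terms, function(p) term_label(p[1], p[2], spec), "")
  coefs <- stats::setNames(ep$prd$coef, labs)
  tl <- term_label(term[1], term[2], spec)
  pl <- vapply(prior_terms, function(p) term_label(p[1], p[2], spec), character(1))
  if (!(tl %in% labs) || !all(pl %in% labs))
    stop("term not in the equation of '", latent, "'")
  pm <- product_moments(spec, c(list(term), prior_terms))
  g_with <- coefs[c(tl, pl)]
  v_with <- drop(t(g_with) %*% pm$cov[c(tl, pl), c(tl, pl)] %*% g_with)
  v_prior <- if (length(pl)) {
    g <- coefs[pl]
    drop(t(g) %*% pm$cov[pl, pl, drop = FALSE] %*% g)
  } else 0
  unname((v_with - v_prior) / endogenous_variance(spec, latent))
}

#' Composite (sum-score) reliability of a latent's scale
#'
#' `(sum lambda)^2 Var(latent) / ((sum lambda)^2 Var(latent) + sum theta)`,
#' the reliability of the unweighted sum (equivalently mean) of the latent's
#' indicators.
#'
#' @param spec A `qisem_model`.
#' @param latent Latent name with at least one indicator.
#' @return Reliability in (0, 1].
#' @export
scale_reliability <- function(spec, latent) {
  m <- spec$measurement[[latent]]
  if (is.null(m) || !nrow(m)) stop("'", latent, "' has no indicators")
  allv <- c(spec$latents, spec$indicators)
  vlat <- if (latent %in% spec$exogenous) {
    spec$variances[.vkey(latent, latent, allv)]
  } else {
    lcov <- linear_latent_cov(spec)
    if (latent %in% rownames(lcov)) lcov[latent, latent]
    else endogenous_variance(spec, latent)
  }
  theta <- vapply(m$indicator, function(i) spec$variances[.vkey(i, i, allv)], 0)
  num <- sum(m$loading)^2 * vlat
  tot <- num + sum(theta)
  if (tot <= 0) stop("zero total scale variance for '", latent, "'")
  unname(num / tot)
}
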