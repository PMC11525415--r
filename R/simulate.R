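#' Simulate an indicator-level dataset from a population QISEM
#'
#' Data are generated equation by equation: exogenous latents are drawn
#' multivariate normal with the declared (co)variances, structural residuals
#' and measurement errors are drawn normal with the declared variances, and
#' each endogenous latent is built constructively in topological order as the
#' coefficient-weighted sum of its realized terms (products formed from the
#' raw realized latent values) plus its residual. Indicators are
#' `mean + loading * latent + error`. Endogenous latents downstream of a
#' product term are thereby model-implied non-normal.
#'
#' @param spec A `qisem_model`.
#' @param n Sample size (>= 1).
#' @param seed Integer seed; required, so that identical calls are
#'   bit-identical.
#' @param return_latents If `TRUE`, attach the realized latent scores as
#'   attribute `"latents"`.
#' @return An `n` by `p` numeric matrix of indicator values, columns in
#'   declaration order, with attribute `"seed"`.
#' @examples
#' spec <- parse_model(example_moderation_model())
#' x <- simulate_dataset(spec, n = 100, seed = 1)
#' dim(x)
#' @export
simulate_dataset <- function(spec, n, seed, return_latents = FALSE) {
  stopifnot(inherits(spec, "qisem_model"), n >= 1)
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for reproducible simulation")
  set.seed(as.integer(seed))
  allv <- c(spec$latents, spec$indicators)
  mu <- function(v) { m <- spec$means[v]; if (is.na(m)) 0 else m }

  lat <- matrix(0, n, length(spec$latents),
                dimnames = list(NULL, spec$latents))
  ## exogenous block: joint MVN
  if (length(spec$exogenous)) {
    phi <- .latent_block(spec, spec$exogenous)
    lat[, spec$exogenous] <- .rmvn(n, phi)
    for (v in spec$exogenous) lat[, v] <- lat[, v] + mu(v)
  }
  ## structural residuals: joint MVN over endogenous (declared covariances)
  if (length(spec$endogenous)) {
    psi <- .latent_block(spec, spec$endogenous)
    zeta <- .rmvn(n, psi)
    colnames(zeta) <- spec$endogenous
    for (l in spec$order[spec$order %in% spec$endogenous]) {
      e <- spec$equations[[l]]
      val <- rep(mu(l), n) + zeta[, l]
      for (i in seq_len(nrow(e))) {
        x <- if (is.na(e$v2[i])) lat[, e$v1[i]]
             else lat[, e$v1[i]] * lat[, e$v2[i]]
        val <- val + e$coef[i] * x
      }
      lat[, l] <- val
    }
  }
  ## measurement
  p <- length(spec$indicators)
  out <- matrix(0, n, p, dimnames = list(NULL, spec$indicators))
  theta <- vapply(spec$indicators,
                  function(i) spec$variances[.vkey(i, i, allv)], 0)
  eps <- matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(theta), p)
  j <- 0L
  for (l in names(spec$measurement)) {
    m <- spec$measurement[[l]]
    for (i in seq_len(nrow(m))) {
      j <- j + 1L
      out[, m$indicator[i]] <- mu(m$indicator[i]) +
        m$loading[i] * lat[, l] + eps[, j]
    }
  }
  attr(out, "seed") <- as.integer(seed)
  if (return_latents) attr(out, "latents") <- lat
  out
}

## MVN draw via Cholesky (pivoted for semidefinite blocks)
.rmvn <- function(n, sigma) {
  k <- ncol(sigma)
  if (k == 0L) return(matrix(0, n, 0))
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance block is not positive definite")
  matrix(stats::rnorm(n * k), n, k) %*% ch
}

#' Simulate a batch of datasets with independent substreams
#'
#' Each element gets its own seed derived deterministically from the master
#' seed, so individual datasets are reproducible regardless of the order (or
#' parallelism) in which they are generated.
#'
#' @param spec A `qisem_model`.
#' @param sizes Integer vector of sample sizes (nonempty).
#' @param seed Master integer seed (required).
#' @return A list of matrices as returned by [simulate_dataset()].
#' @export
simulate_batch <- function(spec, sizes, seed) {
  stopifnot(length(sizes) >= 1)
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for reproducible simulation")
  subseeds <- derive_seeds(seed, length(sizes))
  lapply(seq_along(sizes), function(i)
    simulate_dataset(spec, sizes[i], subseeds[i]))
}

#' Derive reproducible substream seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param k Number of substream seeds.
#' @return Integer vector of length `k`, a deterministic function of
#'   `(seed, k)` alone.
#' @export
derive_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}
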