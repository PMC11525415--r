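#' Allocate replications across adaptive-search steps
#'
#' Splits the replication budget `R` into positive per-step counts summing
#' exactly to `R`. `"equal"` gives `floor(R/steps)` with the remainder on
#' the last step; `"increasing"` makes `R_j` proportional to `j` (more
#' budget for the late, narrow steps); `"u_shaped"` makes `R_j` proportional
#' to `1 + |j - (steps + 1)/2|`.
#'
#' @param R Total replications (>= steps).
#' @param steps Number of steps.
#' @param distRj `"increasing"` (default), `"equal"` or `"u_shaped"`.
#' @return Integer vector of length `steps` summing to `R`.
#' @export
allocate_replications <- function(R, steps,
                                  distRj = c("increasing", "equal", "u_shaped")) {
  distRj <- match.arg(distRj)
  if (R < steps) stop("R must be at least the number of steps")
  w <- switch(distRj,
              equal = rep(1, steps),
              increasing = seq_len(steps),
              u_shaped = 1 + abs(seq_len(steps) - (steps + 1) / 2))
  r <- pmax(1L, floor(R * w / sum(w)))
  r[steps] <- r[steps] + (R - sum(r))
  if (r[steps] < 1L) {  # pathological tiny R: rebalance from the largest
    while (r[steps] < 1L) {
      i <- which.max(r[-steps]); r[i] <- r[i] - 1L; r[steps] <- r[steps] + 1L
    }
  }
  as.integer(r)
}

#' Draw sample sizes uniformly on an integer interval
#'
#' Sizes are distributed symmetrically around the interval midpoint in
#' expectation; a degenerate interval returns `count` copies of the single
#' value. Uses the current RNG state unless a `seed` is given.
#'
#' @param n_min,n_max Interval bounds (`n_min <= n_max`).
#' @param count Number of sizes.
#' @param seed Optional integer seed.
#' @return Integer vector of length `count` within `[n_min, n_max]`.
#' @export
draw_sizes <- function(n_min, n_max, count, seed = NULL) {
  if (n_min > n_max) stop("n_min must be <= n_max")
  lo <- as.integer(ceiling(n_min)); hi <- as.integer(floor(n_max))
  if (lo > hi)                       # sub-integer-width interval: collapse
    lo <- hi <- as.integer(round((n_min + n_max) / 2))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (lo == hi) return(rep(lo, count))
  lo + sample.int(hi - lo + 1L, count, replace = TRUE) - 1L
}

#' Artificial significance-decision backend
#'
#' Instead of simulating data and fitting a QISEM, draws each significance
#' decision directly from the probit (or logit) power curve,
#' `S ~ Bernoulli(linkinv(beta0 + beta1 sqrt(n)))`. Plugs into both search
#' drivers unchanged; used to study the search algorithms themselves at a
#' fraction of the cost of real model fits.
#'
#' @param beta0,beta1 Power-curve coefficients.
#' @param link `"probit"` (default) or `"logit"`.
#' @return A backend object for [run_adaptive()] / [run_brute_force()].
#' @export
make_artificial_backend <- function(beta0, beta1, link = "probit") {
  lk <- .linkfun(link)
  structure(list(
    pois = "poi",
    n_par = NULL,
    eval = function(ns, seeds) {
      ## vectorized: one substream per chunk (decisions are i.i.d. given n)
      set.seed(seeds[1])
      s <- stats::rbinom(length(ns), 1L, lk$inv(beta0 + beta1 * sqrt(ns)))
      list(records = data.frame(n = ns, converged = TRUE, poi = s),
           fits = NULL)
    }), class = "mspe_backend")
}

#' Simulate-and-fit backend for a population QISEM
#'
#' For each requested sample size, simulates a dataset from the population
#' model (independent substream per replication), fits it with the chosen
#' estimator and records the significance decisions for the parameters of
#' interest.
#'
#' @param spec A `qisem_model`.
#' @param method Estimator: `"SR"`, `"FSR"` or `"UPI"`.
#' @param pois Character vector of parameters of interest.
#' @param alpha Significance level of the parameter test.
#' @param test `"onesided"` or `"twosided"`.
#' @param keep_fits Keep the individual `qisem_fit` objects (needed for
#'   estimator performance summaries; default `TRUE`).
#' @return A backend object for the search drivers.
#' @export
make_qisem_backend <- function(spec, method, pois, alpha = 0.05,
                               test = "onesided", keep_fits = TRUE) {
  refs <- lapply(pois, resolve_poi, spec = spec)   # validates early
  structure(list(
    pois = vapply(refs, `[[`, "", "key"),
    spec = spec, method = method,
    eval = function(ns, seeds) {
      fits <- lapply(seq_along(ns), function(i) {
        x <- simulate_dataset(spec, ns[i], seeds[i])
        tryCatch(fit_qisem(x, spec, method),
                 error = function(e) structure(
                   list(method = method, estimates = numeric(0),
                        se = numeric(0), converged = FALSE, n = ns[i]),
                   class = "qisem_fit"))
      })
      rec <- significance_decisions(fits, pois, alpha = alpha, test = test,
                                    spec = spec)
      list(records = rec, fits = if (keep_fits) fits else NULL)
    }), class = "mspe_backend")
}

## fit power curves for every POI column; returns list (may contain errors)
.fit_all_pois <- function(records, pois, link, starts = NULL) {
  lapply(stats::setNames(pois, pois), function(p) {
    st <- if (!is.null(starts) && inherits(starts[[p]], "power_fit"))
      starts[[p]]$beta else NULL
    tryCatch(fit_power_model(records, p, link, start = st),
             error = function(e) e)
  })
}

## decisive fit: the POI with the largest required n among successful fits
.decisive_fit <- function(fits, rho) {
  ok <- Filter(function(f) inherits(f, "power_fit") && f$beta[2] > 0, fits)
  if (!length(ok)) return(NULL)
  ns <- vapply(ok, function(f) tryCatch(required_n(f, rho),
                                        error = function(e) NA_integer_), 0L)
  if (all(is.na(ns))) return(NULL)
  ok[[which.max(ns)]]
}

#' Brute-force selection of sample sizes
#'
#' Draws the `R` replication sample sizes from a user-given interval
#' `[n_min, n_max]` — systematically (an evenly spaced grid, each size
#' repeated `reps_per_size` times) or uniformly at random — evaluates the
#' backend once, fits the power curve to all decisions, and inverts it.
#'
#' @param backend A backend from [make_qisem_backend()] or
#'   [make_artificial_backend()].
#' @param config A config list from [search_config()]; must carry `n_min`
#'   and `n_max`.
#' @return An `mspe_result`.
#' @export
run_brute_force <- function(backend, config) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(config$n_min) || is.null(config$n_max))
    stop("brute-force search requires n_min and n_max")
  if (config$n_min >= config$n_max)
    stop("n_min must be smaller than n_max")
  R <- config$R
  seeds <- derive_seeds(config$seed, R + 1L)
  if (config$draw == "systematic") {
    k <- max(1L, config$reps_per_size)
    grid <- round(seq(config$n_min, config$n_max, length.out = ceiling(R / k)))
    ns <- rep(grid, each = k)[seq_len(R)]
  } else {
    ns <- draw_sizes(config$n_min, config$n_max, R, seed = seeds[R + 1L])
  }
  ns <- pmax(ns, 1L)
  ev <- backend$eval(ns, seeds[seq_len(R)])
  rec <- ev$records
  rec$step <- 1L
  .finalize_result(rec, ev$fits, backend, config,
                   history = data.frame(step = 1L, n_min = config$n_min,
                                        n_max = config$n_max, R_j = R,
                                        beta0 = NA, beta1 = NA,
                                        N_alpha_interim = NA),
                   t0 = t0)
}

#' Adaptive wide-to-narrow selection of sample sizes
#'
#' Implements the step-wise search: step 1 draws sizes on
#' `[n_start/2, 2 n_start]`; wide steps draw on the interval bracketing
#' estimated powers .15 to .85 (centered on the steepest part of the power
#' curve, power .5); from `switch_step` on, narrow steps draw between the
#' sample sizes where the upper and lower confidence bands cross the target
#' power. Every interval is clipped from below by `n_lb` and, with
#' `constrain_change`, each endpoint may change by at most a factor of 2
#' per step. Decisions are computed only for newly drawn sizes; every
#' power-curve fit uses all accumulated records. If a step's fit fails
#' (separation), the next interval doubles the previous one; the error is
#' raised only if it persists in the final fit.
#'
#' @inheritParams run_brute_force
#' @return An `mspe_result`.
#' @export
run_adaptive <- function(backend, config) {
  t0 <- proc.time()[["elapsed"]]
  R <- config$R; steps <- config$steps
  switch_step <- config$switch_step
  Rj <- allocate_replications(R, steps, config$distRj)
  seeds <- derive_seeds(config$seed, R + steps)
  rep_seeds <- seeds[seq_len(R)]
  draw_seeds <- seeds[R + seq_len(steps)]
  n_lb <- max(1, config$n_lb)

  records <- NULL
  all_fits <- list()
  history <- vector("list", steps)
  used <- 0L
  prev_lo <- prev_hi <- NULL
  dfit <- NULL
  fits_prev <- NULL

  for (j in seq_len(steps)) {
    if (j == 1L) {
      cand_lo <- config$n_start / 2
      cand_hi <- 2 * config$n_start
    } else if (is.null(dfit)) {
      ## separation fallback: double the interval toward the uninformative
      ## side (all significant -> smaller sizes, none -> larger sizes)
      rate <- mean(unlist(records[backend$pois]), na.rm = TRUE)
      if (is.nan(rate) || rate > 0.5) {
        cand_lo <- prev_lo / 2; cand_hi <- prev_hi
      } else {
        cand_lo <- prev_lo; cand_hi <- prev_hi * 2
      }
    } else if (j < switch_step) {
      cand_lo <- tryCatch(required_n(dfit, 0.15), error = function(e) prev_lo / 2)
      cand_hi <- tryCatch(required_n(dfit, 0.85), error = function(e) prev_hi * 2)
    } else {
      cand_lo <- .required_n_ub_band(dfit, config$rho, config$alpha_rho)
      cand_hi <- tryCatch(required_n_lb(dfit, config$rho, config$alpha_rho),
                          error = function(e) prev_hi * 2)
      if (is.na(cand_lo)) cand_lo <- prev_lo
    }
    if (config$constrain_change && j > 1L) {
      bound_lo <- prev_lo / 2
      bound_hi <- prev_hi * 2
    } else {
      bound_lo <- -Inf
      bound_hi <- Inf
    }
    n_min_j <- max(cand_lo, bound_lo, n_lb)
    n_max_j <- min(cand_hi, bound_hi)
    if (n_max_j < n_min_j) n_max_j <- n_min_j
    ns <- draw_sizes(n_min_j, n_max_j, Rj[j], seed = draw_seeds[j])

    idx <- used + seq_len(Rj[j])
    ev <- backend$eval(ns, rep_seeds[idx])
    chunk <- ev$records
    chunk$step <- j
    records <- if (is.null(records)) chunk else rbind(records, chunk)
    if (!is.null(ev$fits)) all_fits <- c(all_fits, ev$fits)
    used <- used + Rj[j]
    prev_lo <- n_min_j; prev_hi <- n_max_j

    fits_j <- .fit_all_pois(records, backend$pois, config$link,
                            starts = if (j > 1L) fits_prev)
    fits_prev <- fits_j
    dfit <- .decisive_fit(fits_j, config$rho)
    history[[j]] <- data.frame(
      step = j, n_min = n_min_j, n_max = n_max_j, R_j = Rj[j],
      beta0 = if (is.null(dfit)) NA_real_ else unname(dfit$beta[1]),
      beta1 = if (is.null(dfit)) NA_real_ else unname(dfit$beta[2]),
      N_alpha_interim = if (is.null(dfit)) NA_integer_
                        else tryCatch(required_n(dfit, config$rho),
                                      error = function(e) NA_integer_))
  }
  .finalize_result(records, all_fits, backend, config,
                   history = do.call(rbind, history), t0 = t0)
}

## common tail: final per-POI power fits, inversions, performance summary
.finalize_result <- function(records, fits, backend, config, history, t0) {
  pfits <- .fit_all_pois(records, backend$pois, config$link)
  err <- Filter(function(f) !inherits(f, "power_fit"), pfits)
  if (length(err))
    stop("power-curve fit failed for ", paste(names(err), collapse = ", "),
         ": ", conditionMessage(err[[1]]),
         " (widen the range of sample sizes or increase R)")
  N_alpha <- vapply(pfits, required_n, 0L, rho = config$rho)
  N_lb <- vapply(pfits, required_n_lb, 0L, rho = config$rho,
                 alpha_rho = config$alpha_rho)
  perf <- NULL
  if (length(fits) && !is.null(backend$spec))
    perf <- tryCatch(estimator_performance(fits, backend$spec),
                     error = function(e) NULL)
  structure(list(
    config = config,
    pois = backend$pois,
    records = records,
    power_fits = pfits,
    N_alpha = N_alpha,
    N_lb = N_lb,
    N_alpha_overall = max(N_alpha),
    N_lb_overall = max(N_lb),
    step_history = history,
    fits = fits,
    performance = perf,
    convergence_rate = mean(records$converged),
    elapsed = proc.time()[["elapsed"]] - t0,
    seed = config$seed),
    class = "mspe_result")
}

#' Search configuration
#'
#' Collects the hyperparameters of the sample-size search. Defaults mirror
#' the best-performing constellation of the adaptive algorithm: 10 steps,
#' switch from wide to narrow search at step 5, increasing per-step
#' replication counts, constrained interval change.
#'
#' @param R Total number of replications.
#' @param rho Target power (default .8).
#' @param alpha Significance level of the parameter test.
#' @param alpha_rho Type I error rate of the power-curve confidence band.
#' @param link Power model link, `"probit"` or `"logit"`.
#' @param steps Number of adaptive steps.
#' @param switch_step Step at which the search narrows (default `steps/2`).
#' @param distRj Replication allocation across steps.
#' @param constrain_change Limit interval-endpoint change to a factor of 2
#'   per step.
#' @param n_start Starting sample size (default `10 * #par`, supplied by the
#'   caller).
#' @param n_lb Smallest admissible sample size (default `5 * #par`).
#' @param n_min,n_max Brute-force interval.
#' @param draw Brute-force size selection, `"systematic"` or `"random"`.
#' @param reps_per_size Replications per grid point for systematic draws.
#' @param seed Master seed (required).
#' @return A list of class `search_config`.
#' @export
search_config <- function(R = 2000, rho = 0.8, alpha = 0.05, alpha_rho = 0.05,
                          link = c("probit", "logit"),
                          steps = 10L, switch_step = NULL,
                          distRj = c("increasing", "equal", "u_shaped"),
                          constrain_change = TRUE,
                          n_start = 150, n_lb = 50,
                          n_min = NULL, n_max = NULL,
                          draw = c("random", "systematic"),
                          reps_per_size = 1L, seed = NULL) {
  link <- match.arg(link)
  distRj <- match.arg(distRj)
  draw <- match.arg(draw)
  if (is.null(switch_step)) switch_step <- max(2L, floor(steps / 2))
  if (is.null(seed)) stop("a seed is required")
  stopifnot(R >= steps, n_lb >= 1, rho > 0, rho < 1,
            alpha > 0, alpha < 1, alpha_rho > 0, alpha_rho < 1)
  structure(list(R = as.integer(R), rho = rho, alpha = alpha,
                 alpha_rho = alpha_rho, link = link,
                 steps = as.integer(steps),
                 switch_step = as.integer(switch_step),
                 distRj = distRj, constrain_change = constrain_change,
                 n_start = n_start, n_lb = n_lb,
                 n_min = n_min, n_max = n_max, draw = draw,
                 reps_per_size = as.integer(reps_per_size),
                 seed = as.integer(seed)),
            class = "search_config")
}
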