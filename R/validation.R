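#' Monte-Carlo evaluation of a sample-size search algorithm
#'
#' Repeatedly runs a search on fresh artificial significance decisions and
#' summarizes the lower-bound required-sample-size estimates against a
#' reference value: `Bias = mean(N_lb - N_ref)`, `RMSE` the root mean
#' squared deviation, `Type I = fraction of repeats with N_lb < N_ref`, and
#' relative bias `Bias / N_ref`. Failed repeats (e.g. persistent separation)
#' are counted and excluded from the averages; both counts are reported.
#'
#' @param beta0,beta1 Population power-curve coefficients generating the
#'   artificial decisions.
#' @param config A [search_config()]; its `seed` is ignored in favour of
#'   per-repeat seeds derived from `seed`.
#' @param reps Number of Monte-Carlo repeats (>= 1).
#' @param N_ref Reference required sample size; default: the exact inversion
#'   of the generating coefficients at `config$rho`.
#' @param method `"adaptive"` or `"bruteforce"`.
#' @param seed Master seed for the repeats.
#' @return A list of class `search_performance` with `bias`,
#'   `relative_bias`, `rmse`, `type1`, `N_lb` (per-repeat values), `N_ref`,
#'   `reps`, `failed`.
#' @export
evaluate_search <- function(beta0, beta1, config, reps, N_ref = NULL,
                            method = c("adaptive", "bruteforce"), seed) {
  method <- match.arg(method)
  stopifnot(reps >= 1)
  if (is.null(N_ref))
    N_ref <- required_n(c(beta0, beta1), rho = config$rho, link = config$link)
  backend <- make_artificial_backend(beta0, beta1, config$link)
  seeds <- derive_seeds(seed, reps)
  nlb <- rep(NA_integer_, reps)
  for (i in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seeds[i]
    res <- tryCatch(
      if (method == "adaptive") run_adaptive(backend, cfg)
      else run_brute_force(backend, cfg),
      error = function(e) NULL)
    if (!is.null(res)) nlb[i] <- res$N_lb_overall
  }
  ok <- !is.na(nlb)
  dev <- nlb[ok] - N_ref
  structure(list(
    bias = mean(dev),
    relative_bias = mean(dev) / N_ref,
    rmse = sqrt(mean(dev^2)),
    type1 = mean(nlb[ok] < N_ref),
    N_lb = nlb,
    N_ref = N_ref,
    reps = reps,
    failed = sum(!ok)),
    class = "search_performance")
}

#' @export
print.search_performance <- function(x, ...) {
  cat("Search performance over", x$reps - x$failed, "completed repeats",
      if (x$failed) paste0("(", x$failed, " failed)") else "", "\n")
  cat(sprintf("  reference N: %d\n  bias: %.3f (relative %.4f)\n  rmse: %.3f\n  type I (N_lb < N): %.4f\n",
              x$N_ref, x$bias, x$relative_bias, x$rmse, x$type1))
  invisible(x)
}

#' Sample-size-weighted estimator performance
#'
#' Summarizes a batch of fitted replications against the population values:
#' per structural coefficient, the sample-size-weighted bias
#' `sum(n_i (est_i - pop)) / sum(n_i)` over converged fits, the weighted
#' relative bias in percent (coefficients with population value 0 are
#' excluded from the relative average), and the root weighted MSE
#' `sqrt(sum(n_i (est_i - pop)^2) / sum(n_i))`. Scalar aggregates are the
#' unweighted means over the structural coefficients. The convergence rate
#' counts converged fits over all fits.
#'
#' @param fits List of `qisem_fit` objects.
#' @param spec The population `qisem_model`.
#' @return A list of class `estimator_performance` with per-parameter tables
#'   and scalar `wBias`, `wRelBias` (percent), `rwMSE`, `convergence`.
#' @export
estimator_performance <- function(fits, spec) {
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  if (!any(conv)) stop("no converged fits")
  keys <- structural_parameters(spec)
  pop <- stats::setNames(unlist(lapply(spec$endogenous, function(l)
    spec$equations[[l]]$coef), use.names = FALSE), keys)
  n <- vapply(fits[conv], `[[`, 0, "n")
  est <- vapply(keys, function(k)
    vapply(fits[conv], function(f) f$estimates[[k]], 0), numeric(sum(conv)))
  est <- matrix(est, nrow = sum(conv),
                dimnames = list(NULL, keys))
  wbias <- vapply(keys, function(k)
    sum(n * (est[, k] - pop[k])) / sum(n), 0)
  rwmse <- vapply(keys, function(k)
    sqrt(sum(n * (est[, k] - pop[k])^2) / sum(n)), 0)
  nonzero <- keys[pop[keys] != 0]
  wrel <- 100 * wbias[nonzero] / pop[nonzero]
  structure(list(
    parameters = data.frame(parameter = keys, population = unname(pop[keys]),
                            wBias = unname(wbias),
                            rwMSE = unname(rwmse), row.names = NULL),
    wBias = mean(wbias),
    wRelBias = mean(wrel),
    rwMSE = mean(rwmse),
    wRelBias_by_parameter = wrel,
    convergence = mean(conv)),
    class = "estimator_performance")
}

#' @export
print.estimator_performance <- function(x, ...) {
  cat("Estimator performance (sample-size weighted)\n")
  print(x$parameters, digits = 4)
  cat(sprintf("  aggregate wBias %.4f, wRel-Bias %.2f%%, rwMSE %.4f, convergence %.3f\n",
              x$wBias, x$wRelBias, x$rwMSE, x$convergence))
  invisible(x)
}

#' Run a grid of search-evaluation conditions
#'
#' Reads a condition table (data frame or CSV file) with columns `beta0`,
#' `beta1`, `R` and optionally any [search_config()] field (`steps`,
#' `switch_step`, `distRj`, `constrain_change`, `n_start`, `n_lb`, `rho`,
#' `alpha_rho`) plus `method` (`"adaptive"`/`"bruteforce"`, with `n_min`,
#' `n_max` for the latter), evaluates each condition with
#' [evaluate_search()], and returns (optionally writes) the summary table.
#'
#' @param conditions Data frame or path to a CSV file.
#' @param reps Monte-Carlo repeats per condition.
#' @param seed Master seed; each condition gets a derived seed.
#' @param out Optional path for a CSV of the results.
#' @return A data frame: one row per condition with bias, relative bias,
#'   RMSE, Type I rate, failures.
#' @export
evaluate_search_grid <- function(conditions, reps, seed, out = NULL) {
  if (is.character(conditions)) conditions <- utils::read.csv(conditions)
  stopifnot(all(c("beta0", "beta1", "R") %in% names(conditions)))
  seeds <- derive_seeds(seed, nrow(conditions))
  cfg_fields <- c("R", "rho", "alpha", "alpha_rho", "steps", "switch_step",
                  "distRj", "constrain_change", "n_start", "n_lb",
                  "n_min", "n_max", "draw", "reps_per_size")
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- as.list(conditions[i, , drop = FALSE])
    args <- cond[intersect(names(cond), cfg_fields)]
    args <- args[!vapply(args, function(v) is.na(v) || is.null(v), TRUE)]
    args$seed <- seeds[i]
    cfg <- do.call(search_config, args)
    method <- if (!is.null(cond$method) && !is.na(cond$method)) cond$method
              else "adaptive"
    ev <- evaluate_search(cond$beta0, cond$beta1, cfg, reps = reps,
                          method = method, seed = seeds[i])
    data.frame(beta0 = cond$beta0, beta1 = cond$beta1, R = cond$R,
               method = method, N_ref = ev$N_ref, bias = ev$bias,
               relative_bias = ev$relative_bias, rmse = ev$rmse,
               type1 = ev$type1, failed = ev$failed, reps = reps)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  res
}
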