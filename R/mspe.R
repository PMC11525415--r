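#' Model-implied simulation-based power estimation
#'
#' The main driver. Parses the population model, simulates datasets at
#' search-selected sample sizes, fits each with the chosen estimator,
#' models the significance decisions of the parameters of interest by a
#' probit (or logit) regression on the square root of the sample size, and
#' inverts the fitted power curve for the required sample size at the
#' target power. The reported overall requirement is the maximum over the
#' parameters of interest — the parameter with the lowest power per sample
#' size decides the final required sample size.
#'
#' @param model Population model syntax (string), or a path to a file
#'   containing it.
#' @param poi Character vector of parameters of interest, e.g.
#'   `c("Eta1 ~ Xi1:Xi2")`.
#' @param method Estimator: `"SR"`, `"FSR"`, `"UPI"` (or `"LMS"`, which is
#'   rejected with an explanation — it needs the external Mplus program).
#' @param search_method `"adaptive"` (default) or `"bruteforce"`.
#' @param R Total number of simulated replications (default 2000).
#' @param power_aim Target power rho (default .8).
#' @param alpha Significance level of the parameter test (default .05).
#' @param alpha_power_modeling Type I error of the power-curve confidence
#'   band (default .05).
#' @param test `"onesided"` (default; directional in the sign of the
#'   population coefficient) or `"twosided"`.
#' @param power_modeling_method `"probit"` (default) or `"logit"`.
#' @param steps,switch_step,distRj,constrain_change Adaptive-search
#'   hyperparameters; see [search_config()].
#' @param n_start Starting sample size; default `10 * #par` with `#par` from
#'   [count_parameters()].
#' @param n_lb Smallest admissible sample size; default `5 * #par`.
#' @param n_min,n_max,draw,reps_per_size Brute-force settings.
#' @param seed Master seed (required). All randomness — size draws and
#'   per-replication simulation — derives from it through fixed substreams,
#'   so repeated runs are bit-identical regardless of evaluation order.
#' @param keep_fits Keep per-replication fit objects (for performance
#'   summaries).
#' @return An `mspe_result`: records, per-POI power fits, `N_alpha`,
#'   `N_lb`, overall values, step history, estimator performance.
#' @examples
#' \donttest{
#' res <- mspe(example_moderation_model(), poi = "Eta1 ~ Xi1:Xi2",
#'             method = "SR", R = 400, steps = 5, seed = 7)
#' res$N_lb_overall
#' }
#' @export
mspe <- function(model, poi, method = c("SR", "FSR", "UPI", "LMS"),
                 search_method = c("adaptive", "bruteforce"),
                 R = 2000, power_aim = 0.8, alpha = 0.05,
                 alpha_power_modeling = 0.05,
                 test = c("onesided", "twosided"),
                 power_modeling_method = c("probit", "logit"),
                 steps = 10L, switch_step = NULL,
                 distRj = c("increasing", "equal", "u_shaped"),
                 constrain_change = TRUE,
                 n_start = NULL, n_lb = NULL,
                 n_min = NULL, n_max = NULL,
                 draw = c("random", "systematic"), reps_per_size = 1L,
                 seed = NULL, keep_fits = TRUE) {
  method <- match.arg(method)
  search_method <- match.arg(search_method)
  test <- match.arg(test)
  if (identical(power_modeling_method, "Wald"))
    stop("power modeling method 'Wald' is not implemented; ",
         "use 'probit' or 'logit'")
  power_modeling_method <- match.arg(power_modeling_method)
  if (method == "LMS")
    stop("method 'LMS' requires the external Mplus program and is out of ",
         "scope; use 'UPI', 'FSR' or 'SR'")
  spec <- if (is.character(model) && length(model) == 1L &&
              !grepl("[\n=~]", model) && file.exists(model))
    parse_model(paste(readLines(model, warn = FALSE), collapse = "\n"))
  else parse_model(model)
  npar <- count_parameters(spec, method)
  if (is.null(n_start)) n_start <- 10L * npar
  if (is.null(n_lb)) n_lb <- 5L * npar
  cfg <- search_config(R = R, rho = power_aim, alpha = alpha,
                       alpha_rho = alpha_power_modeling,
                       link = power_modeling_method,
                       steps = steps, switch_step = switch_step,
                       distRj = distRj, constrain_change = constrain_change,
                       n_start = n_start, n_lb = n_lb,
                       n_min = n_min, n_max = n_max, draw = draw,
                       reps_per_size = reps_per_size, seed = seed)
  backend <- make_qisem_backend(spec, method, poi, alpha = alpha,
                                test = test, keep_fits = keep_fits)
  res <- if (search_method == "adaptive") run_adaptive(backend, cfg)
         else run_brute_force(backend, cfg)
  res$spec <- spec
  res$method <- method
  res$test <- test
  res
}

#' Reanalyze a fitted power analysis for new targets
#'
#' Refits the power curves from the stored significance records and
#' re-inverts them for a new target power and/or band level, without any
#' re-simulation.
#'
#' @param result An `mspe_result`.
#' @param rho New target power (default: the original).
#' @param alpha_rho New band Type I error (default: the original).
#' @param power_modeling_method Optionally refit under the other link.
#' @return The updated `mspe_result` (records unchanged).
#' @export
reanalyze <- function(result, rho = NULL, alpha_rho = NULL,
                      power_modeling_method = NULL) {
  stopifnot(inherits(result, "mspe_result"))
  cfg <- result$config
  if (!is.null(rho)) cfg$rho <- rho
  if (!is.null(alpha_rho)) cfg$alpha_rho <- alpha_rho
  if (!is.null(power_modeling_method))
    cfg$link <- match.arg(power_modeling_method, c("probit", "logit"))
  pfits <- .fit_all_pois(result$records, result$pois, cfg$link)
  err <- Filter(function(f) !inherits(f, "power_fit"), pfits)
  if (length(err))
    stop("power-curve fit failed for ", paste(names(err), collapse = ", "))
  result$config <- cfg
  result$power_fits <- pfits
  result$N_alpha <- vapply(pfits, required_n, 0L, rho = cfg$rho)
  result$N_lb <- vapply(pfits, required_n_lb, 0L, rho = cfg$rho,
                        alpha_rho = cfg$alpha_rho)
  result$N_alpha_overall <- max(result$N_alpha)
  result$N_lb_overall <- max(result$N_lb)
  result
}

#' Power-curve data for plotting or export
#'
#' @param result An `mspe_result`.
#' @param n Sample sizes at which to evaluate (default: 100 points spanning
#'   the observed range up to a little beyond `N_lb`).
#' @return A data frame with columns `poi`, `n`, `power`, `lower`, `upper`.
#' @export
power_curve <- function(result, n = NULL) {
  stopifnot(inherits(result, "mspe_result"))
  if (is.null(n)) {
    hi <- max(result$N_lb_overall * 1.2, max(result$records$n))
    n <- unique(round(seq(max(1, min(result$records$n)), hi,
                          length.out = 100)))
  }
  out <- lapply(names(result$power_fits), function(p) {
    pc <- predict_power(result$power_fits[[p]], n,
                        alpha_rho = result$config$alpha_rho)
    cbind(poi = p, pc)
  })
  do.call(rbind, out)
}

#' @export
print.mspe_result <- function(x, ...) {
  cat("MSPE power analysis",
      if (!is.null(x$method)) paste0("(", x$method, ")"), "\n")
  cat("  replications:", nrow(x$records),
      " convergence rate:", sprintf("%.3f", x$convergence_rate), "\n")
  cat("  target power:", x$config$rho,
      " alpha:", x$config$alpha, "\n")
  for (p in names(x$N_alpha))
    cat(sprintf("  %-24s N_alpha = %6d   N_lb = %6d\n",
                p, x$N_alpha[[p]], x$N_lb[[p]]))
  cat("  required sample size (overall N_lb):", x$N_lb_overall, "\n")
  invisible(x)
}

#' @export
summary.mspe_result <- function(object, ...) {
  print(object)
  if (!is.null(object$performance)) print(object$performance)
  invisible(object)
}

#' Base-graphics power-curve plot
#'
#' Draws the fitted power curve(s) with confidence band, the target power
#' and the recommended sample size.
#'
#' @param x An `mspe_result`.
#' @param se Draw the confidence band (default `TRUE`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mspe_result <- function(x, se = TRUE, ...) {
  pc <- power_curve(x)
  pois <- unique(pc$poi)
  graphics::plot(NA, xlim = range(pc$n), ylim = c(0, 1),
                 xlab = "sample size n", ylab = "power", ...)
  for (i in seq_along(pois)) {
    d <- pc[pc$poi == pois[i], ]
    if (se)
      graphics::polygon(c(d$n, rev(d$n)), c(d$lower, rev(d$upper)),
                        col = grDevices::adjustcolor(i, alpha.f = 0.15),
                        border = NA)
    graphics::lines(d$n, d$power, col = i, lwd = 2)
  }
  graphics::abline(h = x$config$rho, lty = 3)
  graphics::abline(v = x$N_lb_overall, lty = 3)
  if (length(pois) > 1L)
    graphics::legend("bottomright", legend = pois, col = seq_along(pois),
                     lwd = 2, bty = "n")
  invisible(x)
}
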