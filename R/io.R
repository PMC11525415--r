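#' Write a power-analysis result to disk
#'
#' Serializes an `mspe_result` as plain-text artifacts: `result.json`
#' (configuration echo, per-POI power-curve coefficients, required sample
#' sizes, convergence rate, seed and wall time), `records.csv` (one row per
#' replication: step, n, convergence, significance decisions),
#' `power_curve.csv` (n, power, lower, upper per POI) and
#' `step_history.csv` (adaptive intervals and interim fits).
#'
#' @param result An `mspe_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_mspe_result <- function(result, dir) {
  stopifnot(inherits(result, "mspe_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(json = file.path(dir, "result.json"),
             records = file.path(dir, "records.csv"),
             curve = file.path(dir, "power_curve.csv"),
             history = file.path(dir, "step_history.csv"))
  fits <- lapply(result$power_fits, function(f)
    list(link = f$link, beta = as.list(f$beta),
         vcov = unclass(f$vcov), n_records = f$n_records))
  payload <- list(
    config = result$config[!vapply(result$config, is.null, TRUE)],
    method = result$method,
    pois = result$pois,
    power_fits = fits,
    N_alpha = as.list(result$N_alpha),
    N_lb = as.list(result$N_lb),
    N_alpha_overall = result$N_alpha_overall,
    N_lb_overall = result$N_lb_overall,
    convergence_rate = result$convergence_rate,
    seed = result$seed,
    elapsed_seconds = result$elapsed)
  jsonlite::write_json(payload, paths["json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(result$records, paths["records"], row.names = FALSE)
  utils::write.csv(power_curve(result), paths["curve"], row.names = FALSE)
  utils::write.csv(result$step_history, paths["history"], row.names = FALSE)
  invisible(paths)
}

#' Read stored significance records
#'
#' Reads a `records.csv` written by [write_mspe_result()], e.g. to refit
#' power curves under new targets with [fit_power_model()].
#'
#' @param path Path to the CSV file.
#' @return A records data frame.
#' @export
read_mspe_records <- function(path) {
  utils::read.csv(path)
}
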