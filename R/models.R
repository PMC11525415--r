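#' Example population model: simple latent moderation
#'
#' A three-latent moderation model: `Eta1 ~ 0.2*Xi1 + 0.5*Xi2 +
#' 0.1*Xi1:Xi2`, standardized latents with `Cor(Xi1, Xi2) = .5` and
#' residual variance `.5975`, so the interaction contributes a variance
#' increment of 1.25% of `Var(Eta1) = 1` — a realistically small moderation
#' effect. Each latent is measured by `indicators` unit-loading indicators
#' whose error variances are set from the requested per-item reliability
#' (`theta = (1 - reliability) / reliability` for unit loadings and unit
#' latent variance).
#'
#' @param indicators Indicators per latent (default 3).
#' @param reliability Per-item reliability (default .8, a high-reliability
#'   setting; use .5 for a low-reliability variant).
#' @return Model syntax string for [parse_model()] or [mspe()].
#' @export
example_moderation_model <- function(indicators = 3L, reliability = 0.8) {
  stopifnot(indicators >= 1, reliability > 0, reliability <= 1)
  theta <- (1 - reliability) / reliability
  ind <- function(prefix, from) paste0(prefix, from + seq_len(indicators) - 1L)
  x1 <- ind("x", 1L); x2 <- ind("x", indicators + 1L); y1 <- ind("y", 1L)
  meas <- function(lat, inds) paste0(
    lat, " =~ ", paste0("1*", inds, collapse = " + "))
  errs <- function(inds) paste0(inds, " ~~ ", theta, "*", inds,
                                collapse = "\n")
  paste(
    "# simple latent moderation model",
    meas("Xi1", x1), meas("Xi2", x2), meas("Eta1", y1),
    "Eta1 ~ 0.2*Xi1 + 0.5*Xi2 + 0.1*Xi1:Xi2",
    "Xi1 ~~ 1*Xi1", "Xi2 ~~ 1*Xi2", "Xi1 ~~ 0.5*Xi2",
    "Eta1 ~~ 0.5975*Eta1",
    errs(x1), errs(x2), errs(y1),
    sep = "\n")
}

#' Example population model: moderated mediation
#'
#' A four-latent moderated-mediation model with two interaction effects:
#' `Eta1 ~ .2*Xi1 + .5*Xi2` and
#' `Eta2 ~ .2*Eta1 + .1*Eta1:Xi1 + .2*Xi1 + .3*Xi2 + .1*Xi1:Xi2`,
#' standardized latents (`Cor(Xi1, Xi2) = .5`, residual variances `.61` and
#' `.620975` make all latent variances exactly 1). `Xi1` moderates both the
#' direct `Xi2 -> Eta2` path and the mediated path through `Eta1`; the two
#' interactions contribute sequential variance increments of 1.25%
#' (`Xi1:Xi2`, added first) and 2.85% (`Eta1:Xi1`) of `Var(Eta2)`.
#' Measurement as in [example_moderation_model()].
#'
#' @inheritParams example_moderation_model
#' @return Model syntax string.
#' @export
moderated_mediation_model <- function(indicators = 3L, reliability = 0.8) {
  stopifnot(indicators >= 1, reliability > 0, reliability <= 1)
  theta <- (1 - reliability) / reliability
  ind <- function(prefix, from) paste0(prefix, from + seq_len(indicators) - 1L)
  x1 <- ind("x", 1L); x2 <- ind("x", indicators + 1L)
  y1 <- ind("y", 1L); y2 <- ind("y", indicators + 1L)
  meas <- function(lat, inds) paste0(
    lat, " =~ ", paste0("1*", inds, collapse = " + "))
  errs <- function(inds) paste0(inds, " ~~ ", theta, "*", inds,
                                collapse = "\n")
  paste(
    "# moderated mediation model, standardized latents",
    meas("Xi1", x1), meas("Xi2", x2), meas("Eta1", y1), meas("Eta2", y2),
    "Eta1 ~ 0.2*Xi1 + 0.5*Xi2",
    "Eta2 ~ 0.2*Eta1 + 0.1*Eta1:Xi1 + 0.2*Xi1 + 0.3*Xi2 + 0.1*Xi1:Xi2",
    "Xi1 ~~ 1*Xi1", "Xi2 ~~ 1*Xi2", "Xi1 ~~ 0.5*Xi2",
    "Eta1 ~~ 0.61*Eta1", "Eta2 ~~ 0.620975*Eta2",
    errs(x1), errs(x2), errs(y1), errs(y2),
    sep = "\n")
}

#' Perfect-measurement variant of the moderated mediation model
#'
#' Single error-free unit-loading indicator per latent: the indicators equal
#' the latent realizations, so every estimator reduces to the path model on
#' the true scores. Used as a consistency oracle.
#'
#' @return Model syntax string.
#' @export
moderated_mediation_model_perfect <- function() {
  paste(
    "Xi1 =~ 1*px1", "Xi2 =~ 1*px2", "Eta1 =~ 1*py1", "Eta2 =~ 1*py2",
    "Eta1 ~ 0.2*Xi1 + 0.5*Xi2",
    "Eta2 ~ 0.2*Eta1 + 0.1*Eta1:Xi1 + 0.2*Xi1 + 0.3*Xi2 + 0.1*Xi1:Xi2",
    "Xi1 ~~ 1*Xi1", "Xi2 ~~ 1*Xi2", "Xi1 ~~ 0.5*Xi2",
    "Eta1 ~~ 0.61*Eta1", "Eta2 ~~ 0.620975*Eta2",
    "px1 ~~ 0*px1", "px2 ~~ 0*px2", "py1 ~~ 0*py1", "py2 ~~ 0*py2",
    sep = "\n")
}
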