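---
title: "Simulation-based power analysis for latent interaction models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based power analysis for latent interaction models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mspepower)
```

## The problem

Structural equation models with latent interaction or quadratic terms
(QISEM) have no analytic power solution: the sampling distribution of an
interaction coefficient such as $\gamma$ in
$\eta = \gamma_1\xi_1 + \gamma_2\xi_2 + \gamma_3\xi_1\xi_2 + \zeta$
depends on the measurement model, the estimator, and higher-order moments of
the latent variables. The practical question — *how many participants do I
need for a power of .8 on the interaction?* — therefore has to be answered
by simulation.

The naive simulation approach estimates power pointwise at a handful of
user-chosen sample sizes. `mspepower` instead implements model-implied
simulation-based power estimation (MSPE): it simulates $R$ datasets at
varying sample sizes $n_i$, records for each replication the 0/1
significance decision $S_i$ of the parameter of interest, and models the
decisions parametrically,

$$\mathbb{P}(S_i = 1 \mid n_i) = \Phi(\beta_0 + \beta_1 \sqrt{n_i}),$$

a probit regression with $\sqrt{n}$ as the predictor (a logit link is
available as an option). The square-root predictor is not ad hoc: for any
asymptotically normal estimator, the $z$ statistic of a parameter with
population value $\vartheta_0$ drifts like $\sqrt{n}\,|\vartheta_0|/\sigma$,
where $\sigma^2$ is the asymptotic (sandwich) variance
$(\mathcal{H}^{-1}\mathcal{I}\mathcal{H}^{-1})_{jj}$, so the exact
large-sample power curve of a one-sided level-$\alpha$ test is
$\Phi(-q_{1-\alpha} + |\vartheta_0|/\sigma\cdot\sqrt{n})$. The probit
coefficients thus converge to $\beta_0 = -q_{1-\alpha}$ and
$\beta_1 = |\vartheta_0|/\sigma$; the package's test suite verifies this
limit on a one-sample $z$-test generator, for which both values are known
in closed form.

Inverting the fitted curve gives the required sample size for a target
power $\rho$:

$$\hat N_\alpha = \left\lceil \left(\frac{\Phi^{-1}(\rho) -
\hat\beta_0}{\hat\beta_1}\right)^2 \right\rceil ,$$

and, because $\hat\beta$ carries sampling error, the package also reports
$\hat N_{\alpha,\mathrm{lb}}$: the smallest $n$ whose *lower*
$1-\alpha_\rho$ confidence bound on the power reaches $\rho$. By
construction $\hat N_{\alpha,\mathrm{lb}} \ge \hat N_\alpha$, and it
exceeds the true requirement with probability roughly
$1-\alpha_\rho/2$ — a deliberate engineering margin against recommending an
underpowered study.

## Population models and simulation

The population model is written in a lavaan-dialect text syntax with
mandatory numeric population values (`Eta1 ~ 0.2*Xi1 + 0.1*Xi1:Xi2`,
`Xi1 ~~ 1*Xi1`, …). Free parameters are rejected: a population model that
cannot be simulated from is an error, and all variances — exogenous latent,
structural residual, and measurement error — must be stated. Quadratic
terms are written `Xi1:Xi1`; the product operator is order-insensitive.
Means default to zero and can be set via `Eta1 ~ 0.3*1`.

Data are generated *equation by equation*: exogenous latents and all
residuals are multivariate normal with the declared (co)variances, each
endogenous latent is built constructively from the realized values of its
terms (products are formed from raw realizations), and indicators add
normal measurement error. Endogenous variables downstream of a product term
are therefore model-implied non-normal, exactly as in the data a user will
eventually collect under this population. Non-normal exogenous
distributions, missing data and clustering are out of scope.

A closed-form moment engine accompanies the simulator. For jointly normal,
centered latents the Isserlis identities give
$\mathrm{Var}(AB) = \mathrm{Var}A\,\mathrm{Var}B + \mathrm{Cov}(A,B)^2$ and
$\mathrm{Cov}(AB, CD) = \mathrm{Cov}(A,C)\mathrm{Cov}(B,D) +
\mathrm{Cov}(A,D)\mathrm{Cov}(B,C)$, while products are uncorrelated with
linear terms. This yields exact endogenous variances, standardizing
residual variances, and explained-variance increments of interaction
terms — the quantities a user needs to pick realistic effect sizes. For
the bundled moderated-mediation example
(`moderated_mediation_model()`), the engine reproduces residual variances
.61 and .620975 and sequential variance increments of 1.25% and 2.85% for
the two interactions. Increments are defined *sequentially* in the order
terms are added; individual increments are order-dependent (the two
product terms covary), but their total is not, and both orderings are
computable. Products involving a latent whose own equation is nonlinear are
excluded from the analytic engine — joint normality fails — and are handled
by simulation only.

## Estimators

Three estimators fit each simulated dataset. All three return
heteroskedasticity-robust (sandwich) standard errors, and none of them is
allowed to abort a run: convergence failures and improper solutions are
flagged per replication and reported as a convergence rate.

* **SR (scale regression).** Scale means per latent are used as single
  indicators; products of the *centered* scale means form the nonlinear
  regressors; the recursive path model is fitted equation by equation by
  least squares with HC1 sandwich errors (via the `sandwich` package). SR
  ignores measurement error, so interaction coefficients are attenuated
  whenever indicators are fallible — the package's tests assert the
  direction of this bias rather than pretending it away.
* **FSR (factor score regression, SL variant).** A linear confirmatory
  factor model is fitted by ML; regression (Thomson) scores estimate the
  exogenous latents and Bartlett scores the endogenous ones; centered
  scores and their products enter the same path-model machinery.
* **UPI (unconstrained product indicators).** Product indicators are built
  by matching (i-th indicator with i-th indicator, squares for quadratic
  terms; the full cross product is available) with double mean centering,
  which removes the mean structure. The augmented linear SEM — one latent
  product factor per product term, all loadings, error variances and latent
  (co)variances free — is fitted by ML.

LMS, the distribution-analytic ML estimator for QISEM, requires the
external Mplus program; the method name is recognized and rejected with an
explanatory error.

The covariance-structure ML fitter behind FSR and UPI is part of the
package: it minimizes
$F(\theta) = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma(\theta)^{-1}) -
\log|S| - p$ over the LISREL-style parameterization
$\Sigma = \Lambda(I-B)^{-1}\Psi(I-B)^{-T}\Lambda' + \Theta$ using BFGS with
an analytic gradient, followed by damped Newton polishing. Start values are
loadings 1, error variances at half the indicator variance, structural
coefficients 0, latent variances at half the anchor-indicator variance.
Convergence requires a gradient maximum below 1e-6 after polishing (the
polish targets 1e-8; the looser declaration threshold acknowledges that
near-boundary solutions stall earlier, and 1e-6 is still orders of
magnitude below estimate noise at any realistic $n$). Negative estimated
variances mark the solution improper and the replication nonconverged.
Standard errors are the sandwich $H^{-1} I H^{-1}/n$ with $H$ the Hessian
of the mean discrepancy and $I$ the empirical score covariance, which the
test suite calibrates against replication SDs.

Identification conventions worth knowing:

* Multi-indicator latents are anchored by fixing the first declared
  indicator's loading at its population value (for the common `1*x1`
  declaration this is the usual fixed-1 convention), which keeps factor
  scores and structural coefficients on the population scale.
* Single-indicator latents fix both the loading and the error variance at
  their declared population values — a free pair is not identified with one
  indicator. A latent product factor measured by a single product indicator
  likewise fixes that indicator error-free. This makes the
  perfect-measurement limit exact, at the cost of assuming the declared
  reliability for single indicators.
* Matched product-indicator pairing follows declaration order, which keeps
  runs deterministic; covariances among multiple latent product factors are
  all free.

## Choosing the sample sizes: brute force and adaptive search

The quality of the inverted power curve depends on *where* the $n_i$ are
placed. Two drivers are provided.

**Brute force** draws the $R$ sizes from a user-given interval
$[n_\min, n_\max]$, either as an evenly spaced grid with a fixed number of
replications per size or uniformly at random. It is the right tool when
prior knowledge brackets the answer; when the requirement falls outside
the interval, extrapolation degrades.

**Adaptive search** needs no prior interval. The budget $R$ is split over
`steps` (default 10) steps, by default proportionally to the step index
(`distRj = "increasing"`), so late, well-informed steps get more
replications. Step 1 draws uniformly on $[n_{\rm start}/2,\, 2n_{\rm
start}]$. *Wide* steps ($2 \le j <$ `switch_step`, default `steps/2`)
re-fit the power curve on all accumulated decisions and draw uniformly
between the sizes with estimated power .15 and .85 — bracketing the
steepest, most informative part of the curve around power .5. *Narrow*
steps ($j \ge$ `switch_step`) draw between the sizes where the upper and
the lower confidence band cross the target $\rho$, i.e. the plausible
range of the answer itself. Intervals are clipped from below by
$n_{\rm lb}$, and with `constrain_change = TRUE` each endpoint may change
by at most a factor of 2 between steps, which keeps one noisy interim fit
from teleporting the search. If an interim fit separates (all decisions
equal), the next interval doubles toward the uninformative side — downward
when everything is significant, upward when nothing is — and only
persistent separation at the final fit is an error. Decisions are never
recomputed and never discarded; the final curve uses all $R$ records.

Defaults mirror the best-performing constellation found for this
algorithm: 10 steps, switch at 5, increasing $R_j$, constrained change.
For model-driven runs, $n_{\rm start} = 10\cdot\#\mathrm{par}$ and
$n_{\rm lb} = 5\cdot\#\mathrm{par}$, where $\#\mathrm{par}$ counts the free
parameters the chosen estimator actually fits (a path-model count for
SR/FSR; the augmented-SEM count for UPI). Uniform integer draws realize
"symmetric on the interval" in the simplest way; the spacing is on the raw
$n$ scale. The factor-2 change constraint is a tunable concretization of
"constrained relative change".

One deliberate choice: with several parameters of interest the interim
interval targeting uses the POI whose fitted curve currently implies the
largest required size (the weakest parameter), and the reported overall
requirement is the maximum of the per-POI $\hat N_{\alpha,\mathrm{lb}}$ —
the parameter with the lowest power decides.

## Reproducibility

Every run takes a master seed. Replication-level seeds and per-step draw
seeds are derived from it as fixed substreams, so a replication's dataset
depends only on (master seed, replication index) — results are
bit-identical across reruns and independent of evaluation order, which is
what makes parallel and serial execution interchangeable. The artificial
decision backend (`make_artificial_backend()`), which replaces
simulate-and-fit with direct Bernoulli draws from a known power curve,
vectorizes each step's draws under a single derived seed; it exists to
study the search algorithms themselves at roughly a thousandth of the cost
of real model fits.

## Validation harness and what the tests show

`evaluate_search()` reruns a search on fresh artificial decisions and
reports bias, relative bias, RMSE and the Type I rate
$\Pr(\hat N_{\alpha,\mathrm{lb}} < N_\alpha)$ against the known truth;
`estimator_performance()` summarizes fitted replications by sample-size
weighted bias, weighted relative bias (in percent, zero-valued parameters
excluded), root weighted MSE, and the convergence rate, with scalar
aggregates taken as unweighted means over the structural coefficients.
Repeats that fail outright are counted separately and excluded from the
averages.

The shipped acceptance checks run, among others: exact inversion of the
reference probit curves ($N_\alpha$ = 616 and 154 for slopes .1 and .2 at
$\rho = .8$); the exact variance decomposition of the moderated-mediation
example against a $10^6$-observation Monte-Carlo oracle; 2000-repeat
evaluations of the adaptive search at $R = 10^4$ against scaled reference
biases (4.32 and 16.53) with the undershoot rate checked against the
nominal $\alpha_\rho/2 = 2.5\%$ band; the closed-form probit limit on
$10^5$ $z$-test decisions within 2%; and perfect-measurement consistency,
attenuation direction, and SE calibration for the estimators. Problem
sizes (2000 repeats, $R = 10^4$, $n = 10^5$–$10^6$ oracles) are the
package's chosen balance between Monte-Carlo error and a test suite that
completes in minutes on a single core.

What passing these tests does *not* show: the synthetic generator draws
normal exogenous latents and errors, so nothing here certifies behavior
under skewed predictors, ordinal indicators, missing data, or misspecified
measurement models — all explicitly out of scope. Power estimated under
ideal distributional conditions is best read as a lower bound on the
required sample size.

## Worked example

```{r example, eval = FALSE}
res <- mspe(example_moderation_model(), poi = "Eta1 ~ Xi1:Xi2",
            method = "SR", R = 2000, seed = 2024)
res
plot(res, se = TRUE)
reanalyze(res, rho = 0.9)$N_lb_overall   # same records, new target
```

The bundled `example_moderation_model()` uses the printed residual variance
.5975 and interaction coefficient .1 (a 1.25% variance increment — a
realistically small moderation effect); loadings and per-item reliability
(default .8) are configuration, since reliability is the main driver of
required sample size and should be varied in any serious analysis.

## Known limitations

* LMS is absent, so the package cannot reproduce comparisons that hinge on
  full-information ML estimation of the nonlinear model.
* The analytic moment engine stops at second-order products of jointly
  normal latents.
* Only recursive (acyclic) structural systems are supported; no equality
  constraints, thresholds, or multi-group models.
* Power for *functions* of parameters (indirect effects) is not modelled;
  the decision machinery is per-coefficient.
* `required_n_lb` inverts one band construction (lower band crossing
  $\rho$); other readings of the lower-bound definition exist but are
  observationally close.
* The lower-bound recommendation is *conservative beyond its nominal level*
  when the power curve is steep: rounding the inverted size up to an
  integer adds roughly half a unit on a scale where the sampling SD of
  $\hat N_{\alpha,\mathrm{lb}}$ may be only two. In such regimes the
  undershoot rate $\Pr(\hat N_{\alpha,\mathrm{lb}} < N_\alpha)$ observed in
  the Monte-Carlo harness drops below the nominal $\alpha_\rho/2$ (e.g.
  ~0.5% instead of 2.5% at $N_\alpha = 154$ with $R = 10^4$), while for
  flatter curves ($N_\alpha = 616$) it is close to nominal. The error is
  in the safe direction — slightly larger recommended samples — and
  disappears as the target sample size grows.
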