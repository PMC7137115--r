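---
title: "Mapping to utility indices with censored normal mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping to utility indices with censored normal mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(utilmap)
```

## Why a censored mixture

Preference-based indices such as EQ-5D-3L, EQ-5D-5L and ICECAP-O make
poor regression targets. Their support is bounded by the tariff — in
England, `[-0.594, 1]`, `[-0.285, 1]` and `[0, 1]` respectively — with a
point mass at the ceiling of 1, marked skewness and multimodality, and,
for the EQ-5D family, a structural *gap* just below perfect health: the
next-best health state after 11111 scores 0.883 (EQ-5D-3L) or 0.951
(EQ-5D-5L), so no observation can fall strictly between that anchor and
1. A linear model fitted by least squares happily predicts into the gap
and outside the bounds; that failure is not a nuisance but a diagnostic,
and the package keeps an OLS baseline (`fit_linear()`,
`gap_violation_rate()`) precisely to expose it.

The adjusted limited dependent variable mixture model (ALDVMM) treats
the observed index as a finite mixture of latent normals seen through
the value set. For component $c$ with mean $x_i'\beta_c$ and scale
$\sigma_c$, and anchors $L$ (floor), $\Psi$ (gap anchor) and $U = 1$
(ceiling), an observation contributes

$$
g_c(y_i) =
\begin{cases}
1 - \Phi\!\left(\frac{\Psi - x_i'\beta_c}{\sigma_c}\right) & y_i = 1,\\[4pt]
\Phi\!\left(\frac{L - x_i'\beta_c}{\sigma_c}\right) & y_i = L,\\[4pt]
\frac{1}{\sigma_c}\,\phi\!\left(\frac{y_i - x_i'\beta_c}{\sigma_c}\right) & L < y_i \le \Psi,
\end{cases}
$$

and latent class membership follows a multinomial logit on covariates
$z_i$, $p_c(z_i) = \exp(z_i'\gamma_c) / \sum_k \exp(z_i'\gamma_k)$ with
the last component as reference ($\gamma_C \equiv 0$). The
log-likelihood is $\sum_i \log \sum_c p_c(z_i)\, g_c(y_i)$.

### Censoring conventions

Two conventions deserve explicitness because the model family admits
variants:

* **Gap rule.** Latent values strictly above $\Psi$ are observed as the
  ceiling; the open interval $(\Psi, 1)$ therefore has zero observable
  probability. This is the convention that makes the gap unobservable,
  which is its purpose. ICECAP-O has no gap ($\Psi = U = 1$) and is
  modelled with plain ceiling censoring.
* **Floor rule.** Latent values at or below $L$ are censored to a point
  mass at $L$, symmetrically with the ceiling, rather than truncated.
  Observed minima in realistic cataract cohorts sit above the tariff
  floors, so the two choices are indistinguishable on such data; the
  likelihood supports floor mass regardless, and the convention is
  recorded here rather than inferred from data.

A consequence worth noting: the closed-form prediction
$E[Y \mid x, z]$ (used by `predict()` and `predict_expected_value()`)
is a continuous function of covariates and **can** legitimately lie
inside the open gap for ceiling-heavy profiles, while always remaining
inside $[L, 1]$. Feasibility "by construction" therefore means:
predictions lie in the bounded range; *simulated* values — the model's
distributional output (`simulate()`, `simulate_from_fit()`) —
additionally place zero mass in the gap. The diagnostics and tests
check exactly these two statements, and apply the gap criterion to the
OLS comparator's point predictions, where predicting into the gap is
the documented failure mode.

## Estimation

`aldvmm()` maximises the log-likelihood by quasi-Newton ascent with an
analytic score (verified against central finite differences in the test
suite). Numerical choices that matter:

* **Staged starting values.** A constant-only model (intercept-only
  means and membership) is fitted first, initialised deterministically
  by slicing the sorted outcomes into quantile groups; its parameters,
  padded with zeros for covariate coefficients, start the full model.
  If a stage fails, a seeded random search (up to 20 restarts, scale
  0.5 perturbations of the staged start) takes over; a restart
  candidate only replaces the incumbent when it improves the
  log-likelihood, so a flat degenerate spike (a collapsed component
  with vanishing weight) can never displace a proper optimum.
* **Internal standardization.** Covariates are centred and scaled for
  optimisation and the estimates and covariance mapped back exactly
  through the linear reparameterisation. Utilities live on a unit scale
  while age is in years; without this the optimiser stalls on
  ill-conditioned Hessians.
* **Newton polish.** BFGS routinely terminates with a score max-norm
  around $10^{-2}$; a few damped Newton steps on the observed
  information push it below tolerance whenever the optimum is regular.
* **Convergence criteria.** Relative log-likelihood tolerance
  $10^{-10}$ inside the optimiser, and a scale-relative score
  criterion $\max_j |g_j| / (1 + |\ell|) < 10^{-5}$. The score
  criterion is relative because the log-likelihood and its gradient
  grow with $n$; an absolute gradient norm would mean different things
  at $n = 100$ and $n = 10{,}000$.
* **Scales on the log scale**, keeping the optimiser unconstrained;
  membership reference is the last component.
* **Covariance and honest non-convergence.** The covariance matrix is
  the inverse of the numerically differentiated observed information
  (differences of the analytic score). If the Hessian is not positive
  definite at the reported optimum — the signature of a collapsed or
  unidentified component — the fit is flagged `converged = FALSE`
  rather than silently accepted, and `information_criteria()` refuses
  to report AIC/BIC for it. Non-convergent specifications are
  first-class citizens of the grid: they are recorded, excluded from
  selection medians, and a pipeline run in which nothing converges
  completes with a report saying so.
* **Component labels.** After fitting, components are sorted by their
  mean linear predictor at the covariate means, healthiest first. The
  sort is a linear reparameterisation (membership logits re-expressed
  against the new reference), so the covariance matrix is transformed
  exactly rather than re-estimated; it is applied only after
  optimisation, never during, to avoid interfering with the search.
* **Degenerate inputs.** A cohort whose outcomes are all identical is
  rejected; missing values in any model column are an error directing
  the user to `complete_case_filter()`; infeasible outcomes (gap or
  out-of-range values) are rejected with the offending row.
* **Age enters linearly only**; the specification grid varies which
  covariates enter, not their functional form.

## The specification grid and selection rule

`build_specification_grid()` takes the Cartesian product of
mean-covariate subsets, membership-covariate subsets and component
counts; the disease-specific score is always present in both roles. The
default component set is `{2, 3}`: single-component models are dominated
in this model family and four-component mixtures rarely converge, so
both are allowed but off by default.

`select_model()` implements the published rule: among converged,
face-valid specifications in ascending RMSE order, pick the first whose
AIC, BIC or MAE is *strictly* lower than the median of that criterion
across all converged specifications. Interpretive choices: "better than
the median" is read as strictly better on each criterion's preferred
(lower) direction; medians are computed over converged rows only; ties
break by input order. When no row passes the gate the lowest-RMSE
converged face-valid row is returned with a warning; when no converged
row is face-valid the lowest-RMSE converged row is returned, also
flagged — selection degrades loudly, never silently.

"Face validity" — informally, predictions should not say that worse
vision means better quality of life — is operationalised as: mean
predictions across deciles of the source score are non-increasing
(equality allowed). `decile_calibration()` bins subjects into source
deciles with stable tie-breaking (bins partition the order statistics
exactly) and compares observed and predicted means with
normal-approximation intervals.

## The synthetic cohort generator

No patient-level data ship with the package; `cohort_scenario()` and
`simulate_cohort()` stand in for a pre/post cataract-surgery cohort of
older adults so that every downstream stage is testable.

What the generator emulates:

* covariate marginals of the published cohort — mean age 73.8 years
  (SD 8.2), truncated at the eligibility age of 50; 51% women; 19%
  diabetic;
* Cat-PROM5 marginals per time point: baseline mean −0.31 (SD 2.34,
  range −9.18 to 7.45) and follow-up mean −3.20 (SD 3.08, range −9.18
  to 4.98). The stated mean/SD are treated as *target moments of the
  truncated marginal*: the generator solves for the underlying normal
  parameters with closed-form truncated-normal moments, because at the
  follow-up range the truncation is strong enough to shift a naively
  parameterised mean by about 0.15;
* outcomes drawn from a known ALDVMM — the model's own data-generating
  process — so parameter recovery has a ground truth. The default
  truths (`default_true_params()`) are two-component sets per
  instrument, calibrated analytically so the implied ceiling mass lies
  in the 15–40% band that brackets the published "best value"
  proportions, with a healthy class near the ceiling, a broader morbid
  class, negative source-score coefficients in both components, and
  membership loaded negatively on the score.

What it deliberately does not emulate: dimension-level questionnaire
responses; correlation between covariates (none is published; an
optional diabetes shift on the outcome linear predictor is exposed
instead of guessing a dependence structure); within-subject correlation
between baseline and follow-up; and any multimodality in the source
score itself — downstream behaviour depends on the outcome model, not
the source-score shape. Tests passing on these cohorts therefore
demonstrate correctness of the machinery and recoverability under the
model's own assumptions, not robustness to misspecification on real
patients.

## Validation design and problem sizes

The test suite checks, among others: exact value-set anchors;
normalization of the censored component mass to 1 by quadrature over a
100-point $(\mu, \sigma)$ sweep per instrument; agreement of the
vectorised log-likelihood with an independently coded direct-summation
oracle to $10^{-10}$; recovery of the closed-form normal-regression MLE
to $10^{-6}$ when bounds are pushed far away; Wald-interval coverage of
all eight parameters of a known two-component truth over 50 replicates
at $n = 2000$; bias shrinkage between $n = 500$ and $n = 10{,}000$
(strict in aggregate, within Monte-Carlo allowance per parameter, since
several parameters are already nearly unbiased at $n = 500$); agreement
of closed-form expectations with $10^6$ simulated draws; feasibility of
every prediction and simulation across a 32-specification grid run at
$n = 500$; and dominance of the grid-selected mixture over the best OLS
baseline, with gap violations present for OLS and absent for the
mixture, across 20 seeded cohorts. These problem sizes keep the whole
suite in the minutes range while leaving Monte-Carlo error well inside
the asserted tolerances.

## Limitations

* The likelihood parameterisation (mass placed exactly at the anchors,
  floor censoring rather than truncation) is a stated convention;
  other software in this model family may differ in details that are
  unidentifiable on data without floor observations.
* Wald intervals rely on the observed information at an interior
  optimum; mixture likelihoods are multimodal and the global optimum is
  not guaranteed, despite staged starts and restarts.
* In-sample error metrics are used for selection, as no external
  validation sample exists in the intended application; RMSE-based
  selection can understate the merit of near-equivalent
  specifications.
* Beta-mixture components, Bayesian estimation, bootstrap standard
  errors and item-level source-score predictors are out of scope.
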