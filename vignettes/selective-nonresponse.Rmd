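---
title: "Simulating bias from selective non-response: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating bias from selective non-response: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(mnarsim)
```

## The question the pipeline answers

Longitudinal survey studies regress a later health outcome on earlier
risk factors. People with heavy health problems respond less often, and
because their (unobserved) outcome drives their non-response, the data
are missing not at random (MNAR). mnarsim quantifies, by Monte Carlo
simulation, how badly this distorts the estimated associations — and how
much of the distortion disappears when the study manages to keep *some*
extreme scorers in the sample rather than losing them entirely. That
contrast (extremes under-represented versus extremes totally missing) is
the pipeline's central comparison.

## Data-generating model

Each replication draws `n = 1000` units (the default; all sizes are
arguments). Predictors `x1`, `x2`, `x3` are normal with mean 0 and
variance 1.15, and the continuous latent health outcome is

$$y = 0.20\,x_1 + 0.30\,x_2 + 0.00\,x_3 + e,\qquad e \sim N(0, 1),$$

so that `Var(y) = 0.13 * 1.15 + 1 = 1.1495` — every study variable has
(essentially) the same total variance of 1.15, chosen so the residual
variance of `y` is exactly 1 and coefficients stay comparable across
variables. `x3` has no direct effect on the outcome: it exists as an
extra predictor of non-response and as the auxiliary variable handed to
FIML and MI.

Two structural quantities are not pinned down by the study design and
are exposed as parameters with documented defaults:

* **`rho_x3` (default 0.10, against `x1`).** The third covariate is
  meant to be weakly related to one of the two risk factors; "weak" is
  not quantified, so we fix a small nonzero default and leave the value
  (including 0) configurable for sensitivity runs.
* **`rho_x12` (default 0).** The two risk factors are treated as
  independent unless the user says otherwise.

Predictors are drawn with the exact population covariance as
*distribution* parameters; drawn samples are never rescaled. Population
properties (variance 1.15, the threshold anchors below) are population
statements, and per-sample moments are allowed to fluctuate as they
would in a real survey.

## Non-response liability

Non-response is governed by a latent liability

$$L = b_0 + b_{non1}(x_1 + x_2 + x_3) + b_{non2}\,y + e_L,$$

with `Var(e_L)` set to `1.15 - Var(systematic part)`, computed from the
full theoretical covariance of `(x1, x2, x3, y)` — including the y–x
covariances — so that `Var(L) = 1.15` in every condition
(`liability_variance()` exposes the decomposition and rejects
combinations that would need a negative residual variance). The study
grid uses the same `b_non1` for all three predictors by design.

Units with the largest realized liability go missing on the outcome
(predictors are always fully observed):

* **Under-represented extremes** (`extremes_removed = FALSE`): the
  `ceiling(n * (1 - response_rate))` units with the largest `L` are
  missing. The implied population cut is 0.52 SD above the mean of `L`
  for a 70% response rate and the mean itself for 50%.
* **Extremes totally missing** (`extremes_removed = TRUE`): the top 10%
  of realized `y` is forced missing first (a population cut of 1.28 SD
  above the mean), and the liability cut is then calibrated so the
  *total* missing count still equals the target — reproducing cuts near
  0.84 SD (70% response) and 0.25 SD (50%) when the dependency is weak,
  and adapting automatically as the overlap between the two criteria
  grows with stronger dependencies.

Two design choices deserve explanation:

* **Realized values, not linear predictors.** Thresholds are applied to
  the realized `L` and `y`. Only this reading makes the stated cuts
  consistent with the stated rates (`pnorm(0.52) ≈ 0.70`; 1.28 SD marks
  the top decile of a normal variable). The deterministic part of `L`
  alone has smaller variance, and cutting it at 0.52 SD would not give
  30% non-response.
* **Rank-based per-sample calibration.** Cuts are implemented as
  empirical quantiles (equivalently, selection of the top-k by rank,
  ties broken by position), so the achieved missingness fraction is
  *exact* in every sample, matching a design in which both rates are
  fixed by construction. For the extremes-removed mechanism this
  one-pass rank selection replaces any iterative threshold search: mark
  the top decile of `y`, then mark the `k` remaining units with the
  largest `L`. The result is identical to calibrating the `L` cut until
  the union has the target size, and it cannot fail to converge. SD
  units in reported thresholds always refer to the theoretical SDs
  (`sqrt(1.15)` for `L`, `sqrt(1.1495)` for `y`).

## Ordinal measurement

The observed scale cuts the continuous outcome at thresholds expressed
in SD units of `y` and anchored to the *theoretical* mean 0 and SD
`sqrt(1.1495)` — the instrument is calibrated to the population trait,
not to whoever happened to respond. Presets: 4 categories at
(-1, 0, +1) SD, 5 at (-1, -0.5, +0.5, +1), 2 at the mean. Intervals are
right-closed — a value exactly one SD below the mean lands in the bottom
category — a measure-zero convention fixed for determinism. Follow-up
analyses can skip categorization entirely
(`ordinal_spec(continuous = TRUE)`) and use linear regression.

## Estimators

All ordinal analyses are ordered probit regressions of the observed
category on `x1` and `x2` with the latent residual variance fixed to 1,
matching the generating model: the true standardized coefficients are
therefore exactly 0.20 and 0.30, and bias can be read directly against
them.

**Standardization.** Raw probit coefficients live on the latent-response
scale `u* = Xb + e`. We report

$$b_s = b\;\mathrm{SD}(x)\,/\,\mathrm{SD}(u^*),\qquad
  \mathrm{SD}(u^*) = \sqrt{b^\top V(x)\,b + 1},$$

with `V(x)` the joint sample covariance of the predictors over the rows
entering the fit — complete cases for CC, all rows for FIML and MI,
which is how SEM software computes standardized solutions from the
analysis sample. Under selective non-response the responders' predictor
variance shrinks, and this correctly feeds through to the standardized
estimate. Standard errors are scaled by the same per-coefficient factor
`SD(x_j)/SD(u*)`; the sampling variability of the scale factor itself is
deliberately ignored. This first-order scaling is an approximation, kept
because it mirrors how the replicated SE columns behave; a full delta
method (propagating the dependence of `SD(u*)` on `b`) gives materially
smaller SEs and correspondingly lower coverage, and is *not* what the
replicated coverage columns reflect. Confidence intervals are Wald,
`estimate ± 1.96 SE`, on the standardized scale; the coverage metric
uses these bounds.

**Complete cases (CC).** `MASS::polr(method = "probit")` on rows with an
observed outcome. A category with no complete cases left (possible in
5-category runs at 50% response) is collapsed into its neighbour for
that fit and the event noted on the fit object. If the default starting
values fail, the fit restarts from marginal-frequency thresholds.

**FIML with an auxiliary variable.** Maximum likelihood over *all* rows
for the joint model

$$u^* = b_1 x_1 + b_2 x_2 + u,\quad
  x_3 = a_0 + a_1 x_1 + a_2 x_2 + v,\quad
  \mathrm{cor}(u, v) = r,$$

with `u ~ N(0,1)` cut at the thresholds. Rows with an observed category
contribute the density of `x3` times the ordinal probability conditional
on `x3` (a conditional-normal mean shift `r (x3 - mu3)/sigma_v` and
residual SD `sqrt(1 - r^2)`); rows with a missing outcome contribute the
marginal density of `x3` only. The residual correlation `r` is the
channel through which the auxiliary informs the missing outcomes. The
likelihood is maximized by `nlminb` over an unconstrained
parameterization (log threshold increments, `log sigma_v`, `atanh r`)
from a complete-case + least-squares start with a neutral fallback
start; standard errors come from the numerically differentiated Hessian
at the optimum. This saturated-correlates-style construction is the
standard auxiliary-variable formulation when missingness is confined to
the outcome; its estimates track CC closely in the MNAR conditions here,
as they should, since both are MAR-based answers to an MNAR problem.

**Multiple imputation by predictive mean matching.** The ordinal codes
are imputed directly (the analysis-model variable), with `x1`, `x2`,
`x3` as imputation predictors. Each of `m` draws (default 50) takes a
proper Bayesian draw of the linear-regression coefficients and residual
variance among observed rows, matches each missing unit's predicted mean
(under the drawn coefficients) to the five observed donors with closest
predicted means (under the posterior-mean coefficients; donor pool size
configurable), and borrows a uniformly sampled donor's observed
category — so imputed values are always legal categories. Each completed
data set is fit by the same ordered probit, standardized per data set,
and pooled by Rubin's rules (mean of estimates; within + `(1 + 1/m)`
between variance) on the standardized scale. A data set whose probit
fails to converge is dropped and counted; more than 20% dropped marks
the pooled fit non-converged. With nothing missing the function returns
the CC fit unchanged.

**Linear complete cases.** For the continuous follow-up, OLS of `y` on
`x1`, `x2` among responders; coefficients are already on the population
scale and are reported unstandardized.

## Metrics

For each scenario, converged replications are aggregated into the mean
estimate, mean SE,

$$\text{relative bias} = 100\,(b_{true} - \bar b_s)/b_{true}$$

(positive = attenuation; computed on the mean estimate, which by
linearity equals the mean of per-replication biases), and 95% coverage
(share of CIs containing the truth). The headline decomposition is

$$\text{preventable bias} = 100\,(R_1 - R_2)/R_1,$$

with `R1` the relative bias when extremes are totally missing and `R2`
when they are present; it is reported as `NA` when `R1 = 0` — there is
nothing to prevent — never as a number. `x3`'s null coefficient is never
used as a bias denominator.

## Replication machinery

`run_scenario()` derives one seed per replication from
`(base_seed, scenario id, replication index)` via a 31-bit string hash,
so results are independent of execution order and of how work might be
scheduled across processes; an identical configuration reproduces every
number byte-for-byte. All randomness inside a replication (sample,
liability noise, imputation draws) runs under that one seed. The full
factorial (`study_grid()`) crosses six dependency pairs
`(b_non1, b_non2)` — (0.3, 0), (0.1, 0.1), (0.3, 0.1), (0, 0.3),
(0.1, 0.3), (0.3, 0.3) — with response rates 70%/50% and both
missingness mechanisms; `followup_grid()` repeats the 50% conditions
with 5-category, 2-category and continuous outcomes, complete cases
only (the follow-ups probe the outcome scale, and CC is the estimator
whose bias the contrast isolates; the MAR methods add nothing under
MNAR, as the main grid shows). Scenario draws are independent across
scenarios — nothing is reused between conditions, the conservative
reading of drawing fresh samples per population.

## Numerical choices

* Probit convergence is delegated to `polr`'s BFGS with a
  marginal-frequency restart; FIML uses `nlminb` at `rel.tol = 1e-10`
  with two starts. Independent-optimizer oracles in the test suite pin
  both optima to within 1e-4.
* Rank ties (liability, top decile) break by position
  (`ties.method = "first"`): ties are probability-zero events, the rule
  just fixes determinism.
* `ceiling(n * (1 - response_rate))` is guarded against floating-point
  representation of the rate (`1 - 0.7` is slightly above 0.3).
* Non-converged fits are excluded from aggregation and counted in
  `n_converged`.

## What the generator does and does not emulate

The generator reproduces the study conditions faithfully: multivariate
normal traits, a single cross-sectional outcome, missingness only in
the outcome, exact response rates, a liability linear in the study
variables. Real cohorts violate most of these in some way — skewed or
heavy-tailed outcomes, measurement error in predictors, missingness in
predictors, longitudinal wave-by-wave attrition, liability
non-linearity. Passing tests therefore demonstrate correctness of the
pipeline and of the qualitative mechanism (total absence of extreme
scorers is far more damaging than under-representation; dependency
strength drives bias), not that the specific percentages transfer to
any particular real study.

## Problem sizes used by the test suite

The suite exercises the headline conditions at the full scale of 500
replications of n = 1000 (complete-case runs take seconds per
scenario). The three-estimator agreement check runs at 100 replications
with 10 imputations — Monte Carlo error of a mean at that scale is
about 0.004, comfortably below the 0.015 agreement band — with the full
setting (m = 50, 500 replications) remaining the documented default of
`mi_settings()` and `scenario()`. Moment checks against closed forms
use single samples of n = 1e6.

## Known limitations

* The FIML auxiliary model assumes `x3` is linearly related to the
  predictors with a normal residual — true here by construction, an
  approximation elsewhere.
* The standardized-SE scaling ignores scale-factor variability (see
  above); coverage is interpretable relative to that convention.
* PMM with a small donor pool on a coarse scale can slightly attenuate
  pooled estimates in small samples; at the default n = 1000 the effect
  is well below Monte Carlo error.
* `prevention_percentage` is unstable when `R1` is near zero; the grid
  reports it as computed and leaves near-zero-denominator cells to the
  reader's judgement.
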