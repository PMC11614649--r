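---
title: "Population pharmacokinetics of quetiapine: model, estimation and dose simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of quetiapine: model, estimation and dose simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quetipk)
```

## The problem

Quetiapine is dosed against a recommended therapeutic window of 100–500
ng/mL. Its clearance is strongly affected by body weight and by
coadministration of CYP inhibitors — fluvoxamine (CYP3A4) and duloxetine
(CYP2D6) — so a starting dose that is right for one patient can be far off
for another. `quetipk` implements the full population-pharmacokinetic (PPK)
workflow used to quantify those effects from sparse therapeutic drug
monitoring (TDM) data and to translate them into initial-dose
recommendations: structural model, nonlinear mixed-effects estimation,
stepwise covariate selection, bootstrap validation, goodness-of-fit
diagnostics, and Monte Carlo probability-of-target-attainment (PTA)
simulation. Because the underlying hospital TDM data are not public, the
package ships a synthetic-cohort generator that reproduces the *statistical
structure* of such data, making every stage of the pipeline testable.

## Structural and statistical model

Concentrations follow a one-compartment model with first-order absorption
and elimination, parameterised by apparent clearance CL/F (L/h), apparent
volume V/F (L) and absorption rate constant Ka, fixed at 1.46 h⁻¹ (a
literature value; sparse TDM data cannot identify it). Bioavailability F is
absorbed into the apparent parameters. After a dose D at time 0,

$$C(t) = \frac{1000\,D}{V/F}\,\frac{K_a}{K_a-k_e}\left(e^{-k_e t}-e^{-K_a t}\right),
\qquad k_e = \frac{CL/F}{V/F},$$

in ng/mL (the mg/L → ng/mL factor of 1000 is applied at exactly one place
in the code). Repeated dosing uses linear superposition; steady state has
the usual closed form with accumulation factors $1/(1-e^{-k\tau})$. When
$|K_a-k_e|/K_a < 10^{-8}$ the analytic limit
$1000\,(D/V)\,K_a\,t\,e^{-K_a t}$ replaces the indeterminate general
expression.

Between-subject variability is a single log-normal random effect on
clearance, $CL_i = CL_{\mathrm{typ},i}\,e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$; V/F and Ka carry no random effect (the sparse
design cannot support more). Residual error is combined proportional plus
additive: $D_{ij} = F_{ij}(1+\varepsilon_{1,ij}) + \varepsilon_{2,ij}$, so
$\mathrm{Var}(D|F) = \sigma_1^2 F^2 + \sigma_2^2$.

The covariate model of the final quetiapine analysis is

$$CL/F = 118 \times (WT/70)^{0.75}\,(1-0.536\,\mathrm{FLU})\,(1-0.537\,\mathrm{DUL}),
\qquad V/F = 2460 \times (WT/70),$$

i.e. fixed allometric weight scaling (exponents 0.75 and 1) and
categorical-linear comedication effects on clearance. Relative clearance
under the four comedication conditions is 1, 0.464, 0.463 and 0.214832.
These values, with $\omega^2 = 0.333$, $\sigma_1^2 = 0.267$,
$\sigma_2^2 = 29.917$, are the package defaults
(`population_model()`).

**Variance-scale convention.** The published variability values carry no
units. We interpret them as *variances* (the NONMEM OMEGA/SIGMA default);
`population_model(..., variability_scale = "sd")` switches to the
standard-deviation reading. The choice matters: as variances they imply a
58% CV of clearance and a 52% proportional residual CV; as SDs, 33% and
27%. The dose-simulation section returns to this.

## Estimation: FOCE-I with an exact Laplace curvature

`fit_model()` minimises an approximate $-2\log$ marginal likelihood. For
each subject the conditional objective

$$l_i(\eta) = \sum_j\left[\frac{(d_{ij}-f_{ij}(\eta))^2}{g^2_{ij}(\eta)}
+ \ln g^2_{ij}(\eta)\right] + \frac{\eta^2}{\omega^2}$$

(with $g^2$ evaluated at the *individual* predictions — the "interaction")
is minimised over $\eta$ by a safeguarded Newton iteration with a grid +
golden-section fallback, warm-started across outer iterations. The subject
contribution is then the Laplace approximation at the mode
$\hat\eta_i$:

$$\mathrm{OFV}_i = l_i(\hat\eta_i) + \ln\omega^2 + \ln\!\left(\tfrac{1}{2}l_i''(\hat\eta_i)\right),$$

computed stably as $l_i(\hat\eta) + \log(1+\tfrac{1}{2}\omega^2 D_i)$ where
$D_i$ is the curvature of the data part. The $n\ln 2\pi$ constant is
omitted (NONMEM convention), so likelihood-ratio thresholds 3.84 / 6.63
apply to OFV differences unchanged, and at $\omega^2 \to 0$ the OFV reduces
exactly to the fixed-effects heteroscedastic $-2\log L$.

We use the *exact* (finite-difference) curvature $D_i$ rather than the
Gauss–Newton surrogate $\sum_j (\partial f/\partial\eta)^2/g^2$. On the
sparse design this package targets (1–2 observations per subject, large
$\omega$), we compared both against an exact marginal likelihood computed
by dense quadrature over $\eta$: the Gauss–Newton form overestimated the
typical clearance by 15–20%, while the exact-curvature Laplace form tracked
the quadrature estimates within a few percent. The Gauss–Newton curvature
is retained only as a fallback when the exact curvature is non-positive.

The outer optimisation is a bounded quasi-Newton (`nlminb`) on transformed
parameters: log scale for $\theta_{CL}$, $\theta_V$ and all variances;
$\log(1+p)$ for categorical-linear coefficients (keeping clearance
positive); identity for power exponents. Convergence requires a fixed
point: a restart from the optimum must change the OFV by `< 1e-6`
(relative) and parameters by `< 1e-4`. Standard errors come from a central
finite-difference Hessian of the OFV at the optimum
($\widehat{\mathrm{Cov}} = 2H^{-1}$); a non-positive-definite Hessian
yields `NA` SEs with a warning, never fabricated values. Fitting is fully
deterministic given data and initial values.

## Covariate selection, bootstrap, diagnostics

`stepwise_covariate_search()` implements the classic forward/backward OFV
search: a candidate enters if it lowers the OFV by more than 3.84
(χ², 1 df, p < 0.05) — the largest qualifying drop first, ties within 1e-6
to the earlier-declared candidate — and a forward-selected covariate
survives backward elimination only if its deletion raises the OFV by more
than 6.63 (p < 0.01). Binary covariates enter linearly; continuous ones as
a power of the covariate centred at its population median. Failed candidate
fits are skipped and logged in the decision trace.

`bootstrap_model()` resamples *subjects* (preserving each subject's event
history) with replacement to the original subject count, refits each
replicate warm-started at the original estimates, and summarises converged
replicates by the median, the 5th–95th percentile interval (reported as a
90% CI) and the relative bias $(\mathrm{median}-\mathrm{estimate})\times
100/\mathrm{estimate}$. Non-converged replicates are excluded and counted.
The replicate count defaults to 1000 (tests use 100–200).

`gof_predictions()` returns PRED (population prediction, $\eta=0$), IPRED
(at the conditional mode) and iWRES $=(DV-\mathrm{IPRED})/g(\mathrm{IPRED})$;
`wres_fo()` returns the classic first-order WRES (population residuals
decorrelated by the Cholesky factor of $G\omega^2G' + \mathrm{diag}(g^2)$
with $G$ evaluated at $\eta=0$); `vpc()` produces binned observed
percentiles with across-replicate simulation bands.

**Calibration caveat.** At this model's own variability (52% proportional
CV, $\omega$ SD 0.58) the first-order machinery is visibly strained: the
conditional mode is pulled below the data by the $\ln g^2(\eta)$ term, so
mean iWRES sits near +0.13 rather than 0, and the FO-WRES variance inflates
to ≈1.4 (this is precisely why CWRES was later introduced; it is noted as
an extension). Both quantities calibrate correctly at moderate variability
(e.g. WRES variance 1.00 at $\omega^2=0.05$), which is what the test suite
asserts; the inflation at full variability is asserted too, as documented
behaviour rather than hidden.

## Synthetic cohorts: the stated world

`generate_cohort()` emulates the source study's design: 96 subjects, ~154
concentrations (each subject contributes 1 or 2, mean 154/96), weight
drawn from Normal(70.88, 16.84²) kg truncated to 40–120 kg (the simulation
span; note the truncated mean is 72.1 kg), fluvoxamine and duloxetine
flags at prevalence 2/96 each, and demographic columns (age, sex, albumin,
creatinine at the reported cohort moments) that carry *no* effect — they
exist as true-negative candidates for the covariate search. Maintenance
dosing defaults to 600 mg/day split q12h for 7 days (past steady state for
a ~14 h half-life); observations are steady-state troughs (TDM practice),
uniform within the final dosing intervals, or "mixed" (one sample in the
first dosing interval, the rest at steady state). Observations are drawn
as $d = f(1+\varepsilon_1)+\varepsilon_2$; negative draws are handled by
redrawing the residual *pair* — redrawing only the additive term cannot
rescue a draw with $1+\varepsilon_1<0$, which occurs with probability
~2.6% per observation at these variances — and the redraw count is logged.

Two generator choices deserve emphasis. First, the *sampling-time policy*
is the main identifiability dial: with trough-only data V/F is barely
identified (the source analysis itself reported a 33.5% SE and a bootstrap
CI of [1222, 5163] L), whereas a single absorption-phase sample per
subject (the "mixed" policy) makes the ±15% recovery of V/F achievable.
Recovery tests therefore use "mixed"; the default remains "trough" because
that is what real TDM data look like. Second, at a fixed number of
subjects the recovery error of the typical clearance is floored by the
realized mean of the 96 subject-level $\eta$s (≈6% SD), so additional
observations per subject improve V/F and error-model recovery but not
$\theta_{CL}$ — the tests encode exactly that.

A green recovery test therefore establishes: the estimator is consistent
with its own generative model under the stated design, with the stated
prevalences boosted to 25% (2/96 subjects cannot identify a comedication
effect). It does not establish anything about the real hospital data,
which are not available.

## Dose simulation and recommendations

`simulate_virtual_patients()` follows the published simulation layout:
1000 virtual patients per cell over weights {40, 60, 80, 100, 120} kg,
daily doses {1, 4, 8, 12, 16, 20, 24, 28} mg/kg/day and the four
comedication conditions; attainment is the fraction of patients inside
100–500 ng/mL and exceedance the fraction above 500 ng/mL.
`recommend_doses()` picks, per condition and weight, the attainment-argmax
dose (ties within 0.5 percentage points resolved toward the lower dose)
and merges contiguous weights sharing a dose into ranges.

The published description leaves the dosing interval, the evaluated
concentration metric and the treatment of residual error unspecified, and
these choices move the PTA numbers materially. All three are explicit
switches in `simulation_design()`; the default policy is q12h dosing,
steady-state trough, between-subject variability on, residual error off.
The acceptance suite emits the full recommendation table under three
policies (q12h trough, q24h trough, q12h average concentration) and
*reports* agreement with the published dose table instead of gating on it;
only the ordering properties are asserted (exceedance non-decreasing in
dose; recommended doses under fluvoxamine/duloxetine/both no higher than
without, with "both" lowest). For the record: under the variance reading of
$\omega^2=0.333$ the q24h-trough policy reproduces the published doses
best; a back-of-envelope log-normal calculation suggests the published
94–97% attainment figures are most consistent with the
standard-deviation reading of $\omega$, which is one more reason both
readings are supported.

## Numerical choices

* Inner $\eta$ search: Newton with finite-difference derivatives
  (step 1e-5), backtracking line search, fallback to a 0.1-step grid on
  [-8, 8] plus golden section; modes warm-started between outer
  iterations. Non-converged subjects are flagged, not raised.
* Laplace curvature: central differences with step 1e-3 (chosen so the
  curvature noise, ~1e-8 of the OFV, stays below the outer optimiser's
  tolerance).
* Outer bounds ±30 on the transformed scale; hitting a bound sets the
  `boundary` flag and vetoes `converged` (this catches degenerate inputs
  such as a single subject with flat data, where $\sigma^2$ components
  collapse).
* Percentiles: linear interpolation between order statistics
  (`quantile` type 7) throughout.
* All stochastic stages (generation, bootstrap resampling, VPC, PTA) take
  explicit seeds and restore the caller's RNG state; fitting itself is
  deterministic.

## Known limitations

* One compartment, no lag time, no inter-occasion variability, single
  random effect: adequate for sparse TDM, not for rich profiles.
* FOCE-type approximations retain a few percent bias on very sparse
  designs even with the exact curvature; the exact-quadrature check used
  in development is the reference if that matters.
* FO-WRES (not CWRES) is the implemented weighted residual, with the
  inflation at large $\omega$ documented above.
* Table-level reproduction of the published PTA probabilities is bounded
  by the under-specified simulation policy; the package treats them as
  soft targets under documented policies.
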