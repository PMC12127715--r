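---
title: "Competing-risks screening for small-for-gestational-age neonates: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competing-risks screening for SGA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgascreen)
```

## The screening problem

A small-for-gestational-age (SGA) neonate — birth weight below the 10th or
3rd percentile for gestational age at delivery — is at elevated risk of
stillbirth and perinatal morbidity, and most candidate interventions (aspirin
prophylaxis, intensified surveillance) must start in the first trimester.
First-trimester screening therefore asks: given what is known at the 11–13
weeks scan — maternal characteristics and history, the uterine artery
pulsatility index (UtA-PI), serum PAPP-A and serum PlGF — what is this
pregnancy's risk of delivering an SGA neonate before a given gestational age?

The competing-risks formulation treats the outcome not as a binary label but
as a point in the plane of gestational age at delivery $g$ and birth-weight
Z-score $z$. "SGA below percentile $p$ delivered before week $c$" is then a
rectangle $\{z < \Phi^{-1}(p)\} \times \{g < c\}$, and one fitted joint
distribution yields risks for *every* percentile/cut-off pair at once — the
practical advantage over fixed logistic regressions, which need a separate
equation per outcome definition.

## Model

**Prior.** Given a maternal profile, $(g, z)$ is bivariate Gaussian,

$$(g, z) \sim N_2\big(\mu_g + \Delta_g(\text{profile}),\;
\mu_z + \Delta_z(\text{profile});\; \sigma_g, \sigma_z, \rho\big),$$

truncated to the support $g \in [24, 43]$ weeks, $z \in [-5, 5]$. The shifts
$\Delta_g, \Delta_z$ are additive effects of maternal-factor indicators
(parity, smoking, chronic hypertension, diabetes, SLE/APS, conception mode,
previous PE/SGA/stillbirth).

**Likelihood.** Each measured biomarker is first converted to a multiple of
the median (MoM): the raw value divided by the expected median for that
woman's covariates, with the expectation modelled on the log10 scale as a
reference value plus additive covariate terms. Conditional on the outcome,
$\log_{10}\text{MoM} \sim N(\mu_b(g, z), \sigma_b)$ where $\mu_b$ is a
continuous *folded plane*: zero at and beyond the knot $(g_0, z_0) = (40, 0)$
(unaffected term pregnancies have expected MoM 1) and linear in
$(g_0 - g)_+$ and $(z_0 - z)_+$ below it. UtA-PI rises, PAPP-A and PlGF fall,
as delivery gets earlier and the neonate smaller.

**Posterior and risk.** Bayes' theorem multiplies the prior by the likelihood
of whatever biomarkers the record carries — records missing a biomarker simply
omit its factor, which is how the nested reporting combinations (maternal
factors only, +UtA-PI, +PAPP-A, +PlGF) arise. The posterior is evaluated on a
dense grid ($g$ step 0.05 weeks, $z$ step 0.02) and rectangle risks are
trapezoidal integrals with linear interpolation in the final partial cell.
Halving both grid steps changes risks by less than $10^{-4}$ (tested). The
likelihood product is accumulated in log space; the vectorized cohort path
exponentiates directly (the unnormalized log posterior is bounded far inside
double range for any plausible record) and falls back to a max-subtracting
per-record path if a denominator degenerates.

## Parameters and defaults

All parameters live in a single `crp_params` object (JSON round-trip via
`write_params()`/`read_params()`). The shipped defaults are **synthetic
stand-ins**, not transcriptions of published coefficients: the published
model's full parameterization lives in its original references, and shipping
approximations under the same names would create transcription risk without
making the pipeline any more correct. What the defaults *are* calibrated to is
the published cohort description (next section), which is what the package's
validation logic needs.

| parameter | default | units / meaning |
|---|---|---|
| $\mu_g$, $\sigma_g$ | 39.68, 1.37 | baseline GA at delivery (weeks) |
| $\mu_z$, $\sigma_z$ | 0.295, 0.667 | baseline birth-weight Z |
| $\rho$ | 0.023 | residual $(g,z)$ correlation |
| UtA-PI plane | $-0.030/w$, $-0.065/z$, $\sigma = 0.12$, knot $(37, -1.2)$ | log10 MoM |
| PAPP-A plane | $+0.018/w$, $+0.060/z$, $\sigma = 0.26$, knot $(37, -1)$ | log10 MoM |
| PlGF plane | $+0.045/w$, $+0.050/z$, $\sigma = 0.16$, knot $(37, -1)$ | log10 MoM |

Plane slopes and SDs were chosen once for field-realistic signs and
magnitudes: PlGF carries the strongest gestational-age signal (so it adds most
for very preterm SGA), PAPP-A is noisy relative to its tilt (so it adds
little over UtA-PI), matching the qualitative pattern reported in validation
studies. The knots sit below term (37 weeks) and below mild smallness
($z \approx -1$) rather than at $(40, 0)$: the biomarker tilt applies only to
clinically small or preterm outcomes. This keeps the population median MoM of
each biomarker inside $[0.97, 1.03]$ — the "distribution of MoM around 1"
that a well-specified MoM model must show — which a knot at $(40, 0)$ cannot
do, because more than half of all pregnancies would then sit on the tilted
part of the plane and the population median MoM would drift to 0.93–1.07.

## The synthetic-cohort generator

The generator emulates a 35 170-pregnancy multicenter European screening
population: maternal marginals (median age 32.7 years, weight 63.5 kg, height
164 cm, 53.9% nulliparous, 11.6% smokers, 90.7% natural conceptions, ...),
log-normal families for weight and interpregnancy interval, normal for age
and height, truncated to plausible ranges; the outcome model above used
generatively; biomarkers drawn from the folded-plane likelihoods and mapped
back to raw units through the MoM regressions; pre-eclampsia co-assigned from
conditional rates; and nested biomarker availability (UtA-PI in 50.8%, PlGF
in a nested 27.8%, missing completely at random).

### Calibration

`calibrate_generator()` solves for the outcome parameters so that the
analytic mixture-of-truncated-Gaussians probabilities match the reference
incidences: SGA<10th 14.5%, SGA<3rd 6.0%, SGA<10th before 37/32 weeks
2.0%/0.4%, SGA<3rd before 37/32 weeks 1.3%/0.3%, median GA at delivery 39.5
weeks, and an overall preterm rate of 6% (a typical European figure; the
reference publication does not print its preterm rate, and pinning it keeps
the solution epidemiologically sensible). Inner layers solve the GA median
(1-D root) and the two SGA marginals (damped Levenberg–Marquardt — the two
tail equations are nearly collinear in $(\mu_z, \sigma_z)$ under a wide
mixture, so plain Newton is unstable) exactly; the outer layer least-squares
the joint incidences over $(\sigma_g, \rho, \lambda_g, \lambda_z, \kappa)$,
where $\lambda_g, \lambda_z$ scale fixed maternal effect *shapes* and
$\kappa$ couples severity to prematurity. The solved optimum reproduces every
target within ±0.001 absolute and is shipped as the package default (also the
solver's warm start, so re-solving takes seconds and is deterministic).

The effect shapes are chosen, once, on epidemiological grounds, and the
printed incidences force a *polarized* preterm stratum: severe placental
disease (chronic hypertension, SLE/APS, previous stillbirth) drives early
**and** very small; previous PE drives early but normally grown; smoking and
previous SGA drive small but hardly earlier. Without that polarization no
parameter setting reproduces the observed severity gradient among preterm
SGA (two thirds of preterm SGA<10th are also <3rd, versus 41% overall).

### PE co-labels

PE enters the validation only through the "SGA without PE" stratification, so
it is a label, not a mechanism: the four conditional rates
$P(\text{PE} \mid \text{preterm} \times \text{SGA10})$ are derived
analytically from the reference counts (655 PE; 211 preterm, 136 of them SGA;
444 term, 99 SGA) and the generator's joint outcome probabilities, which
reproduces the overall (1.9%) and preterm (0.6%) PE rates in expectation.

### What the generator does and does not emulate

It matches the reference cohort's *printed* marginals, incidences and
nested-availability pattern, and — because generator and engine share one
parameter object — makes screening a generated cohort a genuine
self-consistency experiment (risks are true conditional probabilities, so
calibration slope/intercept converge to 1/0). It does **not** emulate:
site/analyzer heterogeneity; gestational-age-dependent biomarker precision;
the real left-skewed GA-at-delivery distribution (the Gaussian margin matches
the median and the preterm-SGA joints, but its interquartile range is wider
than the reference 38.6–40.4 and the very-preterm tail is carried by
exaggerated subgroup shifts — e.g. chronic hypertension at $-6.4$ weeks —
rather than by within-group skewness); outcome-dependent missingness; or
real-world model misspecification. Passing self-consistency tests therefore
demonstrates the *machinery* is correct, not that any particular published
parameterization is externally valid.

## Evaluation statistics

* **Detection rate at fixed FPR**: the threshold is the smallest control risk
  $t$ with $\Pr(\text{control} \ge t) \le$ FPR (ties broken toward lower
  realized FPR); DR is the fraction of cases at or above $t$; Wilson score
  95% CI.
* **AUC**: Mann–Whitney pair probability with ties counted ½, DeLong 95% CI
  (via pROC); verified against brute-force pair counting in tests.
* **Calibration**: slope is the coefficient of logistic regression of outcome
  on logit(risk); the intercept is calibration-in-the-large — the constant of
  the same regression with the slope fixed at 1 (logit risk as offset). The
  jointly-fitted constant would be an extrapolation of the fit to a predicted
  risk of 0.5, several logit units outside the data mass, with a sampling SD
  near 0.09 even at 50 000 pregnancies; the offset form is the field-standard
  calibration hierarchy convention and is what "intercept 0 = perfect" refers
  to here. Risks at 0 or 1 are clipped to $[10^{-9}, 1-10^{-9}]$ with a
  warning; constant risks are flagged as a degenerate fit.
* **McNemar at fixed FPR**: both methods thresholded at their own 10% FPR;
  among cases, discordant detections tested exactly (binomial) when the
  discordant total is below 25, otherwise chi-square with continuity
  correction. The cutoff is the conventional small-count rule; both forms are
  available.
* **"SGA without PE"**: SGA cases with PE are removed from the evaluation
  subset entirely (cases = SGA∧¬PE, controls = ¬SGA) — the stricter of the
  two readings of that stratification, chosen so the case series is purely
  non-hypertensive.

## Numerical choices

* Bivariate-normal rectangle probabilities: 24-node Gauss–Legendre quadrature
  of $\phi(u)\,\Phi\!\big((a-\rho u)/\sqrt{1-\rho^2}\big)$ over
  $u \in [-8.5, h]$; agrees with `mvtnorm::pmvnorm` to ~$10^{-10}$ (test).
* Posterior grid: $381 \times 501$ points; strict inequalities in rectangle
  definitions are immaterial (continuous densities), but partial final cells
  are integrated by linear interpolation so cut-offs need not lie on grid
  nodes.
* Truncated-Gaussian outcome sampling is vectorized rejection with a
  10 000-round cap (an error beyond it indicates parameters with essentially
  no mass on the support).
* Seeds: one master seed expands into named per-stage streams
  (`seed_streams()`), so stages are independently reproducible.

## Problem sizes used by the tests

Unit tests run on a coarsened grid (0.2/0.05 steps) and small cohorts; the
acceptance-style tests use the study-scale conditions: the full 35 170-record
cohort for incidence and marginal checks, 50 000 records for the
self-calibration experiment, $10^6$-draw Monte-Carlo/importance-sampling
oracles for the integrator, and 15 000 records for the biomarker-ordering
checks. The reproduction script (`scripts/acceptance.R`) runs the
self-calibration experiment at 150 000 records, where the sampling SD of the
calibration intercept (~0.03) sits comfortably below the scale on which
miscalibration would matter; at 50 000 records that SD is ~0.05, so an
intercept estimate there says more about label noise than about the model.
These were chosen as the smallest sizes at which the targeted tolerances are
comfortably inside sampling noise.

## Known limitations

* The shipped parameterization is a documented stand-in; bit-compatibility
  with any published software would require transcribing that model's exact
  chart, MoM regressions and plane coefficients into `params.json`.
* The Gaussian GA margin cannot reproduce a realistic preterm tail and a
  realistic interquartile range simultaneously (see the generator section);
  cohort-level incidences are faithful, subgroup-level preterm rates are not.
* Comparator equations are synthetic placeholders exercising the comparison
  machinery; conclusions about published logistic models require their real
  coefficients.
* Analyzer effects (different immunoassay platforms) are representable as
  optional MoM-regression terms but default to zero.
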