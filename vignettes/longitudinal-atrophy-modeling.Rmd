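---
title: "Modeling longitudinal brain atrophy with longmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal brain atrophy with longmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longmorph)
```

This vignette explains the statistical machinery of `longmorph`: the models,
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic cohort generator does and does not emulate, and
the numerical choices a maintainer should know about.

## The data model

The unit of analysis is the *cohort table* (`long_table`): one row per
(subject, visit), subject-level covariates (group, sex, education, baseline
age, intracranial volume), visit-level fields (time from baseline in decimal
years, age at visit, cognitive status), and one numeric column per brain
region. A region dictionary tags every column as a volume (cm³), planar
area (mm²) or cortical thickness (mm), so the three measurement kinds are
never mixed in one normalization pass. Time is decimal years from baseline;
the visit index is ordinal bookkeeping, not calendar time. Missing regional
cells stay missing and are dropped per region at analysis time
(complete-case per region); no imputation is performed anywhere.

Group membership (control, cognitively normal PD, cognitively impaired PD)
is frozen at baseline: cognitive status is stored per visit and may change
during follow-up, but the longitudinal model codes each subject by their
study-entry classification. Subjects whose status changes mid-study are
therefore analyzed in their baseline group; the per-visit status is instead
what drives the converter labeling (below).

## Normalization and covariate correction

Regional values are first scaled to a common head size,
$v^{\mathrm{norm}}_{i} = v_{i}\,\bar V^{\mathrm{ref}} / V^{\mathrm{ref}}_{i}$,
where the subject reference $V^{\mathrm{ref}}_{i}$ is the intracranial
volume for volumes and areas, and the subject's *baseline* mean cortical
thickness for regional thickness values. The cohort scale
$\bar V^{\mathrm{ref}}$ is the arithmetic mean of the subject references
over the baseline visits of the whole study population; follow-up visits
reuse the baseline subject reference, i.e. a subject's head size is treated
as time-constant. The transform is linear in $v$, so it is exactly
scale-equivariant and preserves units.

Normalized values are then adjusted for age and education. Per region, a
three-parameter linear model (intercept, age slope, education slope) is fit
by OLS to the *baseline records of the controls only* — patients must not
inform the "normal" covariate effect — and every value is corrected as
$v^{c} = v^{\mathrm{norm}} - \hat\gamma_1(x^{\mathrm{age}} - \bar x^{\mathrm{age}})
- \hat\gamma_2(x^{\mathrm{edu}} - \bar x^{\mathrm{edu}})$, re-centering at
the whole-population baseline mean age and education. Two details are
deliberate:

* **Which age?** For longitudinal tables the correction uses the age at the
  visit being corrected (`correction_age_mode = "visit"`, the default),
  which is the natural reading of a per-measurement correction; a
  `"baseline"` mode is provided because baseline-only corrections are also
  common and the choice is not observable from a baseline report (at
  baseline the two coincide).
* **Single application.** The correction is not idempotent (applying it
  twice subtracts the covariate term twice), so tables carry a provenance
  flag and `correct_table()` refuses to run on an already-corrected table.
  The same guard exists for normalization.

An optional sex indicator can be added to the correction model per region
(`sex_regions`), intended for cortex-wide mean thickness where a sex effect
survives head-size normalization.

Group summaries are reported as the percent deviation
$\Delta\% = (\bar v_{\mathrm{group}}/\bar v_{\mathrm{controls}} - 1)\cdot 100$,
negative for tissue loss, positive for e-vacuo enlargement (CSF spaces).

## Robust LOWESS

`lowess_fit()` implements Cleveland's locally weighted scatterplot
smoother. At each evaluation point the $q = \lceil f\,n\rceil$ nearest
neighbours are selected (window fraction $f$; distance ties admit all tied
points), weighted by the tricube kernel
$W(u) = (1-|u|^3)^3$ with $u$ the distance scaled by the largest neighbour
distance, and a weighted polynomial of degree $d$ is fitted; the smoothed
value is the local fit's value at the evaluation point. Robustness
iterations compute bisquare weights $B(e) = (1-(e/6m)^2)^2$ for $|e| < 6m$
(with $m$ the median absolute residual, the classical constant) and refit.

Defaults — $f = 0.8$, $d = 1$, two robustness iterations — are the settings
used for exploratory trajectory analysis of morphometry-versus-age scatter
in this literature: a wide window because per-region trajectories are slow
and noisy, straight-line local fits, and enough robustness rounds to
neutralize scanner-artifact outliers. Degenerate cases are defined
explicitly: if the largest neighbour distance is zero (replicated
abscissae), weights collapse to uniform over the replicates; if a window
cannot support the requested degree, the degree is reduced to what is
estimable; if all robustness weights in a window vanish, the unrobustified
tricube weights are used for that window. With a window fraction defined
through $f$, window *width* varies with local data density; this is the
fraction-based convention and the one the defaults are calibrated for.

`annual_rate_readout()` turns a smoothed trajectory into an annual rate by
central differences, reported both in outcome units per year and as a
percentage of the smoothed level.

LOWESS here is exploratory only: no confidence bands are produced, and
inference about rates belongs to the mixed model.

## The mixed-effect atrophy-rate model

Per region, the outcome vector of subject $i$ follows
$y_i = X_i\beta + Z_i b_i + \varepsilon_i$ with $b_i \sim N(0,\Psi)$,
$\varepsilon_i \sim N(0,\sigma^2 I)$. The fixed design has exactly eight
columns, in fixed order: intercept; time from baseline $t$; PD-N indicator;
$t\times$PD-N; PD-CI indicator; $t\times$PD-CI; transformed age; education.
Controls are the reference group, so the group atrophy rates are
$\beta_t$, $\beta_t + \beta_{t\times\mathrm{PDN}}$ and
$\beta_t + \beta_{t\times\mathrm{PDCI}}$. The outcome is the *normalized*
(not covariate-corrected) value: age and education are covariates of the
model itself, so pre-correcting would remove them twice.

**The knotted age effect.** Brain volume and cortical thickness in healthy
adults are roughly flat until about age 60 and decline steadily afterwards,
so age enters as $(z - \mathrm{knot})\cdot H(z - \mathrm{knot})$ with
Heaviside $H(0) = 0$ and a default knot of 60 years (configurable within
[40, 80]). By default the transform is applied to the *enrollment* age,
constant per subject (`age_mode = "enrollment"`), which keeps the age
column from competing with the time column for the within-subject trend; a
time-varying `"visit"` mode is available.

**Random effects.** Intercept and slope per subject with an unstructured
2×2 covariance — compound symmetry is deliberately not assumed, since
subjects differ both in level and in rate. A random-intercept-only mode
exists for designs where slope variance is unidentifiable. Boundary fits
(a variance component estimated at ~0) are flagged (`fit$boundary`), not
silently accepted.

**Estimation.** REML, the standard criterion for unbiased variance
components. The relative covariance $G = \Psi/\sigma^2$ is parametrized by
its log-Cholesky factor (two log-diagonal entries and one free off-diagonal
entry), which enforces positive semidefiniteness without constraints;
$\beta$ and $\sigma^2$ are profiled out, so the optimizer works in three
dimensions only. Optimization is Nelder-Mead (Brent in the 1-parameter
intercept-only mode) from a method-of-moments start built from per-subject
OLS lines; the start is deterministic, so fits are exactly reproducible
without seeds. Subjects sharing a visit-time pattern share their marginal
covariance, so each objective evaluation does one small Cholesky per
pattern and blocked matrix products over subjects — this is what makes the
Monte-Carlo calibration studies below affordable. Log-Cholesky parameters
are clamped to ±15: beyond that the profiled REML surface is flat (the
component is at its boundary) and unclamped values only overflow. Estimates
were validated against an independent REML implementation (`lme4`) in the
test suite; agreement is at ~5 significant digits for fixed effects and
variance components.

**Inference.** The slope-equality hypothesis
($\beta_{t\times\mathrm{PDN}} = \beta_{t\times\mathrm{PDCI}} = 0$) is
tested with $F = (L\hat\beta)'(L\,\widehat{\mathrm{cov}}(\hat\beta)\,L')^{-1}
(L\hat\beta)/\mathrm{rank}(L)$, numerator df 2. For the denominator df the
default is the residual count $N_{\mathrm{obs}} - 8$ — simple, conventional
in large cohorts, and reported explicitly in the output. For small cohorts
the residual df overstates the information available for slope contrasts
(most observations contribute little to slopes once attrition thins the
later visits) and makes the test liberal; a Satterthwaite approximation
(`df_method = "satterthwaite"`; numeric derivatives of the contrast
variance with respect to the variance parameters, Fai–Cornelius combination
for multi-row contrasts, validated against `lmerTest`) restores the nominal
level, and is what the package's own null-calibration study uses. No
attempt is made to reproduce any particular published denominator df, which
depends on unstated software conventions.

## The cross-sectional battery

Welch's unequal-variance t test is the default two-group comparison, and is
computable both from raw vectors and from printed (mean, SD, n) summaries —
the latter is what makes published demographic tables exactly
recomputable. Pearson χ² is computed *without* continuity correction
(matching how such statistics are conventionally printed alongside
demographic tables); Fisher's exact test is available for 2×2 tables and
both can be reported side by side. Kruskal–Wallis (mid-ranks, tie
correction, χ² approximation) handles three-group comparisons, with post
hoc Welch t tests gated on a significant omnibus. Normality is screened
with a Lilliefors test whose p-value comes from Monte-Carlo simulation of
the estimated-parameter null (default 10,000 replicates, seedable) rather
than interpolation tables — reproducible and free of table-range
restrictions. Multiplicity control is Bonferroni (`min(1, p·m)`), with the
family size defaulting to the number of tests in the report table and
recorded in the report's attributes.

## The synthetic cohort generator

`generate_cohort()` emulates the data-generating structure the analyses
assume: three groups with configurable sizes (defaults 85/80/92), truncated
normal ages (group-specific means, bounds 45–80 years), education (bounds
7–30 years), sex frequencies, intracranial volume (mean 1459.3 cm³, SD
120), a five-visit schedule at 0/1.1/2.4/3.2/3.9 years, and monotone
drop-out drawn visit-by-visit to match observed cumulative retention
(e.g. patients: 75%, 31%, 20%, 5% of baseline at follow-ups 1–4). Regional
outcomes follow the mixed model exactly — the 8-term fixed structure
including the knotted age effect, per-subject random intercept/slope, and
Gaussian noise — generated on the normalized scale and then rescaled by each
subject's reference so the normalization stage has real work to undo.
Every draw is reproducible from (config, seed), and the realized random
effects, drop-out pattern and arm assignments are returned as generation
truth for parameter-recovery tests.

Magnitude defaults are synthetic, not estimates: no variance components are
published for data of this kind, so they were chosen once to make
realistic-looking trajectories — controls declining by roughly 0.5%/year in
global volume above age 60, regional thickness ~2.4–2.7 mm with
between-subject SD near 3% of the regional mean and small residual noise —
and are documented here rather than revisited. Drop-out is missing
completely at random, which is the implicit assumption of the REML analysis
itself; an outcome-dependent drop-out mode is deliberately *not* the
default. Visit-time jitter (uniform, configurable half-width) is off by
default so that exactness tests are possible.

What the generator does **not** emulate: scanner and site effects,
non-Gaussian measurement error, floor/ceiling effects in thickness,
informative drop-out, within-subject correlation between regions (regions
are generated independently), or misclassification of cognitive status.
Passing tests on synthetic cohorts therefore demonstrate the correctness
and calibration of the *statistical machinery* under its stated
assumptions — not robustness to the full messiness of multi-center MRI
data.

`generate_converter_scenario()` splits the cognitively normal PD arm into
future converters (default fraction 26/68) and nonconverters, multiplies
the converter arm's trajectory in one thickness region by $1+\delta$
(e.g. −3%), makes converters acquire MCI status from a configurable visit
onward, and plants a configurable rank correlation between the thinned
region and a per-subject cognitive score. Converter-arm retention keeps the
first follow-up complete so every subject is labelable.

## Verification, problem sizes, and limitations

The test suite cross-checks every computational core against an independent
oracle: LOWESS against a literal per-point weighted-least-squares
reimplementation (agreement to 1e-10) and against `stats::lowess`; REML
against `lme4`; Satterthwaite df against `lmerTest`; the Lilliefors
statistic against `nortest`; Fisher's exact p against hypergeometric
enumeration; Kruskal–Wallis against a direct rank computation.

The simulation studies use sizes chosen to give tight Monte-Carlo error at
interactive runtimes: slope recovery and Wald coverage over 200 replicates
of 200-subject cohorts with realistic attrition; null calibration of the
slope-equality F test over 2,000 replicates of 60-subject cohorts (where
the Satterthwaite df is the appropriate method — see above); attrition
calibration over 100 seeds of 172 patients; converter detection over 100
replicates of the planted −3% scenario. `scripts/acceptance.R` recomputes
scaled-down versions of the same quantities (60–600 replicates) in about
two minutes.

Known limitations: Gaussian outcomes only (no generalized mixed models);
no spatial or vertex-wise modeling; no model selection over random-effects
structures; the Satterthwaite implementation uses numeric derivatives and
costs a few dozen extra objective evaluations per test; Wald intervals use
normal quantiles, which is slightly liberal in very small cohorts; and the
Bonferroni family is per report table, which is a convention, not a
theorem.
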