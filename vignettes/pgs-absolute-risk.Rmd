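---
title: "From polygenic hazard ratios to absolute risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From polygenic hazard ratios to absolute risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsrisk)
```

`pgsrisk` estimates cumulative incidence of disease from birth to age 80,
stratified by polygenic score (PGS), by combining relative hazards
estimated in cohort data with population incidence, prevalence and
mortality rates. This vignette documents the statistical model, the
package's numerical conventions, the synthetic-data generator used to
validate it, and the design decisions taken where more than one
reasonable choice existed.

## 1. Relative hazards from cohort data

The exposure is the PGS standardized to mean 0 and variance 1 *within
each study* (`standardize_pgs()`, unbiased n−1 denominator), so all
hazard ratios are per standard deviation on a common scale despite
different raw score distributions across genotyping batches and scoring
pipelines.

Associations are proportional-hazards fits with **age as the timescale**:
follow-up runs from birth to the earliest of disease onset, death from
another cause, censoring, or age 80. This choice makes the baseline
hazard an age curve, which is exactly the object the life-table
calibration replaces with population rates. Fits use
`survival::coxph()` with the Efron tie approximation — with continuous
ages ties are rare and Efron is the standard default. Sex is included as
a covariate in pooled (mixed-sex) fits and is absent, by construction,
in sex-stratified fits; technical covariates (genetic principal
components, batch) pass through by column name but play no role in the
synthetic validation, which generates none of those artifacts.
Non-convergent fits are flagged (`converged = FALSE`) and excluded from
meta-analysis rather than silently propagated.

Four model families are fitted per disease: full sample, sex-stratified,
age-stratified, and age-and-sex-stratified. Age stratification cuts
follow-up into four intervals at the onset-age quartile boundaries
(type-7 quantiles per study, averaged arithmetically across studies).
Within interval `[L, U)`, individuals whose onset precedes `L` are
excluded entirely; everyone else enters the risk set at `L` — the
interval restriction is encoded as **left truncation (delayed entry)**,
the standard survival-analysis encoding of "onset only counted within
the interval" — and is censored at `U` if event-free.

## 2. Heterogeneity tests and model selection

Per-study estimates are pooled by inverse-variance fixed-effects
meta-analysis on the log scale (`meta_fixed()`, backed by
`metafor::rma(method = "FE")`); a study enters a stratified scheme only
if it has a converged estimate in every stratum of that scheme.
Sex-specific effects are tested with a PGS-by-sex interaction (two-sided
Wald test on the meta-analyzed interaction coefficient); age-specific
effects with Cochran's Q across the four quartile estimates. The main
significance threshold defaults to 0.05/18 ≈ 2.8×10⁻³, a Bonferroni
correction over a panel of 18 phenotypes; it is a plain argument
(`alpha_main`) for other panel sizes.

Age trends are summarized by weighted linear regression of quartile
log-HRs on the **median onset age within each quartile**, with weights
1/SE² and a fixed-variance coefficient covariance (meta-regression, not
OLS: the residual variance is not rescaled). Slopes are compared between
sexes with a z-test on the slope difference, treating the sexes as
independent (they are disjoint samples). With only two usable quartile
points the line interpolates them exactly and its covariance comes from
the two SEs — a documented fallback for sparse strata; with fewer than
two, the group falls back to its constant (full-fit) HR.

`select_model()` applies the decision rules: *sex* if the interaction is
significant at `alpha_main`; *age* if the overall quartile Q is;
*age-and-sex* if both hold, or if quartile heterogeneity appears in
exactly one sex where it was absent overall, or if the sex-specific age
slopes differ at a nominal 0.05. One deliberate refinement: the nominal
slope-difference rule is **only consulted when some age-specific signal
exists** (overall or per-sex Q significant). An always-on nominal test
would route about 5% of perfectly null datasets into the age-and-sex
model, which would defeat the purpose of the Bonferroni-corrected main
threshold; gating it on prior age evidence keeps the null selection rate
where the other rules put it. Missing evidence entries are treated as
non-significant and recorded in the returned evidence object, from which
the choice is exactly reproducible.

## 3. The life table and recalibration

Population rates come per (location, sex, five-year age group):
incidence, point prevalence, cause-specific and all-cause mortality. The
life table (`life_table()`) is:

* hazard `= incidence / (1 − prevalence)`, constant within its bin;
* other-cause mortality `= all-cause − cause-specific` (tiny negative
  differences within 1e-12 are clamped with a warning, larger ones
  error);
* `survival_k = exp(−5 Σ_{m<k} (mortality_m + hazard_m))`, with
  `survival_0 = 1`. The printed form of this expression is ambiguous
  about what the exponent covers; it is implemented as the exponential
  of −5 times the whole sum, the only reading consistent with "rates per
  year multiplied by 5 to cover a 5-year group" and with the closed form
  `survival_k = exp(−rk)` under a constant combined rate `r`;
* `risk_m = 1 − exp(−5 hazard_m)`, the within-bin onset probability.
  This deliberately ignores the competition of death *within* the bin
  (it is applied between bins through `survival`), matching the
  published scheme; the resulting discretization bias is quantified by
  the simulator-agreement tests below and stays well inside their 0.02
  tolerance at realistic rates;
* cumulative incidence `CI(A) = Σ_{k<A} survival_k · risk_k` over the 16
  bins `{0, 5, …, 75}`, reported at boundaries `{0, …, 80}`.

Sub-bin ages use the exact constant-hazard solution
`CI(k + t) = CI(k) + survival_k (1 − e^{−t·hazard_k})`, which reproduces
the boundary values to 1e-12 — no linear interpolation anywhere.

Recalibration across PGS groups inverts the population constraint: with
group proportions `n_i/n` and hazard ratios `HR_i` (reference 40–60%,
`HR ≡ 1`), the reference incidence is
`I_0 = n I / (n_0 + Σ HR_i n_i)` and group incidences are
`I_i = I_0 HR_i`, so the proportion-weighted mean recovers `I` exactly
(tested to 1e-12). Each group's incidence is converted to a hazard using
the **population** prevalence — group-specific prevalences are not
identifiable from summary rates, a simplification inherited from the
published scheme — and other-cause mortality is shared across groups.
Age-varying HRs are evaluated at the **bin midpoint** (m + 2.5; a
configurable-in-principle choice — lower-bound evaluation shifts curves
by less than the trend's SE at these bin widths) and held constant at
the nearest fitted value outside the span of the quartile estimates, so
extrapolation beyond the observed onset ages never amplifies a trend.
With age-specific models the trend is fitted per PGS group on that
group's own quartile HRs; a rescaling of the per-SD trend is *not* used
by default because group HRs are not log-linear transforms of the per-SD
effect once the tails are this asymmetric.

Multi-study settings meta-analyze the group HRs before any curve is
computed (`pool_strata_hr()`, `transfer_with_meta_hrs()`); transferring
pooled HRs onto another country's rate table is the same computation
with a different baseline.

## 4. Uncertainty

`bootstrap_curves()` and `bootstrap_scalar()` implement a parametric
bootstrap: per replicate, each requested parameter block is perturbed —
baseline rates log-normally with the SD implied by their 95% bounds
(prevalence on the logit scale, preserving bounds and positivity),
scalar log-HRs normally with their SEs, and age-trend coefficients either
sampled from their joint WLS normal (default) or re-derived by
resampling the quartile log-HRs and refitting the regression
(`trend_mode = "refit"`). Both modes exist because summary tables do not
say which level the original perturbation targeted; the default samples
the fitted trend, the cheaper and smoother choice. Log-HRs are perturbed
independently across strata — joint covariances are unavailable from
summary tables, a documented limitation that understates the correlation
of neighbouring groups. Bands are pointwise percentile intervals
(defaults 2.5/97.5, B = 1000); screening-age intervals hold the clinical
threshold fixed at its point estimate, since the threshold plays the
role of an external guideline value. Replicates where a crossing age is
undefined are counted, and intervals with more than half undefined are
flagged unreliable rather than silently truncated.

## 5. The synthetic-data generator

`simulate_cohort()` draws from the generative model
`λ(a|x) = h₀(a) · exp{x (β₀ + β_sex·1[male] + β_age (a − a_ref) + u_s)}`
with standard-normal PGS `x`, a piecewise-constant baseline `h₀`,
competing piecewise-constant other-cause mortality, administrative
censoring at 80, and study offsets `u_s ~ N(0, study_sd²)`. Event times
are sampled by **exact inversion within hazard segments** (the
age-varying exponent integrates in closed form per segment), so there is
no discretization error in the simulator itself and oracle comparisons
test the analysis, not the generator. Sex is independent of PGS; the
linear-in-age log-HR is an assumption adopted for testability — observed
age declines in per-SD effects are approximately linear, but the
generator makes no biological claim — with the reference age defaulting
to 40 so `β₀` is the mid-life effect.

Defaults encode a common, screenable disease: baseline hazard rising
from 1e-4/yr (ages 0–20) through 1e-3 and 4e-3 to 8e-3/yr (60–80),
giving a lifetime cumulative incidence near 20%; other-cause mortality
1e-3/5e-3/2e-2 per year over the same spans (about 40% all-cause
mortality by 80); `β₀ = 0.3` (HR ≈ 1.35 per SD, typical of strong
common-disease PGSs); `β_sex`, `β_age` and `study_sd` zero unless a test
switches them on.

`derive_population_rates()` returns the GBD-shaped rate table implied by
the same parameters: prevalence as the ever-diagnosed fraction among
those alive at the bin midpoint, incidence as expected new cases per
person-year alive within the bin, marginalized over the PGS by
Gauss–Hermite quadrature (61 nodes) with Gauss–Legendre age integration
(8 nodes per bin); cause-specific mortality is zero because the
generator does not model death from the disease.
`analytic_cumulative_incidence()` supplies the continuous-time ground
truth, optionally restricted to a PGS quantile slice, and is the
reference in the coverage and consistency tests.

What the generator deliberately does **not** emulate: ascertainment and
healthy-volunteer bias, disease-dependent mortality, non-proportional
hazards beyond the linear age trend, secular/cohort effects in the rate
tables, LD structure or genotype-level noise in the score, and
non-European-ancestry transferability. Passing tests therefore
demonstrate internal consistency of the estimation machinery under a
proportional-hazards world, not robustness to those real-data features.

## 6. Numerical conventions and degenerate inputs

* Quantiles and percentile ranks: type-7 (linear interpolation of the
  empirical distribution) throughout; group assignment uses
  `(rank − 1)/(n − 1)·100` with half-open `[lower, upper)` intervals,
  top group closed — with distinct values the canonical grouping splits
  n = 100 as 20/20/20/20/10/5/5 exactly.
* All-equal PGS within a study: an error naming the study (ranks and
  standardization are undefined), never silent.
* Empty strata, non-convergence, or a threshold unreached by 80: flagged
  (`converged = FALSE`, sentinel `NA` with `not_reached`), never
  fabricated.
* Reference-group HR is forced to exactly 1 at construction.
* All stochastic entry points take an explicit seed and are reproducible
  byte for byte; the pipeline writes its seed and every convention above
  into its log and manifest.

## 7. Problem sizes used in validation

The test suite validates parameter recovery at cohorts of 100,000
(per-SD log-HR within 0.05 of truth, 95% CI coverage over 20
replicates), model selection at 200,000 per replicate (the smallest size
at which the quartile Q test is decisively powered for a −0.01/yr
trend), simulator/life-table agreement at 200,000 (within 0.02 absolute
everywhere on the 5-year grid), bootstrap coverage with B = 200, and the
screening direction check over 20 replicates of 100,000. Exact identities
(conservation, telescoping, oracle equivalence, round-trips) are tested
to 1e-12.

## 8. Known limitations

Group log-HRs are treated as independent in the bootstrap; group
incidences reuse the population prevalence; the within-bin risk formula
ignores within-bin death competition by design; crossing ages inherit
the 5-year resolution of the rate tables (exactly interpolated, but the
underlying hazard is still piecewise constant); and the meta-analysis is
fixed-effects, so between-study heterogeneity widens nothing — it is
surfaced through Cochran's Q and the transfer comparison instead.
Non-genetic risk factors, family history and rare variants are out of
scope.
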