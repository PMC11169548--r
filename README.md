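# pgsrisk

Absolute disease risk over the life course, stratified by polygenic score
(PGS), calibrated to population rates.

Biobank cohorts yield *relative* risks — hazard ratios per standard
deviation of PGS, or per PGS percentile group — but clinical decisions
(when to start screening, whom to screen earlier) need *absolute* risk in
the population of interest, by country, sex and age, and accounting for
the competing risk of death from other causes. `pgsrisk` implements that
translation as a tested pipeline: Cox proportional-hazards models with age
as the timescale estimate the PGS effect; interaction and heterogeneity
tests decide whether the effect differs by sex or declines with age;
fixed-effects meta-analysis combines studies; and a discrete life table
built from population incidence, prevalence and mortality in five-year
age groups turns the hazard ratios into per-stratum cumulative-incidence
curves, bootstrap bands and risk-based screening ages.

The package is aimed at statistical geneticists and epidemiologists
building country-specific PGS risk calculators, and ships a synthetic-data
generator with analytically known ground truth so every stage can be
validated end to end without access to individual-level biobank data.

## The model

For five-year age groups `[m, m+5)`, population rates define a disease
hazard and a competing-risk life table:

    hazard_m   = incidence_m / (1 - prevalence_m)
    survival_k = exp(-5 * sum_{m<k} (mortality_m + hazard_m)),  survival_0 = 1
    risk_m     = 1 - exp(-5 * hazard_m)
    CI(A)      = sum_{k<A} survival_k * risk_k

where `mortality` is other-cause mortality (all-cause minus
cause-specific). PGS enters by splitting the population incidence `I`
across percentile groups with hazard ratios `HR_i` (reference group
40–60%, `HR_0 = 1`):

    I_0 = n I / (n_0 + sum_i HR_i n_i),      I_i = I_0 * HR_i

so that the proportion-weighted average of group incidences reproduces
`I` exactly. Each group's incidences feed the same life table with shared
other-cause mortality. Where the PGS effect declines with age, group HRs
come from a weighted regression of quartile-specific log-HRs on median
onset age, held constant beyond the fitted range. Screening ages are the
earliest ages at which a stratum's curve reaches the population's
cumulative incidence at a guideline index age (e.g. 45 for type 2
diabetes, 50 for breast cancer), solved exactly within bins under the
piecewise-constant hazard.

## Worked example

```r
library(pgsrisk)

cfg    <- sim_config(n_individuals = 40000, seed = 11, beta0 = 0.3)
cohort <- assign_pgs_groups(standardize_pgs(simulate_cohort(cfg)))

fit_cox_full(cohort)[, c("stratum", "log_hr", "se", "n_cases", "converged")]
#>   stratum    log_hr         se n_cases converged
#> 1    full 0.2824627 0.01142203    7674      TRUE

strata <- estimate_strata_hr(cohort, "full")
rates  <- derive_population_rates(cfg)
curves <- stratified_cumulative_incidence(rates, strata, sex = "female")
subset(curves, age == 80, c(stratum, cumulative_incidence))
#>     stratum cumulative_incidence
#>  population            0.1977118
#>         <20            0.1338386
#>       40-60            0.1892446
#>         >95            0.3088844    (middle groups omitted here)

screening_report(curves, index_age = 45)[, 1:4]
#>     stratum crossing_age reached diff_vs_index
#>  population     45.00000    TRUE     0.0000000
#>         <20     50.91094    TRUE     5.9109414
#>         >95     40.65829    TRUE    -4.3417111
```

The generator's true per-SD log hazard ratio was 0.3; the fit recovers
0.282 (SE 0.011). By age 80 the top 5% of the PGS distribution reaches a
cumulative incidence of 30.9% against 13.4% for the bottom 20%, and the
top 5% attains the population's age-45 risk level (4.2%) 4.3 years
earlier, the bottom 20% 5.9 years later. A small GBD-shaped rate table
for experimenting with `read_rate_table()` ships in
`inst/extdata/synthetic_rates_demo.csv` (synthetic, derived from the
default generator).

`run_pipeline(pipeline_config(...))` chains all stages — simulation,
association, model selection, calibration, bootstrap, screening — and
writes CSV/JSON outputs plus a manifest with checksums and the numerical
conventions in force.

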