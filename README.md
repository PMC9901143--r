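# regcomplete

Completeness assessment for passive disease registries via illness–death
incidence modelling.

## What problem this solves

Population registries for acute myocardial infarction, stroke and other
major non-communicable diseases rely on routine case reports from health
facilities, and routinely miss incident events — patients who die before
reaching care, seek care elsewhere, or are never reported.  Deaths, by
contrast, are registered nearly completely.  `regcomplete` estimates the
fraction of incident cases a registry captures by reconstructing the
"true" incidence rate that is internally consistent with better-measured
epidemiological quantities, in the DisMod II tradition.

The model is a three-state (susceptible / diseased / dead) life table with
age-specific hazards: incidence *i*, remission *r*, case fatality *f* and
other-cause mortality *m*.  Prevalence obeys

    p' = i (1 − p) − r p − f p (1 − p)

so, given prevalence, remission and case fatality (the latter derived from
the cause-specific mortality rate as f = csmr / p, or from the all-cause
mortality relative risk RR = (m + f)/m), incidence can be back-calculated
exactly:

    i(a) = [ p'(a) + r(a) p(a) + f(a) p(a) (1 − p(a)) ] / (1 − p(a))

Registry completeness is then the incidence rate ratio

    IRR = observed incidence rate / modelled incidence rate

with log-scale normal confidence intervals, an optional secular-trend
adjustment along cohort lines (a constant annual proportional change in
incidence since a base year), percentile-bootstrap uncertainty from
normally perturbed prevalence, direct age standardisation with the WHO
World Standard Population, and one-sided Z-tests for improvement in
completeness between survey years.  A synthetic-data module generates
internally consistent epidemiological worlds with known hazards and known
under-reporting so every stage of the pipeline is testable end to end.

Intended users: epidemiologists and surveillance analysts evaluating
registry data quality, and anyone needing a scriptable, tested
re-implementation of illness–death incidence back-calculation.

## Worked example

Simulate an AMI-like world in which the registry truly captures 42% of
male incident cases, then estimate that fraction from the emitted inputs:

```r
library(regcomplete)

world    <- make_world("ami_like", seed = 1)
inputs   <- emit_model_inputs(world, noise = 0.05)
registry <- emit_surveillance(world, seed = 2)

fit <- fit_incidence(
  prevalence    = rt_stratum(inputs$prevalence, sex = "male"),
  remission     = rt_stratum(inputs$remission, sex = "male"),
  csmr          = rt_stratum(inputs$csmr, sex = "male"),
  relative_risk = rt_stratum(inputs$relative_risk, sex = "male"),
  trend      = trend_spec(-0.02, survey_year = 2015),
  boot       = bootstrap_spec(n_iter = 100, seed = 3),
  population = world$population)
fit
#> Illness-death incidence model fit
#>   stratum: ami_like/male/2015
#>   trend: -2.0% per year since 2000
#>   modelled incidence (crude, per 100,000 person-years): 368.3
#>   trend-adjusted:                                     359.7
#>   bands: 20; bootstrap: 100 iterations

cm <- completeness(fit, rt_stratum(registry$incidence, sex = "male"))
subset(as.data.frame(cm), is.na(age_lo) | age_lo %in% c(40, 60, 80),
       select = c(age_lo, observed, modeled, irr, lo, hi))
#>    age_lo observed  modeled   irr    lo    hi
#> 9      40  0.00021 0.000632 0.332 0.271 0.407
#> 13     60  0.00128 0.003368 0.379 0.345 0.417
#> 17     80  0.00717 0.017629 0.407 0.380 0.435
#> 21     NA  0.00154 0.003597 0.428 0.417 0.438
```

The per-band rows compare observed and modelled rates (per person-year);
the final row (`age_lo = NA`) is the person-year-weighted total: an
estimated completeness of 0.43 (95% CI 0.42–0.44) against a configured
truth of 0.42.  Narrow-band estimates scatter more because each band's
registry count is a small Poisson draw.

`run_pipeline()` orchestrates the same sequence for many
disease/sex/year strata from a single YAML config and writes a report
(`report.json`, rate and ratio tables as CSV, a stage log with input
checksums); `inst/scripts/run_pipeline.R` exposes `run` and `simulate`
subcommands for shell use.  The methods vignette
(`vignettes/registry-completeness.Rmd`) documents the model, the grid and
trend conventions, and the generator's assumptions.

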