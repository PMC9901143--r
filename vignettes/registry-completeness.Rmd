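---
title: "Assessing registry completeness with an illness-death incidence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing registry completeness with an illness-death incidence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regcomplete)
```

## The problem

Passive disease registries — surveillance systems that rely on routine case
reports from health facilities — systematically miss incident events:
patients who die before reaching care, seek care elsewhere, receive a
non-specific diagnosis, or are simply never reported.  Mortality
registration, by contrast, is usually near-complete because death
certification is mandatory.  `regcomplete` estimates *how much* a registry
misses by reconstructing the "true" incidence rate that is mutually
consistent with better-measured quantities — point prevalence, remission,
cause-specific mortality and the all-cause mortality relative risk of
cases — and expressing registry completeness as the incidence rate ratio

$$\mathrm{IRR} = \frac{\text{observed incidence rate}}
                     {\text{modelled incidence rate}},$$

the fraction of incident cases the surveillance system captures.  This is
the DisMod II strategy familiar from burden-of-disease work, rebuilt here
as an open, testable pipeline.

## The illness-death model

The core is a three-state continuous-time life table with states
*susceptible* (S), *diseased* (C) and *dead*, and four age-specific
transition hazards (all per person-year):

* incidence $i(a)$: susceptible $\to$ diseased,
* remission $r(a)$: diseased $\to$ susceptible,
* case fatality $f(a)$: diseased $\to$ death from the cause,
* other-cause mortality $m(a)$: either living state $\to$ death from
  other causes.

A unit birth cohort evolves by the linear system

$$\frac{dS}{da} = -(i+m)S + rC, \qquad
  \frac{dC}{da} = iS - (r+f+m)C,$$

with cause deaths accumulating as $dD_c/da = fC$.  Derived quantities are
the point prevalence $p = C/(S+C)$ and the cause-specific mortality rate
(cause deaths per person-year of total population) $\mathrm{csmr} = f\,p$.
`forward_solve()` treats hazards as constant within each single-year age
interval and advances by the exact matrix exponential of the generator per
interval; the two living states admit a closed-form $2\times 2$
exponential, and the death integrals are evaluated by seven-point
Gauss–Legendre quadrature of the closed-form occupancies, so conservation
of probability holds to near machine precision (the test suite checks
$10^{-9}$, and agreement with a fine-step Runge–Kutta integrator to
$10^{-6}$).

Prevalence itself follows the scalar ODE

$$p' = i(1-p) - rp - fp(1-p),$$

which `invert_incidence()` inverts exactly:

$$i(a) = \frac{p'(a) + r(a)p(a) + f(a)p(a)\bigl(1-p(a)\bigr)}{1-p(a)}.$$

This back-calculation — prevalence, remission and case fatality in,
incidence out — is the estimator at the heart of the package.

### Input pathways

The observable inputs are age-band tables of prevalence, remission,
cause-specific mortality, and optionally the relative risk
$RR = (m+f)/m$ of all-cause death among cases versus non-cases.  Case
fatality is derived primarily as $f = \mathrm{csmr}/p$ (the mortality input
is locally measured surveillance data); where prevalence falls below
`eps = 1e-6` that ratio is unstable and the relative-risk pathway

$$m = \frac{m_{\mathrm{all}}}{1 + p(RR-1)}, \qquad f = m(RR-1)$$

is used as a fallback when available.  The relative risk otherwise serves
as a consistency diagnostic: `consistency_residuals()` compares the input
prevalence, csmr and implied RR against the forward-solved model, and large
residuals flag mutually inconsistent inputs.  With four inputs the system
is over-determined; we deliberately privilege the measured csmr over the
modelled RR import.

## Age interpolation

Inputs arrive in five-year bands; the model runs on single ages 0–99.
`to_single_ages()` fits a natural cubic spline through (band midpoint,
band value) knots — the terminal open-ended band's knot sits five years
above its lower bound, i.e. at the midpoint of a notional ten-year band —
evaluates it at single-age interval midpoints $a + 0.5$, holds the curve
constant beyond the outer knots, and clamps the result to the measure's
admissible range (prevalence to $[0,1]$, rates to $\ge 0$).  Clamping
after a plain cubic spline, rather than a shape-constrained spline, keeps
the method the standard one; the clamp only engages on pathological
inputs.

Two grid conventions coexist deliberately.  Occupancies are naturally
reported at exact integer ages (where constant-hazard closed forms such as
$p(a) = 1 - e^{-ia}$ hold exactly), while *schedules* — interpolated
inputs and everything fed to the inversion — live at interval midpoints.
`forward_solve()` therefore also reports `p_mid`/`csmr_mid`; mixing the
two conventions would introduce a half-year shift worth several per cent
at realistic hazard slopes.  The prevalence derivative uses a fourth-order
centred stencil in the grid interior (second-order beside the ends,
one-sided at the ends); the remaining round-trip error is
discretization-limited by the piecewise-constant hazards, about
$6\times10^{-4}$ relative at an incidence log-slope of 0.05 per year of
age and growing roughly quadratically with the slope.  Ages where the
inversion would return a negative incidence are floored at zero and
flagged rather than failing, since sampling noise near zero prevalence
makes small negative values routine.

## Secular trend adjustment

A cross-section's prevalence at age $a$ was generated by that cohort's
*past* incidence.  When incidence changes by a constant proportion
$\delta$ per calendar year (since a base year, 2000 by default; rates are
frozen at the base-year level before that), the hazard the cohort aged
$a$ experienced at age $u$ is

$$i(u)\,(1+\delta)^{-(a-u)},$$

with the lag capped at the survey-to-base-year distance.  The default
configurations carry an annual change of $-2\%$ for AMI (both sexes) and
$+3\%$/$+2\%$ for stroke in men/women, trend settings appropriate to the
urban Chinese surveillance setting the presets emulate.

The trended inversion exploits a triangular structure: the survey-age
prevalence of the cohort aged $a$ depends on the current-rate schedule
only at ages $\le a$, and on $i(a)$ itself only through the cohort's final
half-year interval.  A single forward sweep — advance all cohorts one
interval at a time along their own lagged hazards, then solve a monotone
one-dimensional root problem as each cohort reaches its survey age —
therefore inverts the model exactly (the suite verifies recovery of
generating schedules to $10^{-6}$ relative and bit-identical reduction to
the untrended inversion at $\delta = 0$).  A declining trend pulls the
trended estimate below the untrended one (cohorts accumulated prevalence
under historically higher rates); a rising trend pushes it above.

## Uncertainty

Following the original uncertainty exercise, only prevalence is
perturbed: each bootstrap replicate draws every band value independently
from a normal distribution centred on the observed value with its
per-band standard deviation (taken from the `se` column, or
$(\mathrm{ci_{hi}} - \mathrm{ci_{lo}})/(2 \times 1.96)$ when only interval
bounds are given), truncates to $[0,1]$, and re-runs interpolation,
hazard derivation and inversion.  Intervals are percentile intervals
across `n_iter = 100` replicates (percentile rather than normal-theory,
appropriate at small replicate counts); the point estimate always comes
from the unperturbed run, so it is seed-invariant, and the whole exercise
is deterministic given the seed.  Truncation instead of resampling is a
deliberate simplification — at the prevalence magnitudes of
cardio/cerebrovascular disease the truncation probability is negligible.

## The completeness statistic

`completeness_ratio()` forms $\mathrm{IRR} = \text{obs}/\text{mod}$ with a
normal approximation on the log scale,
$\operatorname{var}(\log \mathrm{IRR}) =
\operatorname{var}_{\mathrm{obs}}/\mathrm{obs}^2 +
\operatorname{var}_{\mathrm{mod}}/\mathrm{mod}^2$, the observed variance
coming from Poisson counts and the modelled variance from bootstrap
replicates.  Temporal change is tested one-sidedly
(`ztest_irr_increase()`): $z = (\log\mathrm{IRR}_2 -
\log\mathrm{IRR}_1)/\sqrt{s_1^2 + s_2^2}$, $p = 1 - \Phi(z)$ for the
alternative that completeness increased.  Observed-rate confidence
intervals use Byar's approximation to the exact Poisson interval (accurate
to well under a per cent at double-digit counts).  Modelled incidence is
reported on the population scale $i\,(1-p)$ — new cases per person-year of
total population, the quantity a registry's denominator measures — and
age-group and total rollups are person-year-weighted means of single-age
rates.  Rates are kept per person-year internally; "per 100,000" and
two-decimal ratio rounding appear only in the formatted report tables.
The `incidence_mortality_ratio()` diagnostic mirrors the classic
plausibility check: a registry capturing most cases of a disease with case
fatality below one should report more incident cases than deaths.

## Synthetic worlds

Because the real inputs behind such analyses (burden-of-disease prevalence
/ remission / relative-risk extracts and registry denominators) are not
deposited anywhere machine-readable, validation runs on synthetic worlds
(`make_world()`) whose ground truth is known exactly:

* smooth parametric hazards — exponential-in-age incidence and case
  fatality, constant remission (0.30/yr for the acute-resolution AMI-like
  preset, 0.02/yr for the chronic stroke-like preset), Gompertz
  other-cause mortality;
* preset magnitudes shaped to urban Chinese cardio/cerebrovascular
  epidemiology (AMI-like incidence declining 2%/yr, stroke-like rising
  3%/2%/yr, steep age gradients, maximum prevalence checked below 0.2 for
  the AMI-like preset);
* a per-band reporting fraction $\rho \in [0,1]$ (defaults mirror the
  sex gap of the motivating setting: 0.42/0.30 for AMI-like men/women,
  0.55/0.53 for stroke-like);
* a default population of $10^5$ person-years per single age through
  mid-life, tapering linearly above age 60.

The world's "true" cross-sectional prevalence is computed by
forward-solving every cohort along its own trended hazard history, so the
emitted inputs and the trend-adjusted inversion are mutually consistent by
construction.  `emit_model_inputs()` band-averages the truth
(person-year-weighted) and attaches standard deviations as a coefficient
of variation (default 0.05, a GBD-style relative uncertainty);
`emit_surveillance()` thins incident events by $\rho$ and draws Poisson
counts (independent thinning being the standard surveillance model), with
death counts drawn at full completeness.  The seed applies a small
deterministic jitter to the hazard parameters so replicate worlds differ.
A 28-day-recurrence counting rule is represented only as an optional
incidence-inflation factor, not by event-level simulation.

What passing recovery tests on these worlds does **not** show: real
inputs are not internally consistent (they come from different systems
and a meta-regression), real reporting is not an age-homogeneous Poisson
thinning within bands, and the modelled "truth" is itself a model.  The
synthetic suite validates the *machinery* — that the pipeline recovers
known reporting fractions to within a few hundredths when its assumptions
hold — not the epidemiological accuracy of any particular application.

## Numerical choices and problem sizes

* Age grid 0–99 single years; default reporting bands 0–4 … 90–94, 95+.
* Prevalence floor for the case-fatality ratio: $10^{-6}$.
* Root solves in the trended inversion: bracket $[0, 10]$ per
  person-year, `uniroot` tolerance $10^{-14}$.
* Bootstrap default: 100 iterations, 95% percentile intervals.
* The validation suite runs 20 recovery worlds at $10^7$ person-years per
  band, a 200-replication coverage study at 100 bootstrap iterations
  each, and 2,000 null simulations for the Z-test size — sizes chosen so
  the whole suite completes in well under a minute on a single core while
  keeping Monte-Carlo error small relative to the tolerances tested.

## Known limitations

* The estimator inherits the identifying assumption that the modelled
  incidence is the gold standard; biased prevalence or mortality inputs
  translate directly into biased completeness.
* The open-ended terminal age band is represented by a knot five years
  above its lower bound; band-mean round-trips there are a few per cent
  looser than for closed bands, and estimates above age ~85 should be
  read cautiously.
* The trend model is a single constant proportional change since a base
  year, applied to incidence only (remission and case fatality are held
  at current levels along cohort lines).
* Only prevalence uncertainty is propagated, matching the original
  exercise; mortality and remission uncertainty would widen the intervals
  further.
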