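---
title: "Methods: small-area life expectancy and the lives-saved simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-area life expectancy and the lives-saved simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models and numerical choices behind
`lifegain`: the Chiang abridged life table, the negative binomial
small-cell smoothing, the agent-based lives-saved simulation, the
equivalence analyses, and the synthetic-city generator that the test
suite uses in place of restricted vital-statistics data. It also states
what passing the tests does and does not demonstrate about real data.

## Data model

The package works on four plain tabular structures, all on a common
age-band schema (default 0–4, 5–9, …, 80–84, 85+):

* individual death records: geounit, calendar year, age at death in
  completed years, cause-group code, optional sex/race, and a `pseudo`
  flag marking records synthesized from aggregate counts;
* aggregate death tables: counts per geounit × year × band × cause
  (× strata);
* population tables: person counts per geounit × year × band;
* geounit covariates: proportion non-Hispanic Black, proportion
  non-Hispanic white, median household income, proportion with
  educational attainment above high school.

Ages are integers because death certificates report completed years;
fractional ages are rejected at ingest. Deaths with missing geounit or
cause are dropped and counted in a validation report. Ages above a
configurable maximum (default 110) are dropped by default or clamped on
request — vital-statistics exports differ in how they code extreme ages,
and neither choice is clearly right, so the policy is explicit.

## The Chiang abridged life table

For one geounit, deaths and person-years are pooled over the observation
window (the default, matching multi-year annualized usage; per-year
rates are available for the simulation), giving central death rates
$M_x = D_x / P_x$ per band. For a closed band of width $n_x$,

$$q_x = \frac{n_x M_x}{1 + n_x (1 - a_x) M_x},$$

where $a_x$ is the average fraction of the interval lived by those who
die in it. The terminal band has $q = 1$ and person-years $L = l / M$.
From the radix $l_0 = 100{,}000$: $d_x = l_x q_x$,
$L_x = n_x(l_{x+n} + a_x d_x)$, $T_x$ by reverse cumulative sum, and
$e_x = T_x / l_x$.

Choices worth stating:

* **$a_x$ defaults.** 0.5 for every closed band under the default
  schema. If the user supplies a schema that separates infancy, the
  conventional adjustment applies ($a_{<1} = 0.1$, $a_{1-4} = 0.4$),
  because infant deaths cluster early in the interval. No published
  value dictated this; it is the standard demographic convention.
* **Radix.** Fixed at 100,000; $e_x$ is invariant to it.
* **Degenerate inputs.** $q_x$ is clamped to 1 for extreme rates; a
  zero rate in the terminal band is an error (the open interval's
  person-years are $l/M$), which in practice the smoothing step
  prevents by filling empty old-age cells.
* **Zero-population bands** are only tolerated when they also carry
  zero deaths; deaths without exposure are a hard error naming the
  cell.

The test suite checks the implementation against an agent-based cohort
microsimulation that shares the model's assumptions but none of its
arithmetic: the band death probability is recovered *numerically* (root
finding) from the identity $M = q / (n(1-q) + a n q)$ between a band's
central rate and its per-agent person-years, band deaths are binomial
draws over the surviving cohort, decedents live $a_x n_x$ years of the
interval, and terminal survivors draw exponential lifetimes at rate
$M$. One million agents give a Monte-Carlo standard error of about
0.015 years; agreement is required within three standard errors over
fifty random human-plausible schedules. A continuous-time
piecewise-constant-hazard simulation would *not* be an unbiased oracle
here: the $a_x = 0.5$ mid-interval convention differs from exponential
within-band death timing by roughly 0.01–0.02 years of $e_0$, a real
(and well-known) model approximation rather than an implementation
property, and the oracle is designed to test the implementation.

## Small-cell smoothing

Neighborhood-level cause-specific death cells are small; cells with
fewer than five deaths (the conventional suppression/instability
cut-off) are replaced by predictions from a negative binomial
regression, fitted by maximum likelihood (log link) on all
geounit × band cells of the chosen cause, with six covariates: age at
interval start, age-specific population, and the four demographic
covariates above. Design choices:

* one model per cause, pooled across all geounits and bands;
* population enters as a covariate, matching the covariate list the
  model is defined by; a log-population offset is available behind a
  flag (`offset_population = TRUE`) for users who prefer a rate model;
* predictors are centred and scaled internally for optimizer stability;
  coefficients and their covariance are reported back-transformed to
  the raw scale;
* if the dispersion estimate degenerates (e.g. equidispersed or
  zero-variance counts), the fit falls back to Poisson and says so;
* predictions exceeding the *study-area-wide* total of the cause in
  that age band are capped at that total. The cap's reference total is
  configurable (`cap = "geounit"` caps at the cell's own observed
  count, which makes the cap binding almost always and is provided only
  for completeness; `"none"` disables it). The area-wide reading is the
  default because it is the only one under which a prediction can
  plausibly exceed the reference.
* smoothed counts stay fractional for rate computation; nothing is
  re-rounded.

The all-cause table used for life expectancy is rebuilt as observed
other-cause counts plus smoothed cause cells, so smoothing affects
observed and expected arms identically and the reported gain isolates
the intervention.

## The lives-saved simulation

A reduction scenario names a cause, a proportion $p$ (the menu
5/10/15/20% reflects achievable programmatic goals, but any value in
$(0,1)$ is accepted), a mode, a replicate count (default 100) and a
seed.

**Targeting.** In `within-age` mode the target per band-year cell is
$\mathrm{round}(p\,D_{x,y})$ (round-half-even, for reproducibility). In
`overall` mode the yearly total $\mathrm{round}(p\,D_y)$ is apportioned
across bands proportional to death shares by the largest-remainder
method, capped at the deaths available per band; the apportionment
conserves the rounded yearly total exactly. Reducing within each band
preserves the cause's age distribution exactly, but real programs
target particular age ranges, which motivates comparing both modes.

**One replicate.** For each year in ascending order, the targeted
number of that year's cause-specific decedents is drawn without
replacement and marked saved. Each saved agent then advances one
integer year of age per calendar year (crossing band boundaries as it
ages; beyond the terminal bound it stays in the open band) and dies
with probability equal to its peers' annual all-cause rate for its
current band and year — a Bernoulli draw per agent-year. Agents who die
are removed from the lives saved and their deaths are re-added to the
expected table at the band where they died. Net lives saved are tallied
at the band of original selection, keeping the accounting aligned with
the bands whose deaths were reduced. If a target exceeds the available
decedents, everything available is averted and the shortfall is logged.

Peer mortality in follow-up is *all-cause* (survivors of an averted
heart-disease death face the full mortality of their peers, including
heart disease again); that is the natural reading of "the same
mortality rate as their peers", and a cause-specific-only attrition
hook exists for sensitivity work. A deterministic mode replaces the
Bernoulli draws by expected survivor weights, which is variance-free
and used to verify the stochastic mode against the closed-form
expectation $\sum_y t_y \prod_{y'>y}(1 - M_{b(y'),y'})$.

**Aggregation over replicates.** Each replicate runs on an
independently derived seed stream (results do not depend on execution
order), and the median across replicates — per band — of net lives
saved and of the signed death-table change summarizes the run. The
expected death table is the observed all-cause band total plus the
median signed change, floored at zero; expected life expectancy comes
from pushing that table through the same smoothing-consistent rate and
Chiang path as the observed arm. A zero-proportion scenario is exactly
the identity, which the tests assert bit-for-bit.

## Equivalence analyses and ranking

`rank_geounits()` computes observed/expected life expectancy and gain
for every geounit (per-geounit seeds derived from one root seed),
sorts by gain with ties broken by geounit id, and reports the median
and IQR of gains using linear-interpolation quantiles (R type 7), so
distribution summaries are exactly reproducible.

`compare_reduction_modes()` and `compare_individual_vs_aggregate()`
quantify the package's two methodological equivalences as squared
Pearson correlations across geounits ($R^2$ of paired outputs, not a
regression through the origin): overall versus within-age reductions,
and individual-level versus aggregate-level input. The aggregate arm
expands counts to pseudo-individuals assuming deaths are uniform across
each 5-year band: a cell of $k$ deaths over width $w$ places
$\lfloor k/w \rfloor$ deaths on every single-year age deterministically
and assigns the remainder by a seeded draw without replacement, so
re-aggregation returns the input table *exactly* and the expansion is
reproducible. The open 85+ band uses a configurable span (default
85–89), mirroring the closed bands. Stratified cells expand
independently, preserving stratum proportions within each age group.
Both arms of every comparison share the smoothing model and the
per-geounit seed streams, so the comparison is not confounded by
Monte-Carlo noise.

On the default synthetic city, both equivalences are tight: the mode
comparison rounds to $R^2 = 1$ and the aggregate comparison exceeds
0.99 for both expected deaths and expected life expectancy (the
acceptance script recomputes these numbers; the vignette does not
assert values the code has not printed).

## The synthetic city

Because neighborhood-level death records are restricted, the generator
produces a city with the structure such data would have, with known
ground truth:

* 55 geounits of 5,000–20,000 residents (uniform totals, fixed
  plausible urban age structure), five calendar years;
* a Gompertz–Makeham baseline hazard
  $M(x) = 4\times10^{-4} + 6.377\times10^{-5} e^{0.09x}$ at band
  midpoints plus an infant-band excess of $8\times10^{-4}$, calibrated
  so the baseline life expectancy is 73.0 years (crude death rate
  ≈ 10.6 per 1,000) — the order of magnitude of a large US city with
  marked health inequities;
* geounit heterogeneity as a multiplicative rate factor
  $\log m_g = 0.40(\text{propBlack}-0.5) - 0.10\,z_{\text{income}} -
  0.06\,z_{\text{educ}} + \varepsilon$, $\varepsilon \sim N(0,
  0.08^2)$, giving a true life-expectancy spread of roughly 15 years
  across geounits — comparable to the near-20-year gaps documented
  between neighborhoods of one city;
* cause shares constant across bands (leading cause 24.4%, cancer
  21.3%, stroke 4.9%, injury 8.0%, remainder "other"), so the leading
  cause's empirical share reproduces ~24% of deaths;
* death counts per (geounit, year, band, cause) drawn negative
  binomially (size 10) around population × rate, then expanded to
  individual records with uniform ages within bands.

Everything is deterministic given the seed, and the truth (per-geounit
rate schedules, multipliers, $e_0$) is returned for recovery tests.

What the generator does *not* emulate — and therefore what passing
tests cannot show about real data: cause shares that vary with age
(heart-disease shares in reality rise with age; a constructed fixture,
not the generator, exercises the young-age-burden ranking behavior),
year-to-year population drift and trend in rates, spatial correlation
between neighboring geounits, coding errors in cause or residence, and
sex/race-specific mortality schedules (the generator assigns sex at
random, which suffices to exercise stratified code paths but carries no
sex effect). Results on the synthetic city validate the *machinery*,
not any substantive claim about a particular city.

## Problem sizes and runtime choices

The test suite runs the full 55-geounit city with 100 replicates for
the equivalence checks, a one-million-agent cohort oracle over fifty
random schedules for the life-table check, 500 replicates on a
hand-computable two-band system for the simulation expectation, and 100
random tables for the aggregation round-trip; the whole suite completes
in well under a minute on one core. These sizes were chosen so that
Monte-Carlo standard errors are small relative to the tolerances being
asserted, with determinism guaranteed by fixed seeds throughout.

Two statistical details in the tests deserve a note. The smoothing
recovery check verifies seven regression coefficients at once; a
per-coefficient two-standard-error rule would falsely fail about a
quarter of correctly-working runs, so the acceptance check uses
three-standard-error per-coefficient bounds together with a jointly
sized Wald test (7 d.f., 99.9% quantile). And because targeted counts
are integers, a 5% reduction can legitimately round to zero averted
deaths in small cells; the monotonicity check therefore requires gains
to be non-negative and non-decreasing in the proportion, and strictly
positive at 20%.

## Known limitations

* Single-cause scenarios only; no competing-risk reassignment of
  averted deaths to other causes, so gains are optimistic for causes
  with strong comorbidity.
* No confidence intervals on life expectancy (the Chiang variance
  estimator is out of scope); replicate spread in the simulation is
  available but is Monte-Carlo, not sampling, uncertainty.
* The smoothing model is pooled across bands with age as a covariate;
  strongly non-log-linear age patterns of a cause will be smoothed
  imperfectly in sparse cells.
* Follow-up stops at the observation window's end; lives saved near
  the window's last year face little attrition, which mildly favors
  late-window aversions.
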