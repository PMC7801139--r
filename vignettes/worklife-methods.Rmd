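---
title: "Methods: multistate estimation of working life expectancy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multistate estimation of working life expectancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(worklife)
```

## The problem

Administrative registers record a person's working life as overlapping
*episodes*: earnings spells, sickness allowances, rehabilitation spells,
pensions, unemployment benefits. Two things make life-course summaries from
such data non-trivial. First, episodes overlap — a person can draw an
unemployment benefit while having a (marginal) earnings spell — so a
deterministic rule set must resolve each calendar day into exactly one
labor-market state. Second, people move repeatedly in and out of work, so
single-exit survival summaries understate time at work; a multistate model
that allows re-entry is needed.

`worklife` implements that pipeline for the age window 50–63: daily state
assignment over seven states, a 27-transition multistate Cox model on the
age axis, Aalen–Johansen transition probabilities, expected length of stay
(ELOS), and the working-life-expectancy (WLE) / working-years-lost (WYL)
decomposition with percentile bootstrap intervals.

## State space and assignment rules

The seven states, in the canonical order that fixes transition numbering,
are: work, time-restricted work disability, unemployment, economic
inactivity, disability retirement, retirement, death. Death is absorbing;
retirement can only lead to death; disability retirement only to retirement
or death; the four active states communicate freely. This gives
4 × 6 + 2 + 1 = 27 transitions, enumerated row-major so that ids are
reproducible across runs. The structure is data (a 0/1 matrix), not code,
so reduced spaces (e.g. a three-state illness–death model) reuse all the
machinery — the simulation studies below exploit this.

Daily assignment applies explicit overrides first:

* part-time sickness allowance counts as **work** (recipients must work
  part of the time);
* a partial disability pension counts as **work** when an earnings spell is
  concurrent, otherwise as time-restricted work disability;
* any unemployment benefit **overrules** concurrent earnings;
* full sickness allowance, vocational rehabilitation and temporary
  disability pension are time-restricted work disability; a full permanent
  disability pension is disability retirement; an old-age or early pension
  is retirement; a day with no episode at all is economic inactivity.

Remaining simultaneity is broken by a configurable priority order,
defaulting to death > retirement > disability retirement > time-restricted
work disability > unemployment > work > economic inactivity. Ranking
non-working states above work avoids understating WYL. Two conventions in
this order are package decisions rather than settled methodology and are
therefore arguments of `assign_daily_states()`: ill-health ranks above
unemployment when both benefits are drawn on the same day, and a state
change takes effect on the first day of the winning episode. Follow-up ends
at the earliest of the study end date, death, and the day before the age
variable (entry age + days/365.25) reaches 63.

## Estimation

Every sojourn in a non-absorbing state is expanded into one counting-process
record per allowed exit (competing-risks long format), with entry age at the
sojourn start (delayed entry / left truncation) and exit age at the state
change or censoring. Each of the 27 transitions gets its own Cox model with
the same covariate set — the Markov assumption: intensities depend on the
current state, age, and baseline covariates only. Analyses are stratified by
gender (separate pipelines, no gender covariate).

Numerical choices:

* **Ties.** Breslow approximation. Ages have day resolution, so ties are
  common; Breslow composes cleanly with the Breslow baseline estimator.
* **Baseline hazard.** Breslow estimator at the fitted coefficients,
  computed with reverse cumulative sums over entry/exit-sorted weights
  (O(n log n)). When a degenerate fit produces extreme linear predictors,
  the subtraction of cumulative sums can cancel catastrophically; those
  event times are recomputed by exact summation over the risk set.
* **Degenerate fits.** Covariate columns without variation are dropped and
  their coefficients fixed at 0, so "identical covariates give beta = 0"
  holds exactly and bootstrap resamples cannot crash. A transition with
  zero events keeps a null baseline (identity factor in the product
  integral) and is reported via a message. Monotone likelihoods (possible
  on sparse transitions at small n) are left as `survival::coxph` returns
  them; see the capping rule below for why this stays bounded.
* **Product integral.** The Aalen–Johansen estimator multiplies
  `I + dA(u)` over the pooled event ages of all transitions, where the
  off-diagonals of `dA(u)` are the profile-adjusted increments and each
  diagonal is minus its row sum. Rows therefore sum to one by construction
  and are never renormalized by division. If an extreme covariate profile
  pushes a row's off-diagonal sum above 1, the row is scaled so the
  diagonal of `I + dA` stays at 0 (a message is emitted); this is the same
  guard that mstate-style estimators need and affects only ages with tiny
  risk sets.
* **ELOS.** The integral of `P_work,j(50, u)` uses left-endpoint step
  evaluation, which is exact for the càdlàg step estimator. Consequently
  WLE + ΣWYL = 13 years to floating-point accuracy for every profile —
  this conservation is asserted in the tests rather than imposed.

One modelling ambiguity is left to the user: stratified summaries can come
either from models with a single covariate set (class only / exposure only)
or from a joint model evaluated at covariate profiles. Both are supported
(`covariate_mode` of `run_config()`: `class`, `exposure`, `joint`); the
default output mirrors the stratification of typical published tables. In a
class-only model the class coefficients absorb any correlated workload
effects, which is visible in the synthetic example of the README.

## The bootstrap

Uncertainty intervals resample *persons* (not records) with replacement at
the original cohort size, re-run the entire estimation per resample, and
take the empirical 2.5th/97.5th percentiles of each summary (B = 100 by
default). A master seed spawns one sub-seed per replicate, so results are
reproducible and independent of execution order. With B = 100 the
percentile interval is coarse and mildly anticonservative; no
normal-approximation alternative is offered because the percentile
definition is the one the method targets.

## The synthetic register generator

Because real register data of this kind are confidential, the package ships
a generator whose output has the statistical structure the analysis
assumes: a cohort aged 50–63 at a common baseline (2005-01-01), all in work
at entry, followed to a study end date (2014-10-31) and censored at age 63.
Latent trajectories are a continuous-time Markov chain on the age axis with
piecewise-constant baseline intensities over the bands 50–55, 55–60, 60–63
(events per person-year) and proportional covariate effects, simulated by
competing exponentials within bands, then discretized to days. Latent
states are rendered as episode records (earnings for work, benefit spells
otherwise, a one-day death episode, no episode for economic inactivity),
and a configurable share of benefit episodes receives a spurious
overlapping earnings spell so the priority rules are exercised. With no
injected overlaps, assignment recovers the latent trajectory exactly
(round-trip identity, tested).

Default parameter choices, made once:

* entry ages uniform on [50, 63] — no age distribution is prescribed, and
  uniform entry maximizes coverage of the delayed-entry machinery;
* baseline intensities with plausible magnitudes for an older workforce
  (rising ill-health exits with age, old-age retirement concentrated in
  60–63, high return-to-work from short sickness spells);
* covariate effects with the expected epidemiological directions (manual
  class and high physical exposure raise ill-health and unemployment exit
  intensities and slightly lower re-employment; the self-employed have
  lower unemployment and ill-health exits), with deliberately strong
  magnitudes so that effect-recovery tests have signal at moderate n;
* a small gender-specific job-exposure matrix over eleven occupation codes
  whose class-specific pools span all three exposure categories (none,
  1–3, 4–5 exposed factors at the 0.40 dichotomization threshold).

No published per-transition hazard ratios exist for this design, so the
generator's parameterization cannot (and does not claim to) reproduce any
real national workforce; it defines a synthetic population with known
ground truth. Features of real registers it does not emulate: benefit
amounts and eligibility clocks, calendar-time legislation changes, seasonal
employment, occupation changes after baseline, and within-person
heterogeneity beyond the two baseline covariates. Passing tests therefore
certify the *estimator* and the *pipeline*, not any substantive claim about
a real population.

## Verification strategy and problem sizes

Every non-trivial computation is checked against an independent oracle:

* transition enumeration vs a brute-force loop over rule sets (including
  randomized spaces up to six states);
* Cox coefficients vs direct maximization of a hand-coded partial
  likelihood on ≤10-record fixtures (agreement to 1e-6);
* the Breslow baseline vs `survival::survfit` Nelson–Aalen at beta = 0,
  and adjusted cumulative hazards vs subgroup Nelson–Aalen;
* the covariate-free Aalen–Johansen estimator vs a simple independent
  implementation on small cohorts (exact agreement);
* constant-hazard scenarios vs closed forms: a two-state exponential
  cohort of 50 000 reproduces WLE = (1 − e^(−1.3))/0.1 within 1%, and a
  20 000-person illness–death cohort reproduces the matrix-exponential
  solution of the Kolmogorov forward equations within Monte-Carlo error;
* Wald coverage of configured log hazard ratios: 100 replicates of a
  20 000-person illness–death cohort with a binary covariate;
* bootstrap coverage of the true WLE (computed deterministically by a
  fine-grid product of matrix exponentials, not by resimulation): 100
  replicates of a 400-person cohort with B = 100.

The simulation-study sizes (n = 50 000 / 20 000 / 400, 100 replicates) are
the package's chosen trade-off between Monte-Carlo precision and a test
suite that runs in minutes; the closed-form checks use cohorts entering at
exactly age 50 so the full 13-year window is observed.

## Known limitations

* The Markov assumption ignores duration-in-state effects (no semi-Markov
  clocks); this mirrors the standard design for this estimator.
* Separate unpenalized Cox fits on 27 transitions can produce monotone
  likelihoods on sparse transitions in small cohorts; estimates stay
  bounded through the product-integral guard, but profile-adjusted
  summaries for such strata should be read with care (real register
  applications have orders of magnitude more events).
* Occupation, class and exposure are fixed at baseline; time-varying
  covariates are out of scope.
* The percentile bootstrap with B = 100 gives coarse interval endpoints;
  increasing `B` is the only remedy offered.
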