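# worklife

Multistate estimation of working life expectancy (WLE) and working years
lost (WYL) between ages 50 and 63 from episode-level register data.

`worklife` is aimed at researchers in occupational epidemiology and labor
economics who study late-working-life dynamics with administrative register
data: employment and benefit spells that overlap, many transitions in and
out of work, delayed entry at different ages, and administrative censoring.
The package turns raw episode records into daily labor-market states,
estimates a multistate Cox model, and integrates the resulting transition
probabilities into life-course summaries with bootstrap confidence
intervals. A synthetic register generator with known ground truth makes
every stage testable without access to confidential data.

## The model

Seven daily states are distinguished: work, time-restricted work disability
(full sickness absence, vocational rehabilitation, temporary disability
pension, or partial disability pension without concurrent earnings),
unemployment, economic inactivity, disability retirement, retirement, and
death. Death is absorbing, retirement may only lead to death, and
disability retirement only to retirement or death; the four remaining
states communicate freely, giving **27 allowed transitions**.

For each transition *j → k* a Cox proportional hazards model is fitted on
the **age** time axis with delayed entry (left truncation at the age of
cohort entry) and Breslow handling of ties:

    λ_jk(t | z) = λ0_jk(t) · exp(β_jk' z)

with z the covariates (occupational class and/or physical-workload exposure
category, both derived at baseline; exposure comes from a gender-specific
job-exposure matrix dichotomized at 0.40). The Breslow baseline cumulative
hazards, adjusted by the fitted hazard ratios for a covariate profile, feed
the Aalen–Johansen product integral

    P(s, t) = ∏_{s < u ≤ t} ( I + dA(u) )

which yields the full matrix of transition probabilities from age *s* under
the Markov assumption. The expected length of stay in state *j* is

    ELOS_j = ∫_50^63 P_work,j(50, u) du

computed exactly for the step-function estimator. WLE is ELOS in work;
WYL = 13 − WLE is decomposed into the expected years spent in each of the
six non-work states, so WLE + ΣWYL = 13 by construction. Uncertainty comes
from a percentile bootstrap: persons are resampled with replacement, the
whole estimation is re-run (default B = 100), and the 2.5th/97.5th
percentiles are reported.

## Worked example

```r
library(worklife)

sim     <- simulate_register(sim_config(n_persons = 2000, seed = 42))
persons <- add_exposure(sim$persons[, c("person_id", "gender",
                                        "occupational_class",
                                        "occupation_code", "entry_age")],
                        sim$jem)
traj    <- assign_trajectories(sim$episodes, persons,
                               sim$config$baseline_date,
                               sim$config$study_end_date)
struct  <- transition_structure(canonical_state_space())
records <- to_transition_records(traj, persons, struct)
fit     <- fit_multistate(records, persons, struct,
                          c("class_manual", "class_lower_non_manual",
                            "class_self_employed"))
manual  <- lifecourse_summary(fit, make_profile(fit$covariates,
                                                class = "manual"))
print(manual)
```

```
WLE: 4.43 years (of 13 potential)
WYL by state (years):
time_restricted_work_disability           disability_retirement
                           0.74                            3.43
                          death                    unemployment
                           1.36                            1.56
            economic_inactivity                      retirement
                           0.50                            0.98
total WYL: 8.57
```

A manual worker in this synthetic cohort is expected to spend 4.43 of the
13 potential years at work; the complement decomposes into 3.43 years lost
to disability retirement, 1.56 to unemployment, and so on (the seven
components always sum to 13.00). The synthetic defaults deliberately use
strong class and exposure effects, and in a class-only model the manual
coefficient also absorbs the correlated workload exposure, so the class
gradient here is much steeper than in real register populations:

```r
upper <- lifecourse_summary(fit, make_profile(fit$covariates))
round(wyl_difference(upper, manual), 2)
#>                                 WLE_diff
#>                                     3.33
#> WYL_diff_time_restricted_work_disability
#>                                    -0.28
#>           WYL_diff_disability_retirement
#>                                    -2.20
#> ...
```

Upper non-manual employees gain 3.33 years of WLE over manual workers,
mostly by avoiding disability retirement (2.20 years). `run_pipeline()`
wraps all of the above (including gender stratification, the
self-employed-exclusion sensitivity switch, and the bootstrap) behind a
YAML-configurable interface, and `inst/cli/worklife.R` exposes it on the
command line.

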