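# crsim — empirical simulation for competing risks

`crsim` is an R toolkit for understanding, analysing and *planning*
competing-risks studies from a simulation point of view. It is aimed at
biostatisticians and trialists working with time-to-first-event data where
the event can be one of two mutually exclusive types — e.g. a composite
cardiovascular endpoint versus death from other causes.

The organising idea is that the two cause-specific hazards (CSHs)
α₀₁(t), α₀₂(t) are momentary event forces that generate the data in two
steps:

1. the event time *T* is drawn from the all-cause distribution, whose hazard
   is α₀₁(t) + α₀₂(t);
2. at *T*, the event type is drawn: cause *j* with probability
   α₀ⱼ(T)/(α₀₁(T) + α₀₂(T)).

Because every estimand — the survival function P(T > t), the cumulative
incidence functions P(T ≤ t, X_T = j) — is a deterministic function of
*both* CSHs, a treatment effect on one hazard cannot be interpreted without
the other hazard and both baselines. `crsim` makes this concrete: any
control dataset becomes a discrete simulable law, treatment arms are
generated under ideal proportional-CSH models exp(βⱼ)α₀ⱼ(t) with optional
monotone transformations of the baselines, and replicated studies report
what a cause-specific Cox analysis would see.

## What is in the box

| Layer | Functions |
|---|---|
| Data | `crdata()`, `read_crdata()`, `write_crdata()`, `summary()` |
| Estimation | `nelson_aalen()`, `kaplan_meier()` (event & censoring roles), `aalen_johansen()`, `evaluate()`, `write_estimate_csv()` |
| Empirical law | `empirical_law()`, `law_from_hazards()`, `implied_cif()`, JSON I/O |
| Scenarios & simulation | `scenario()`, `apply_scenario()`, `simulate()`, `simulate_trial()`, `draw_events()` |
| Regression | `cscox()` — cause-specific Cox model, Breslow ties, native Newton–Raphson |
| Study runner | `run_scenario()`, `run_table()`, `table1_scenarios()`, `point_mass_comparison()`, `power_curve()` |
| Control fixture | `calibrate_fixture()`, `generate_fixture()` |

A thin command-line wrapper with `fixture`, `estimate`, `simulate` and
`study` subcommands is installed at `inst/cli/crsim.R`.

## Worked example

A control cohort resembling a dialysis-trial placebo arm (636 patients,
38.2% events of interest, 20.3% competing events, 41.5% censored, roughly
constant hazards) is calibrated and generated, turned into a law, and used
to plan a trial under a treatment that lowers the hazard of interest by
exp(−0.3) ≈ 0.74 while leaving the competing hazard untouched:

```r
library(crsim)

spec <- calibrate_fixture()          # solve for the constant hazards
spec
#> Constant-hazard fixture: lambda1 = 0.14923, lambda2 = 0.07922 per year
#>   censoring ~ Uniform(2, 6), default n = 636

control <- generate_fixture(spec, seed = 2026)
summary(control)
#> n = 636 subjects
#>   event of interest    249 (39.2%)
#>   competing event      117 (18.4%)
#>   censored             270 (42.5%)

empirical_law(control)
#> Empirical competing-risks law: 366 support points, tail mass 0.2860
#>   event mass 0.7140, censoring distribution on 270 points

# one simulated 500-per-arm trial, analysed with a cause-specific Cox model
fit <- cscox(simulate_trial(control, scenario(-0.3, 0), seed = 1), cause = 1)
fit
#> Cause-specific Cox model (cause 1, Breslow ties)
#>   log CSH ratio -0.4056 (se 0.1076), CSH ratio 0.6666 [0.5398, 0.8231], p = 0.000164
#>   356 events, n = 1000, 4 iterations

# the full replicated study: bias, empirical CI, coverage, power
run_scenario(control, scenario(beta1 = -0.3, beta2 = 0),
             n_replicates = 1000, seed = 7)
#> Scenario study: 1000 replicates (0 failed)
#>   cause 1: true -0.30, mean -0.308, emp. 95% CI [-0.517, -0.094], coverage 94.9%, power 82.0%
#>   cause 2: true +0.00, mean +0.002, emp. 95% CI [-0.273, +0.297], coverage 95.3%, power 4.7%
```

Reading the last block: across 1000 simulated trials the cause-specific Cox
estimate is essentially unbiased for β₁ = −0.3, the Wald interval covers at
its nominal 95% level, a trial of this size detects the effect about 82% of
the time — and the null competing-event test rejects at its nominal 5% size.
The tail mass of 0.286 is the probability the control Kaplan–Meier never
spends within the observed horizon; simulated event times drawn from it are
always censored.

`run_table(control, table1_scenarios(), ...)` runs the built-in ten-scenario
design (effects −0.1/−0.3 crossed with competing effects 0/0.3/−0.3 and
baseline transformations x↦x^¼, x↦x²), and `power_curve()` turns the same
machinery into a sample-size tool. `point_mass_comparison()` visualises how
a scenario moves event-time mass between arms, overall and for cause-1
times only.

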