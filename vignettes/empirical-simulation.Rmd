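---
title: "Empirical simulation of competing risks: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical simulation of competing risks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsim)
```

## The model

A two-cause competing-risks process starts in an initial state and moves, at
the event time $T$, into one of two absorbing states: the event of interest
($X_T = 1$) or the competing event ($X_T = 2$). The stochastic behaviour of
the process is fully determined by the two cause-specific hazards (CSHs)

$$\alpha_{0j}(t)\,dt = P(T \in dt,\ X_T = j \mid T \ge t), \qquad j = 1, 2,$$

which act as momentary event forces. Their sum $\alpha_{0\cdot}$ drives *when*
an event happens; their ratio drives *which* event happens. This is the
two-step reading that the package operationalises:

1. draw $T$ from the all-cause distribution $1 - P(T > t)$, whose hazard is
   $\alpha_{01}(t) + \alpha_{02}(t)$;
2. at $T$, draw the event type: cause $j$ with probability
   $\alpha_{0j}(T)/\alpha_{0\cdot}(T)$.

All standard estimands are deterministic functions of the CSHs: the survival
function $P(T > t) = \exp(-A_{01}(t) - A_{02}(t))$ in the continuous case,
and the cumulative incidence functions (CIFs)
$P(T \le t, X_T = j) = \int_0^t P(T > u-)\,\alpha_{0j}(u)\,du$, which add up
to the all-cause distribution function. A treatment that lowers the hazard of
interest ($\beta_1 < 0$ in a proportional-CSH model) therefore does *not*
automatically lower the CIF of interest: the competing hazard and both
baselines enter too. The package exists to make such constellations easy to
construct, simulate and inspect.

## Estimation

`nelson_aalen()` computes the cumulative CSH estimator
$\hat A_{0j}(t) = \sum_{s \le t} d_j(s)/Y(s)$ over observed cause-$j$ event
times, `kaplan_meier()` the product-limit survival estimator (which equals
the product-integral of the pooled Nelson-Aalen increments exactly) and
`aalen_johansen()` the CIF plug-in
$\sum_{s\le t} \hat S(s-)\, d_j(s)/Y(s)$. Three conventions are fixed
throughout and matter for exactness:

* **Ties.** At a time carrying both events and censorings, events are
  processed first: subjects censored at $t$ remain in the risk set for events
  at $t$. The same convention with roles swapped defines the censoring-role
  Kaplan-Meier.
* **Left limits.** $\hat S(s-)$ is the value at the previous jump (1 before
  the first event time).
* **Evaluation beyond the data.** All curves freeze at their last jump; they
  are never extrapolated.

With these conventions two identities hold to machine precision on *every*
dataset, and the test suite asserts them at $10^{-12}$:
$\widehat{CIF}_1(t) + \widehat{CIF}_2(t) = 1 - \hat S(t)$, and
$\hat S = $ product-integral of the pooled hazard increments.

The Nelson-Aalen variance accumulates $d_j(s)/Y(s)^2$, the simplest of the
standard choices, and pointwise 95% limits use the log transformation
$\hat A\,\exp(\pm 1.96\,\widehat{se}/\hat A)$. These are display aids; no
downstream computation consumes them.

## The empirical law

`empirical_law()` converts a dataset into a discrete simulable distribution:

* the support is the set of observed event times; each carries the drop of
  the all-cause Kaplan-Meier there, $\hat S(s-) - \hat S(s)$;
* the probability that the Kaplan-Meier curve never spends (it does not reach
  zero when the largest observation is censored) becomes a **tail point
  mass**: draws from it represent events beyond the observed horizon and are
  always censored in simulated data;
* each support point carries the binomial cause-1 probability
  $d_1(s)/(d_1(s)+d_2(s))$ — in real data usually 0 or 1, because two causes
  rarely share a time point;
* the censoring distribution is the discrete law of the censoring-role
  Kaplan-Meier. It must be proper; if it has unspent mass (the largest
  observation was an event), that mass is parked just after the largest
  observed time and a warning is raised, so simulated subjects can always
  receive a censoring time.

`law_from_hazards()` goes the other way, from a pair of cumulative-hazard
step functions to a law, using the **discrete product-integral**
$S(t) = \prod_{s\le t}(1 - \Delta A_1(s) - \Delta A_2(s))$ rather than
$\exp(-A)$. The discrete form is what makes `empirical_law()` and
`law_from_hazards()` exact inverses on empirical input — the package
operates on step-function estimators end to end, so the continuous
exponential relation would introduce systematic error at every jump.
A pooled increment above 1 means the inputs no longer define a
distribution (a transformation or hazard ratio pushed a late, large
increment past 1); increments within $10^{-9}$ above 1 are clamped as float
slack, anything larger is an error that names the offending time rather
than a silent truncation.

## Scenarios

`scenario()` bundles the treatment effects and baseline manipulations:
log CSH ratios $\beta_1, \beta_2$ (the treatment arm's hazards are
$e^{\beta_j}\,\alpha_{0j}$), and monotone transformations of each cumulative
baseline hazard with $f(0)=0$. Two are built in: $x \mapsto x^{1/4}$, which
amplifies a cumulative hazard below 1, and $x \mapsto x^2$, which shrinks
it. Transformations act on the *cumulative* hazard, after which increments
are recovered by differencing on the original support — the support is a
fixed feature of the empirical input, and monotonicity plus $f(0)=0$
guarantee nonnegative increments. `table1_scenarios()` ships the ten-row
reference design crossing $\beta_1 \in \{-0.1, -0.3\}$ with
$\beta_2 \in \{0, 0.3, -0.3\}$ and the two transforms.

Both arms share the control censoring distribution: the censoring mechanism
is a property of the study, not of the treatment.

## Simulation and analysis

`simulate()` on a law applies the two-step algorithm and then attaches an
independent censoring draw per subject; the observed time is the minimum. A
tie between event and censoring time — possible with discrete laws, though
never in continuous data — counts as an observed event, mirroring the
events-first estimator convention so that estimate → simulate → estimate is
self-consistent. Tail draws receive a censoring time like everyone else and
are recorded as censored at it.

`cscox()` fits the cause-specific Cox model for the binary group covariate,
recoding other-cause events as censored. Ties use the Breslow
approximation: discrete laws generate many tied event times by design, and
Breslow's is the form whose partial likelihood is simple enough to verify
against dense grid search, which the tests do on every small fixture to
$10^{-4}$. Newton-Raphson starts at 0, uses step-halving, and stops at
score $< 10^{-8}$ or step $< 10^{-10}$ (max 50 iterations). Before
iterating, the fitter checks that the score changes sign over the real
line; configurations without a finite maximiser (complete separation and
its risk-set-degenerate relatives) are returned as non-converged fits with
`NA` coefficient rather than errors, and scenario studies count them as
failed replicates. Only the single binary covariate is supported — exactly
the two-arm design the scenario machinery generates.

## The scenario study

`run_scenario()` repeats simulate-and-fit `n_replicates` times and
aggregates, per cause: the mean estimate, the empirical 95% confidence
interval, Wald coverage of the true $\beta_j$, and empirical power
(two-sided Wald $p < 0.05$, equivalently the 95% Wald interval excluding
0). Two reporting conventions were genuinely open and are fixed as follows,
deliberately and visibly:

* the *empirical confidence interval* is the pair of 2.5th/97.5th
  percentiles of the replicate estimates, computed with R's default
  interpolated quantile (type 7) — not mean $\pm 1.96\,$SD;
* *power* is the rejection fraction of the two-sided 5% Wald test; under a
  true null it estimates the test's size.

Seeding follows a spawning rule: a throwaway RNG seeded with the master
seed draws one sub-seed per replicate (and, in `run_table()`, one per
scenario before that), so every replicate is individually reproducible and
a scenario's results do not depend on which other scenarios run. Identical
inputs give byte-identical reports.

`point_mass_comparison()` exposes the two-step reading of a scenario
directly: per support point, each arm's event-time mass (step 1), or the
mass carried by cause-1 events only (step 2). The default window
$[0.07, 5.4]$ trims the steep ends of the observed range where masses spike;
it is configurable. `power_curve()` re-runs a scenario over a grid of
per-arm sample sizes — the simulation-based alternative to closed-form
sample-size formulas, usable with any pilot or control dataset and any
baseline shape, with no constant-hazard assumption.

## The calibrated control fixture

The reference control cohort behind the package's study conditions is known
only through printed summaries: 636 subjects, 38.2% events of interest,
20.3% competing events, 41.5% censored, an all-cause Kaplan-Meier spending
roughly three quarters of its mass, and near-constant cause-specific
hazards. `calibrate_fixture()` chooses the simplest joint model consistent
with all of these: exponential event times with constant rates
$\lambda_1, \lambda_2$ and independent uniform censoring on a window,
default $(2, 6)$ years — a round-number stand-in for staggered accrual over
several years followed by an administrative study end. The all-cause rate
solves

$$P(T < C) = 1 - \frac{e^{-\lambda c_{\min}} - e^{-\lambda c_{\max}}}
{\lambda\,(c_{\max} - c_{\min})} = 0.585$$

by bisection to $10^{-10}$ (yielding $\lambda \approx 0.23$ per year, split
243:129 between the causes), and the implied unspent Kaplan-Meier mass
$e^{-6\lambda} \approx 0.25$ falls out of the calibration rather than being
targeted separately. These defaults *are* the package's study conditions;
they are modelling choices, stated once and not tuned.

What the fixture does not emulate: covariates, accrual dynamics, any
non-constant hazard shape, or the treatment arm (treatment arms only ever
arise from scenarios). Consequently, replicated-study results that depend
on the baseline shape — empirical power above all — are reproduced
approximately, not exactly; tests assert bands rather than point values for
those quantities, while estimator identities and the Cox oracle are exact.

## Problem sizes and numerical notes

The shipped study conditions are 1000 replicates of 500 subjects per arm on
a 636-subject control cohort; a full scenario runs in a few seconds, so the
tests and the acceptance script use the conditions unreduced. Large-sample
checks use $n = 10^5$ cohorts (Monte-Carlo error on a proportion
$\approx 0.15$ points) and estimator-consistency checks run at
$n \in \{500,\ 5000,\ 50000\}$. Degenerate inputs are handled as named
errors: empty datasets, datasets without events (no law exists), requests
for a cause with no events (a hazard identically zero is returned; a Cox
fit is an error), inadmissible increment configurations.

## Limitations

One transient and two absorbing states only; no left truncation or
time-dependent covariates; single binary covariate in the regression; no
Efron or exact tie handling; no subdistribution-hazard (Fine-Gray style)
modelling or CIF-based testing; no smoothing of the per-time binomial
probabilities. The empirical law treats the observed support as exhaustive:
simulated event times never fall between observed ones, which is the
intended discrete reading of the estimators, not an approximation error —
but it does mean the simulator should be fed datasets large enough that the
support is reasonably dense.
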