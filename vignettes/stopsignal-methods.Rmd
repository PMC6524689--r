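---
title: "Models and methods behind stopsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

This vignette documents the generative model, the SSRT estimator, the
inference layer, and the numerical and design choices made where the
published record leaves them open. Nothing here states an empirical result
that the test suite or the acceptance script does not itself compute.

## The task and the race model

Each simulated session mirrors the administered design: a 48-trial two-choice
block (left/right stimulus, speeded left/right response), then a 288-trial
stop-signal block in which 25% of trials (72) carry a stop signal after a
delay (SSD). The SSD starts at 100 ms and moves on a 50 ms lattice: one step
up after a successful inhibition, one step down after a failed one. This
negative-feedback staircase tracks the delay at which inhibition fails about
half the time; in long sessions the simulator's p(respond | signal) settles
within a percent or two of 0.5 (the test suite checks 0.50 ± 0.02 over 10^4
stop trials).

Trial outcomes follow the independent horse race. The go process finishes
with an ex-Gaussian latency — Gaussian(mu, sigma) plus an exponential tail of
mean tau, the standard parametric RT model — and the stop process with a
normal latency truncated at zero. A stop trial produces a response iff the go
finishing time is below SSD + stop latency. Two lapse parameters complete the
model: a choice-error probability (response on the wrong side) and an
omission probability (the go process never finishes).

Assumptions worth making explicit: the two runners are stochastically
independent with context-independent stop latencies; there are no trigger
failures (the stop process always starts); and proactive slowing acts on the
go process only. These are the classical estimator-level assumptions — data
generated with trigger failures or severe context dependence would bias any
integration-method analysis, and this simulator does not emulate them.

### Proactive slowing

Participants strategically slow their go responses once stop signals can
occur. The simulator implements this as a multiplicative factor on the
Gaussian location mu in the stop-signal block only (ratios, not additive
shifts, are what the behavioural slowing index reports). The slowing index is
defined as mean no-signal RT divided by mean two-choice RT; because the
exponential tail tau is left untouched, a target index `i` maps to the factor
`s = (i (mu + tau) − tau) / mu`, which is how `default_cohort_spec()` derives
its factors from the target indices 1.298 (hands) and 1.239 (feet).

### Cohort generation and its defaults

`default_cohort_spec()` encodes the study conditions the package emulates: 30
experts (elite handball players) and 30 active controls, each tested with
hands and feet. Group-level stop-latency means are 229.36 / 261.52 ms
(expert / control, hands) and 259.5 / 276.74 ms (feet); go parameters give
two-choice RT means near 408 ms (hands) and 424 ms (feet). Where the
published record is silent the defaults are fixed once at values conventional
for RT work: go ex-Gaussian sigma = 40 ms and tau = 78 ms; within-subject
stop-latency SD 30 ms; choice-error rate 0.02 and omission rate 0.005; SSD
bounded to [0, 900] ms (unbounded staircases can degenerate); stop trials
placed by exact-count uniform shuffling with no constraint on consecutive
stop trials. Between-subject heterogeneity is one shared draw per participant
(SD 30 ms on both the go location and the stop-latency mean), shared across
effectors — this is what induces the positive hands–feet SSRT correlation at
the individual level. Choice-block order counterbalancing is a metadata-level
fact with no consequence for an order-free simulator, so it is not modelled.

Seeding: a session is a pure function of (design, params, seed). Cohorts
derive one child seed per session from the master seed by a fixed integer
recurrence, so adding or reordering participants never perturbs other
sessions. All per-trial randomness is drawn up front through inverse-CDF
samplers (a fixed number of uniforms per trial); varying a single parameter
therefore leaves the random stream aligned, which is what makes the
monotonicity property — a slower stop runner never inhibits more often under
the same stream — testable at all. Note that with the staircase active this
monotonicity is a feedback-damped, empirical property rather than a theorem:
the SSD adapts against the change, and the suite checks it over a spread of
stop-latency means where the race effect dominates.

## The integration estimator

`estimate_ssrt_integration()` implements the integration method: rank the
stop-signal-block go RTs ascending, take the RT at rank
`ceiling(N × p(respond | signal))` (never below 1, capped at the number of
rankable RTs so p = 1 selects the maximum), subtract the mean SSD over all
stop trials. Choices the literature leaves open, and what this package does:

* **Rank rounding** — ceiling, consistent with the classical worked example
  `288 × 0.6 = 172.8 → 173`; nearest-integer rounding gives the same value
  there, ceiling is used and documented.
* **Basis count `N`** — two modes. `total_trials` (the default) uses the full
  block length (288), matching the classical formula in which n multiplies
  the total trial count even though only 216 trials are go trials.
  `go_trials` uses the go-trial count, making the rank a genuine p-quantile
  of the go distribution. The two differ systematically: with p tracked near
  0.5, `total_trials` reads the go distribution at quantile ~0.67 rather than
  ~0.5 and therefore overestimates SSRT by roughly 25 ms under the default
  generator, while `go_trials` recovers the generative stop latency to within
  a few ms (the suite requires |bias| < 10 ms over 500 replicate sessions).
  Fidelity to the printed convention and unbiasedness are different goals;
  use `total_trials` to reproduce published numbers and `go_trials` for
  parameter recovery.
* **Omissions** — assigned the maximum observed go RT before ranking, the
  standard conservative treatment.
* **Choice errors** — included in the ranking by default (documented switch
  `include_choice_errors`).
* **Ties** — stable ascending sort; the rank picks a value directly, so ties
  need no breaking.
* **p(respond | signal) denominator** — all stop trials. Tracking makes this
  the only reading that lands near 0.5.

Two exact invariances are tested: the estimate is order-invariant within a
session, and adding a constant c to every SSD lowers the estimate by exactly
c.

## The inference layer

**t tests and d.** Group contrasts use the pooled-variance Student t with
df = n1 + n2 − 2 and the pooled-SD Cohen's d, coded second group minus first
(control − expert, so positive means an expert advantage). Pooled rather than
Welch: the reproduced df of 58 at n = 30/30 and the d/CI arithmetic of the
reference results are those of the pooled test.

**Noncentral-t CI for d.** The exact pivot interval: find the noncentrality
parameters at which the observed t = d·sqrt(n1 n2 / N) sits at the
(1 ± conf)/2 tails of the noncentral-t distribution, then rescale. Roots are
bracketed generously and solved to 10^-9; the suite verifies the tail
probabilities at the returned bounds to 10^-6 and the 95% simulated coverage
at d = 0.5, n = 30/30 to ±1.2% over 10^4 replicates.

**Bayes factors.** `jzs_bayes_factor()` integrates the noncentral-t
likelihood over a Cauchy(location, scale) effect-size prior — truncated and
renormalised to a half-line for directed hypotheses — against the point-null
likelihood, by adaptive quadrature (`stats::integrate`, relative tolerance
10^-10; the quadrature's absolute error is propagated into the result). The
default prior is Cauchy(0, 0.707); the informed prior Cauchy(0.5, 0.5) places
its mass on a medium-sized directed effect. A Monte-Carlo prior-integration
oracle (10^6 prior draws) agrees within 1% across t in [0, 5] in the suite.
`bf_robustness()` sweeps the scale at location 0.

One reproduction caveat, stated plainly: recomputing from the published
rounded group summaries, the hands-condition Bayes factors match the
published values to ~0.15%, but the feet-condition values come out at 1.56
(default prior) and 1.76 (informed) against published 1.46 and 1.64 — about
7% high, outside the ±5% band that rounding alone would explain. Both
published feet values back-solve to an underlying t of about 1.62, whereas
the published feet summaries (and the published t itself) give 1.67; the
source numbers are internally inconsistent at that level, and this package
reports what the summaries imply rather than matching the printed Bayes
factors.

**Correlations.** Fisher-z intervals (SE 1/sqrt(n−3)) with a one-sided
variant returning (lower, 1]; independent correlations are compared by the
normal z test on the atanh difference.

**Mixed 2×2 ANOVA.** Classical split-plot sums of squares via `aov()` with an
`Error(participant)` stratum: group against subjects-within-groups, effector
and the interaction against the subject × effector residual. Partial eta
squared is SS_effect / (SS_effect + SS_error), which for df1 = 1 reduces to
F/(F + df2). The suite checks the algebraic oracle that the between-group F
equals the squared pooled t on per-subject means, and calibrates the per-effect
type-I error to 0.05 ± 0.01 over 10^4 null simulations.

**Sample size.** `sample_size_mixed_anova()` returns the smallest balanced N
whose between-factor test reaches the target power under the noncentral-F
approximation with lambda = f²·N·m / (1 + (m−1)ρ). The repeated-measures
correlation ρ is an explicit argument because published power analyses often
leave it implicit: at f = 0.33, alpha = 0.05, power = 0.80 and the
conventional planning default ρ = 0.5, the minimal N in a 2×2 within-between
design is 58 (N = 56 reaches only 0.7997) — exactly the reconstruction of
the reference study's plan. The upstream derivation of f = 0.33 itself (a 60%
CI bound on a historical d at unequal n) rests on further unstated
assumptions and is deliberately not asserted; the operation is parameterised
instead.

**Multiplicity.** No multiple-testing correction is applied anywhere: the
reproduced analyses are planned, one-tailed contrasts, and the package
mirrors that, documented here.

## Pipeline, problem sizes, and what passing tests show

`run_pipeline()` chains simulate → estimate → analyze from one config and
seed and writes trials, summaries and a JSON/markdown report; it is
byte-for-byte idempotent for a fixed config and seed. The test suite runs the
staircase property at 10^4 stop trials, estimator recovery at 500 replicate
sessions of the full 288-trial design, ANOVA calibration at 10^4 simulated
null datasets of 20 participants, Bayes-factor validation at 10^6 Monte-Carlo
draws per grid point, and the end-to-end effector-gradient check (hands d
exceeding feet d, as the generative means dictate) over 120 replicate
cohorts at the full 30 + 30 scale — sizes chosen to keep Monte-Carlo error
well inside each assertion band.

Passing these tests shows that the chain is internally correct for data that
obey the race model with the stated lapse structure. It does not show that
real stop-signal data meet those assumptions: trigger failures, RT drift
across a session, fatigue, and SSD-dependent strategy shifts are all real
phenomena the generator deliberately omits, and all of them move
integration-method estimates in documented ways. Conclusions about real
cohorts still require the usual checks (inhibition functions, RT
distributions, slowing diagnostics) on the empirical data themselves.
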