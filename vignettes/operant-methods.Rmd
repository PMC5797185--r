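---
title: "Methods: schedules, session rules, and the virtual-mouse model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: schedules, session rules, and the virtual-mouse model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(operantr)
```

## Scope

`operantr` models the computational core of a two-well nose-poke operant
experiment: the reinforcement schedules, the within-session state machine,
the event-log format, the task-progression criteria, a generative
virtual-mouse model, and the cohort statistics. It does not talk to
hardware; it operates on recorded or simulated poke streams.

## Reinforcement schedules

A fixed-ratio schedule FR*n* delivers one reinforcement per *n* counted
active-well responses. The progressive-ratio schedule computes the
requirement for the *N*-th reinforcement as

$$R_N = \left\lVert s\,e^{N r} - s \right\rVert, \qquad N = \text{rewards earned} + 1,$$

with scale $s = 5$ and rate $r = 0.2$ by default, $\lVert\cdot\rVert$
denoting rounding to the nearest integer. Nearest-integer rounding is the
only reading consistent with the canonical series 1, 2, 4, 6, 9, 12, …:
the fifth requirement is $5e^{1}-5 = 8.59$, which must give 9 (a floor
would give 8). We round half away from zero for determinism; half-integer
values cannot arise from the default constants at machine precision. The
requirement is clamped below at 1, which is latent with the defaults
(the formula's first value is 1.107) but protects nonstandard constants.

## Session state machine

`run_session()` consumes a time-ordered poke stream and applies, poke by
poke:

* counted active pokes advance progress toward the current requirement;
  reaching it delivers a reward at that poke's time and re-computes the
  requirement;
* every counted active poke opens a timeout window $(t, t+\tau]$
  ($\tau = 1$ s by default); pokes in either well strictly inside an open
  window are logged with `in_timeout = TRUE`, are not counted, and do not
  extend the window;
* inactive pokes never advance the schedule and never open a timeout;
* the session ends at the time limit (60 min default) or at the capping
  reward (50 for FR1 sessions; unlimited for FR5/PR), whichever is first.

Numerical choices:

* **Millisecond clock.** Input times are rounded half-up to integer
  milliseconds on entry and every window/limit comparison is done in
  integer milliseconds. This mirrors the clock resolution of chamber
  firmware and makes two invariants exact rather than
  floating-point-approximate: replaying a logged stream reproduces the
  log bit for bit, and the CSV write/read round-trip is the identity.
* **Ties.** Equal-time pokes are processed in input order and the later
  one is treated as infinitesimally later, so it falls inside a timeout
  window opened by the earlier one. The window is half-open: a poke at
  exactly $t+\tau$ is still in timeout.
* **Timeout pokes are logged, not dropped.** Whether a physical rig
  records pokes made during the timeout varies between firmwares; logging
  them with a flag preserves the information and lets the analysis
  decide. The per-session metrics count them in the active/inactive/total
  tallies (they are physical pokes) and also report them separately.
* **The reward cap applies only to FR1.** The 50-reinforcement cap is an
  acquisition-phase rule; FR5 and PR sessions run the full hour.

## Event-log format

One CSV row per event with the fixed header
`mouse_id,genotype,day,phase,t_ms,event,well,in_timeout,counted` and
events `session_start`, `poke`, `reward`, `session_end`. Plain text was
chosen over a binary container so behavioral records stay auditable;
integer milliseconds avoid float-format drift. The `session_end` row
carries the end reason (`TIME_LIMIT`/`REWARD_CAP`) in its `well` column —
the header has no dedicated column and we keep it bit-stable. The session
configuration is not serialised; `read_event_log()` accepts it as an
argument when needed. Reward indices are reconstructed from row order and
validated (monotone times, no reward before a counted active poke, no
poke both counted and in timeout).

## Progression criteria

* **FR1 acquisition:** active:inactive ratio ≥ 3:1 *and* ≥ 20
  reinforcements, on 3 consecutive days; the acquisition day is the third
  day of the first unbroken run. A mouse that poked only the active well
  has an infinite ratio and passes (it is maximally discriminating); a
  mouse with no pokes fails. No acquisition by day 17 means exclusion.
* **PR stabilization:** scanning 3-day windows in order, a window
  stabilizes when every day lies within `tol` of the window mean, with
  `tol = max(1, 0.1 × mean)` for means ≥ 10 and `tol = 1` below (an
  animal earning few rewards gets an absolute, not relative, allowance;
  the `max(…, 1)` keeps the relative rule from ever being stricter than
  the small-count rule). The earliest stabilizing window wins — animals
  advance as soon as they are stable.

Two genuinely open choices are resolved as follows and exposed in
`criteria_config()` for users whose rigs differ: the ±10% band is
anchored to the **window mean** (symmetric agreement, rather than
anchoring to the first day), and the reported stabilized breakpoint is
the **window mean** (real-valued), since the criterion itself aggregates
three days.

## The virtual-mouse model

No behavioral model is inherited from the experimental literature the
package is aimed at; the agent here is the simplest three-mechanism model
whose parameters can independently set learning speed, throughput and
breakpoint:

1. **Poking.** While engaged, pokes form a Poisson process at
   `poke_rate_hz` (default mean 0.0759 Hz ≈ 273 pokes/h, matching typical
   FR5 throughput).
2. **Learning.** Each poke hits the active well with probability
   $p(d) = \text{floor} + (\text{ceiling}-\text{floor})\,
   \mathrm{logistic}((d - \text{midpoint})/\text{slope})$, with the day
   counter $d$ accumulating across phases. Defaults: floor 0.5 (chance),
   ceiling 0.88, midpoint 4.25 d, slope 1 d.
3. **Motivation.** In PR sessions only, immediately after earning reward
   $k$ the agent stays engaged with probability $e^{-r_{k+1}/m}$, where
   $r_{k+1}$ is the upcoming requirement and $m$ is the `persistence`
   effort scale (pokes). The first failure permanently disengages the
   agent for that session (an absorbing state — this keeps the breakpoint
   interpretable as a final reinforcement count); it then pokes at a low
   residual rate (0.01 Hz) at chance accuracy.

Between-mouse variation is lognormal for positive parameters
(parameterised by the mean, so zero dispersion degenerates to the mean)
and logit-normal for probabilities. Genotype profiles share every
parameter except `persistence`: the mutant deficit is purely
motivational, which is what makes the simulated phenotype FR-normal and
PR-impaired.

### Calibration

The frozen defaults in `default_profiles()` were found by grid search
over the persistence means, the persistence dispersion and the learning
midpoint, holding the throughput parameters at their directly-identified
values (0.0759 Hz = 273/3600). Targets and achieved values (30 replicate
cohorts of 12 + 12):

| quantity | target | achieved |
|---|---|---|
| FR1 days to criteria (mean ± SD) | 7.5 ± 2.4 | ≈ 7.8 ± 2.3 |
| FR1 exclusion rate | ≈ 5% | ≈ 2–3% |
| FR5 total pokes/session | ≈ 273 | ≈ 273 |
| breakpoint reduction (mutant vs wild-type) | 37–46% | ≈ 36–38% |
| breakpoint Cohen's d | 1.6–1.8 | ≈ 1.8–2.0 |

The reduction and the effect size cannot be pushed jointly much higher:
with ~0.076 Hz poking and a 60-minute session the cumulative-requirement
curve caps the wild-type breakpoint near 12, so raising the wild-type
mean compresses wild-type variance against that ceiling and inflates
*d*. The frozen profiles (persistence 170 vs 34 pokes, log-SD 0.55) sit
at the compromise. The wild-type absolute breakpoint level (~9) is a free
choice of the calibration; only relative reductions and effect sizes were
targeted.

### Randomness

`simulate_cohort()` gives every mouse its own L'Ecuyer-CMRG substream
spawned from the master seed (`parallel::nextRNGStream`), so enlarging a
cohort never perturbs earlier mice; within a mouse, days consume the
substream sequentially. The caller's RNG state is restored on exit.
`simulate_session()` itself uses the current RNG state and is
reproducible under `set.seed()`. In PR sessions the engagement coins are
drawn as a fixed-size block before the stream is scored, so the draw
order does not depend on the realised reward count.

### The fast breakpoint sampler

`simulate_breakpoints()` draws daily PR breakpoints directly from the
generative law — the minimum of the coin-flip survival process and a
Poisson counted-poke budget, with the post-response timeout entering as a
dead-time thinning $\lambda_c = \lambda_a/(1+\lambda_a\tau)$ — without
building poke streams. It exists for large-scale power and type-I-error
studies (thousands of cohorts), where the event-level simulator would be
needlessly slow; the two routes are checked against each other in the
test suite. For a type-I-error study only the *equality* of the two group
distributions matters, which the fast path preserves exactly.

## Statistics

Welch's *t* (unequal variances, Welch–Satterthwaite df) is used for
inference; Cohen's *d* uses the pooled SD without small-sample correction
(a Hedges-corrected variant is available behind a flag); analytic power
uses the pooled noncentral-*t* formulation with
`ncp = d·sqrt(n1·n2/(n1+n2))` and `df = n1+n2−2`. Power deliberately uses
the pooled convention of standard power calculators even though inference
uses Welch — the two conventions are the ones actually paired in this
literature, and the asymmetry is intentional and documented.

## What the simulator does and does not show

Passing calibration tests shows the package's pipeline — schedules,
session rules, criteria, statistics — behaves correctly on data whose
generating process is fully known, and that the chosen parameters occupy
a realistic operating regime. It does not validate the agent as a model
of mouse cognition: real mice show within-session satiety and rate
decay, bout-structured (non-Poisson) poking, day-to-day correlations
beyond the learning curve, and re-engagement after pauses, none of which
are modelled (a satiety hook is reserved in the design but not
implemented). Conclusions about real animals must come from real event
logs, for which the analysis half of the package is generator-agnostic.

## Problem sizes

The test suite runs ~300 randomized short streams against a brute-force
oracle, 20 replicate full cohorts (12 + 12 mice) for the calibration
checks, 10,000 Monte-Carlo replicates for the power cross-check, 1,000
sessions for persistence recovery, and 1,000 fast-sampled cohorts for the
type-I-error check; the acceptance script uses 20 replicate cohorts and
120 simulated mice per fixed-ratio quantity. These sizes put Monte-Carlo
error well inside the tolerances asserted while keeping a full run in a
few minutes on one core.
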