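---
title: "Simulating automated conditioning experiments with condukt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating automated conditioning experiments with condukt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condukt)
```

## What condukt models

Automated conditioning rigs for small fish replace hand feeding with a
scheduled, sensor-gated apparatus: a circular tank with feeding ports on
opposite sides, LED and underwater-sound stimuli, infra-red beam-break
sensors, and a robotic feeder arm, all driven by a controller that executes
a multi-day plan of *trials*, *runs*, and *reps* (a rep is one
stimulus/reward opportunity; a run is a block of consecutive reps launched
at a scheduled clock time; the full multi-day set of runs is a trial).

`condukt` is a software-only counterpart of such a rig.  It has three layers:

1. **Schedule model** — a declarative, validated description of the
   experiment plan (`parse_schedule()`, `expand_trial()`,
   `randomize_runs()`), read from a YAML dialect in which every scheduler
   field is named and unknown fields are rejected.
2. **Conditioning engine + virtual tank** — a discrete-event executor
   (`run_rep()`, `run_trial()`) that drives agent-based virtual fish
   through each rep, enforces classical vs operant reward logic, and emits
   canonical event logs and 30 fps trajectories.
3. **Measurement and learning statistics** — per-rep behavioral metrics
   (`distance_series()`, `window_stats()`, `speed_and_darts()`,
   `turning_rate()`, `score_rep()`) and trial-level analyses
   (`learning_curve()`, `pre_post_test()`, `rm_learning_test()`,
   `fit_learning_model()`).

The virtual clock never sleeps: wall times are computed, so a four-day
trial simulates in seconds.  Every source of randomness derives from one
user seed through tagged sub-streams (`derive_seed()`), so a rep's outcome
never depends on cohort size, rep order, or anything outside its own
stream, and identical inputs reproduce logs and trajectories byte for byte.

## Rep timeline semantics

Recording onset is `t = 0` and is the reference for every delay.  Stimuli
switch on at their configured onset delays and off after their durations.
The two paradigms differ only in the reward rule:

* **Classical**: food drops unconditionally at `food_delay` seconds from
  recording onset.
* **Operant**: a response window opens at sound-playback onset and closes
  after `response_window` seconds.  The first rising edge of the correct
  sensor inside the window triggers a feed within the feed latency
  (default 0.5 s, apparatus contract at most 1 s); the window then closes
  at the feed, so a feed can never fall outside an open window.  Without a
  trigger the rep ends unrewarded.

Recording stops `record_end_delay` seconds after the feed (or after window
close when no feed occurred).  If a feed comes due while the arm is still
rotating, the engine waits for `arm_move_end` and flags the feed event with
`warning=arm_moving`.  Ties at equal timestamps are broken in a fixed,
documented order (rep start, sensor, stimulus, feeder/window, recorder,
rep end), so logs are canonical.

Two readings of the operant window length exist in practice — equal to the
stimulus duration, or a fixed interval after sound playback — so
`response_window` is an independent parameter; the bundled operant preset
uses 8 s with a 4 s sound, the classical preset's proximity analysis
corresponds to a 4 s sound.  Whether LEDs in the classical paradigm stay
on until the feed is equally underdetermined; presets give LEDs a fixed
duration (sound duration + 2 s).  Wrong-sensor triggers during the window
are logged but neither reward nor terminate the rep.

## The virtual fish

Each fish is a correlated random walk in the 30 cm arena, stepped at the
frame interval (1/30 s, so one simulation step is one video frame):

* heading receives a wrapped-Gaussian perturbation with per-second sd
  `1/sqrt(turn_concentration)` radians;
* speed is a truncated-normal draw around `base_speed`;
* while any stimulus plays, speed and turning are multiplied by
  `arousal_gain` (post-onset arousal: more turns, higher swim speed);
* wall collisions reflect the heading; an optional chord divider with a
  gap (off by default) blocks crossings outside the gap;
* while a *learned* stimulus plays, heading drifts toward the reward-port
  bearing at `bias_gain * w * sin(bearing - heading)` rad/s with weight
  `w = V / (1 + satiation)`.

Association strength `V` per stimulus follows the Rescorla–Wagner rule:
`V <- V + alpha * (lam - V)` after a rewarded presentation and
`V <- V * (1 - alpha / 4)` (mild extinction) after an unrewarded one —
sham sounds, marked `rewarded: false`, therefore never build an
association.  Feeds drop a Poisson number of grains (mean 3 for simple
feed, 5 for enhanced); each grain adds `satiation_decay` to satiation,
which halves every `satiation_half_life` hours, producing the familiar
within-day dips and overnight recovery of appetite-driven performance.

The sine-drift form of the port attraction matters: the stationary heading
concentration scales with `w`, so a weak association gives weak,
noise-dominated homing, while `w = 1` converges on the port bearing with a
time constant of about `1/bias_gain` seconds.  (A per-tick interpolation
toward the target would compound across ticks and make even a tiny
association home almost deterministically.)

### Default parameters and what they reproduce

| parameter | default | unit | rationale |
|---|---|---|---|
| `base_speed` | 4 | cm/s | adult zebrafish cruising speed |
| `speed_sd` | 1.5 | cm/s | per-tick speed variability |
| `turn_concentration` | 2 | – | meandering baseline exploration |
| `arousal_gain` | 1.5 | × | post-onset arousal on speed and turning |
| `bias_gain` | 4 | rad/s | trained fish orient to the port within ~2 s |
| `alpha` | 0.1 | per rep | success rises over ~10–12 h of half-hourly reps |
| `V0` | 0.02 | – | near-naive initial association |
| `satiation_decay` | 0.05 | per grain | measurable within-day satiation |
| `satiation_half_life` | 3 | h | appetite recovery between run blocks |

With these values a naive fish triggers the sensor within the 8 s window
about 20 % of the time by chance, a trained one about 90–95 %, and the
transition takes roughly 20 reps — the dynamics the package's acceptance
checks exercise.  Cohorts get multiplicative log-normal jitter (sd 0.1) on
the kinematic parameters, emulating between-fish variability; each agent
draws from its own RNG stream split from the rep seed, so cohort size never
changes an individual's path.

What the generator deliberately does **not** emulate: social interactions
(chasing and dominance in group housing — the reason operant training is
usually run one fish at a time), 3-D swimming and posture, hydrodynamics,
and any auditory-periphery detail.  Passing tests on this generator
therefore show that the *pipeline* (scheduling, gating, logging, metrics,
statistics) behaves correctly and that the analyses recover known
generative structure — not that real fish will learn at these rates.

## Measurement conventions

* Distances are Euclidean to a target point (feeder port) or unsigned
  perpendicular distance to a chord plane (divider analyses).
* Analysis windows default to PRE = 1 s before sound onset and POST2 /
  POST3 = the second and third seconds after onset; frames are assigned by
  half-open intervals `[start, end)` so none is counted twice.  Windows
  much later than ~3 s post-onset mostly add behavioral noise (fish that
  reached the target start wandering back), which is why the defaults stop
  at POST3.
* Three zones at increasing distance from the active port are split at 10
  and 20 cm by default.
* A *dart* is a maximal run of frames above the speed threshold (default
  12 cm/s = 3 × cruising speed); a *turn* is a frame with more than 30°
  heading change.  Neither threshold has a canonical value; both are
  parameters.
* Operant success is scored 1 iff a correct-sensor rising edge occurred
  inside the response window; a fish already sitting in the beam when the
  window opens must leave and re-enter.

## Statistical procedures and numerical choices

The ANOVAs are computed from sums of squares directly and take p-values
from the F distribution, so the package's core contract does not depend on
a statistics package; the test suite cross-checks both against
`stats::aov`.  Degenerate inputs follow stated conventions: zero residual
variance with equal means gives `F = 0, p = 1`; with unequal means,
`p = 0`.

`learning_curve()` is a Nadaraya–Watson estimator: Gaussian-kernel
weighted means of the 0/1 scores on an even time grid, with a band equal
to the kernel-weighted standard deviation around the curve.  The kernel
and bandwidth are user choices (bandwidth default 4 h); the curve is
shift-invariant in time.

`rm_learning_test()` is the balanced two-way within-subject decomposition
of per-subject, per-block success rates (subject and block/time effects,
each against the subject-by-block residual).  Blocks default to
consecutive reps grouped in threes; block construction is a parameter.
No multiple-testing correction is applied anywhere, matching standard
practice for these single-outcome designs.

One calibration subtlety is worth knowing when analyzing single reps: PRE
and POST window means of the *same* fish in the *same* rep are positively
correlated (r ≈ 0.65 in simulation — positions decorrelate over seconds),
which makes the one-way ANOVA across windows conservative in that design.
The package's calibration simulations therefore draw each window from an
independent rep of fully null agents (`alpha = 0`, `V0 = 0`,
`arousal_gain = 1`), where the test's independence conditions hold and the
empirical size matches the nominal 5 % level.

`fit_learning_model()` estimates `(alpha, V0, guess)` by maximum
likelihood under the observation model
`p = guess + (1 - guess) * V`, with `V` updated by the rewarded-update
rule along the observed outcome sequence.  The optimizer is a bounded
quasi-Newton search from a fixed grid of start points (`alpha` ∈
{0.02, 0.1, 0.3} × `V0` ∈ {0.05, 0.3} × `guess` ∈ {0.1, 0.3}); the
confidence interval for `alpha` is a profile-likelihood interval over a
grid of 0.02 steps, which stays valid at the `alpha = 0` boundary where a
Wald interval would not.  All-0 or all-1 series are flagged as boundary
fits.  An ordinary linear regression of actual vs predicted responses can
be formed from the fitted probabilities, but it is exercised only on
synthetic data.

## Problem sizes used by the test and acceptance suites

The suites run the generator at sizes chosen to give stable Monte-Carlo
estimates while staying comfortably interactive: 1,000 randomized reps for
the reward-gating invariant, 500 simulations per calibration (nominal-size
bands of 3–7 % at α = 0.05), 50 seeds × 200 reps for `alpha` recovery and
100 seeds for boundary coverage, and 100 seeds for the qualitative
trained-vs-null contrasts.  The acceptance script (`scripts/acceptance.R`)
recomputes the same quantities from scratch at 300-simulation calibration
size.

## Known limitations

* The success probability of the agent model is an emergent property of
  the kinematics, not an analytic function of `V`; `fit_learning_model()`
  is therefore calibrated against its own observation model, and fitting
  it to agent-generated series recovers learning *structure* rather than
  the agent's literal `alpha`.
* The scheduler deliberately has no time zones or DST; clock times are a
  timezone-free local clock rendered internally as UTC.
* Only idTracker-style plain-text exports are ingested (`read_idtracker()`
  with an explicit pixel-to-cm scale); Ctrax `.mat`, wrMTrck, and
  DeepLabCut outputs are unsupported.
* Group social dynamics are not modeled; multi-fish cohorts are
  independent agents sharing one tank.
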