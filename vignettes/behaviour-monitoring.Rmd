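---
title: "Behaviour monitoring from PIR motion-sensor streams: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behaviour monitoring from PIR motion-sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmsense)
```

`bmsense` monitors the in-home mobility of a single resident through
room-level PIR motion sensors. This vignette is the package's account of
the underlying model, its assumptions, the tunable parameters, the
synthetic-data generator, and the design decisions taken where the design
was genuinely open.

## The data and its central assumption

A PIR sensor emits a trigger when it senses movement and then sleeps
briefly to save battery. The stream is therefore a sparse sequence of
`<timestamp, sensor>` events, one sensor per room (plus one virtual
*Outside* room for time away from home). Everything rests on one
assumption: **the resident stays in the room of the most recent
observation until a different room reports one**. The interval between
two consecutive observations, attributed to the earlier room, is a
*stay*. This is a single-resident model: visitors or pets violate the
assumption and are out of scope.

## The behaviour model

Time is cut into a weekly grid of 7 weekdays × `1440/delta_t` intervals
(`delta_t = 60` min by default). Intervals are half-open `(t, t + Δt]` —
an event exactly on a boundary belongs to the earlier-labelled cell — and
stays are split exactly across the cells they overlap, including across
midnight, so no dwell time is lost or double-counted (the test suite
checks this against a per-second oracle).

Each cell accumulates, over a sliding learning window (default 4 weeks,
shifted 1 week):

* **Total stay time** per room, divided by the number of window days
  mapping to the cell (4 Mondays in a 4-week window). Without this
  normalisation the dwell share of an interval would exceed 1; with it,
  the self-transition probability `P[i,i]` is the probability of finding
  the resident in room `i` during that weekday/interval.
* **Transition counts** `M[i,j]` from consecutive observation pairs,
  credited to the cell containing the later observation. `M` is not
  symmetric, and same-room consecutive observations count as
  self-transitions.
* **Activity rates** per minute: global (all observations), inter-room
  (transitions excluding self-transitions) and per-room. By construction
  the per-room rates sum to the global rate and the inter-room rate never
  exceeds it.
* **Continuous stays**: consecutive same-room stays merged into runs; a
  run is broken by *any* interleaved stay in another room, even one of
  zero duration, and is credited to the calendar day it started. Each
  weekday keeps the list and the maximum per room.

The self-transition probability is computed as the room's share of the
*observed* dwell time in the cell rather than of `Δt` itself; the two
coincide whenever the cell is fully covered by the stream (the normal
case), and the former keeps the probabilities summing to one when
coverage is partial (stream edges). Off-diagonal probabilities allocate
the remaining mass `1 − P[i,i]` proportionally to transition counts. Two
degenerate cases are handled explicitly: a room with dwell but no
outgoing transitions in a cell keeps all its mass on the diagonal (row
sum 1), and a room never observed in a cell has an all-zero row, flagged
unobserved, with likelihood lookups returning 0.

Room adjacency is descriptive, not enforced: the learner counts whatever
the sensors report (real sensors misfire), and a strict mode in
`stays_from_observations` can warn about physically impossible
transitions.

### Window updates

`update()` shifts the window, drops observations that fell out of it,
and rebuilds the model from the retained buffer. Rebuilding from
observations rather than patching counts incrementally makes the update
*exactly* equal to a from-scratch fit on the shifted window — an
invariant the tests assert bit-for-bit — at negligible cost (a 4-week
buffer holds a few tens of thousands of events). A consequence worth
knowing: an abrupt change of routine is absorbed linearly over
`window/shift` = 4 weekly steps, which the test suite verifies as a
four-step staircase in the bedroom stay probability after switching
between the two synthetic profiles.

## Detection

Detection runs asynchronously from learning and emits exactly one record
per sampling period (default 1 min), regardless of when observations
arrive:

1. **Location likelihood** `l`: the model's stay probability for the
   detected room (most recent observation) in the current cell.
2. **Normalisation** by the cell's most probable room, because in many
   cells even the correct room has probability well below 1; an all-zero
   cell yields 0 and is flagged unmodelled.
3. **Smoothing**: an unweighted moving average over the last
   `smoothing/sampling` samples (default 10). No filter type is imposed
   by the problem; the moving average is the simplest FIR filter with
   the intended glitch-suppression behaviour. During warm-up (the first
   window, when the filter state is undefined) no abnormality is
   emitted.
4. **Thresholding**: abnormal iff the smoothed likelihood drops
   *strictly below* the threshold (default 0.25).
5. **Confirmation automaton** with states Normal → PotentialAbnormal →
   Abnormal and one timer. In Normal, abnormal samples increment the
   timer, a single normal sample resets it, and exceeding `N1 = 5` min
   enters PotentialAbnormal — so glitches shorter than `N1` never leave
   Normal. In PotentialAbnormal the timer is *not* reset by a normal
   sample, only decremented (±dt per sample); reaching `N2 = 10` min
   confirms Abnormal, draining to 0 returns to Normal. The exit from
   Abnormal is not constrained by the problem definition; the package
   returns to Normal after a sustained normal streak of `N1` minutes,
   with a `latch_abnormal` option to hold the alarm until acknowledged —
   the auto-release is what makes false alerts countable as episodes
   over long runs, one alert per entry into Abnormal.

## Rule-based classification

Confirmed deviations are mapped to four classes using the remaining
model dimensions. Per sample the classifier sees: the automaton state
`Z`; the current continuous stay against the room's longest learned stay
(`S` = High when the current stay has *reached* the learned longest —
equality already counts, since "shorter than expected" fails); the
model's expected room (cell argmax, ties broken by layout order); the
weighted global activity `W_AG = m/Δt · AG(cur) + (Δt−m)/Δt · AG(prev)`;
and the sampled global activity `S_AG` (trailing-`Δt` observation count
per minute — defined that way here so it is directly comparable to the
model's `AG`). `W_AG` and `S_AG` are each quantised into five equal
bands of the model's maximum global activity, and their agreement `W` is
Normal iff the bands differ by at most one — which reproduces exactly
the tridiagonal 5×5 agreement matrix the classifier is specified by.

The rules fire in order; no anomaly is ever emitted while `Z` is Normal:

1. detected room = bedroom ∧ `S` High → **OverSleeping**;
2. expected room = bedroom ∧ detected ≠ bedroom → **LessSleeping**;
3. detected = Outside ∧ `S` High → **NotBackHome**;
4. detected ∉ {bedroom, Outside} ∧ `S` High ∧ `W` Abnormal ∧ `S_AG`
   VeryLow ∧ `Z` fully Abnormal → **Dead**;
5. otherwise Normal (an unclassified deviation).

A few choices deserve justification:

* *Sleeping time is model-derived*, not wall-clock: rule 2 keys on the
  expected room being the bedroom, so the classifier is agnostic of
  whether the resident sleeps at night (profile A) or by day (profile B).
* *Rule 2 places no condition on which room the person is in instead* —
  including Outside. A known consequence, observed in the experiments:
  a silent long stay in the store during expected sleeping hours is
  labelled LessSleeping, not Dead, which caps the Dead accuracy for the
  nightly profile. This trade-off is inherent to ordering bedroom
  evidence first.
* *The expected longest stay is the room's longest continuous stay over
  the whole week*, not the current weekday's. With a 4-week window each
  weekday contributes only 4 samples, and the per-weekday maximum is
  noisy enough that ordinary slightly-long sleeps fire OverSleeping
  alerts; the weekly maximum is the stabler reading of "the expected
  longest stay value from the model". Per-weekday profiles remain
  available (`longest_stay`, and the `weekday` argument of
  `stay_state`).
* *Dead requires the fully confirmed Abnormal state*, given the severity
  of the alarm; the other classes may fire already in PotentialAbnormal,
  which is what gives the classifier its shorter detection delay than
  the automaton.

## The synthetic generator

`simulate_profile()` emulates two deliberately contrasting 12-week
single-resident routines over a six-room home (Bedroom, Bathroom,
Livingroom, Kitchen, Store, Outside; bathroom and store are dead ends,
Outside is reached through the living room):

* **A — morning person**: bedroom 0–8 h, outside 8–16 h, living room
  16–24 h;
* **B — nightly person**: outside 23–8 h, bedroom 8–16 h, living room
  16–23 h.

The schedule fixes only segments; everything else is behavioural
texture, chosen once as realistic for an older single resident and
exposed in `profile_spec()`:

| parameter | default | meaning |
|---|---|---|
| `active_gap` | 5 min | mean exponential observation gap while active |
| `asleep_gap` | 30 min | mean gap while asleep (sparse stirrings) |
| `jitter_sd` | 10 min | SD of day-to-day segment-boundary jitter |
| `night_bathroom_rate` | 0.5/night | Poisson rate of bathroom visits while asleep |
| `kitchen_rate`, `store_rate` | 2, 0.2/evening | excursions from the living room |

Excursions and segment changes follow shortest adjacency paths, one
observation per traversed room; outside periods emit a single exit
observation and then silence until return. Streams are byte-identical
for identical (spec, seed).

The boundary jitter matters doubly. It is what produces non-zero false
alarms on anomaly-free data (a resident 15 minutes late out of bed looks,
to the estimator, exactly like a deviation until the model catches up) —
without it the pipeline would report an implausible zero false-positive
rate. Its flip side is that grid cells abutting a scheduled transition
average a blurred occupancy: the bedroom probability in the 7–8 h cell is
~0.93 rather than ~1. The learned-shape checks therefore assert full
strictness on segment-interior cells and dominance (argmax) on boundary
cells.

Anomaly injection *replaces* baseline events in the anomaly window, so
ground truth is unambiguous for scoring: OverSleeping extends sleep-rate
bedroom events through the window (removing the jittered wake transition
back to the last sleep observation); LessSleeping puts activity in the
override room during expected sleep; NotBackHome removes everything
after the last exit observation, so the scheduled return never happens;
Dead emits a brief arrival in the override room and then total silence.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: visitors and multi-occupancy (the dominant
confound in real deployments), sensor faults and missed triggers,
seasonal drift, and the irregular room semantics of real homes (the
public CASAS "Aruba" layout has 31 sensors over 10 rooms, and inferring
"Outside" from PIR silence needs a heuristic). The CASAS reader and the
inactivity-gap questions are left to the user's configuration.

## Evaluation metrics and problem sizes

* **Detection delay**: minutes from anomaly onset to the first flagging
  sample at a level (estimator `h`, automaton = entry into Abnormal,
  classifier = first correctly-labelled sample). Misses are reported as
  `NA` and excluded from averages.
* **Confirmation time**: total flagged time within the anomaly window —
  an 8-h anomaly sustained for 7.9 h means the alarm held essentially
  throughout.
* **Weekly false positives**: alert episodes per anomaly-free week
  (maximal abnormal runs, or entries into Abnormal).
* **Classification accuracy**: percentage of in-window samples carrying
  the injected label, averaged over three seeds.

The packaged experiments (`run_experiment`, `fp_experiment`,
`scripts/acceptance.R`) simulate 12 weeks per profile, train on the 4
weeks preceding the anomaly week, monitor the anomaly day at 1-min
sampling, and average over three seeds; false-positive runs monitor the
8 post-training weeks with weekly window updates. These sizes keep a
full acceptance run in seconds while leaving every rate estimated from
thousands of samples.

## Numerical choices and degenerate inputs

* Timestamps are stored to the second (UTC); durations are fractional
  minutes. Conservation of stay time under splitting is exact to ~1e-6
  min over 72-h stays.
* Boundary convention everywhere: an instant exactly on a grid boundary
  belongs to the earlier cell, implemented with a 1e-7-min epsilon.
* Duplicate timestamps from distinct sensors are kept in file order; the
  zero-length stay still records its transition.
* Unknown sensors are dropped with a surfaced count; unsorted input is a
  hard error, not silently reordered.
* A deserialised model (JSON) carries tallies, not the observation
  buffer: it can detect but not `update()`, and says so.

## Known limitations

Single resident only; room-level localisation only (no within-room
activity recognition); the four anomaly classes are a closed set, and
rule order resolves their overlaps by fiat (bedroom evidence first);
Dead vs. LessSleeping is structurally confusable for day-sleepers; and
all headline numbers are synthetic-data numbers — real deployments add
the confounds listed above, visitors first among them.
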