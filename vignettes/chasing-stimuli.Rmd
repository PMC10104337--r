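---
title: "Simulating and analysing wolf-chasing-sheep displays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing wolf-chasing-sheep displays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chasesim)
```

## The display model

chasesim generates the moving-disc displays used in studies of animacy
perception: a *wolf* disc pursues a *sheep* disc among distractor discs
inside a bounded 32 x 24 degree frame, and observers try to identify the
wolf (or the sheep) from motion alone. Every quantity in the package is in
degrees of visual angle and seconds; the canonical frame rate is 60 Hz
(`dt = 1/60`), which makes the 167 ms distractor re-direction interval an
even 10 frames.

All agents move on an eight-direction grid (the four cardinal and four
ordinal headings), a legacy of keyboard control: a policy computes a
continuous bearing and `quantize_direction()` snaps it to the nearest
compass heading. Exact ties (bearings half-way between two headings) are
broken toward the smaller counterclockwise-from-east index, and the
implementation snaps bearings within 1e-9 of a tie onto that rule so the
outcome never depends on floating-point noise. Each frame a disc moves
`speed * dt` along its heading; displacement that would leave the frame is
clamped, which zeroes the exiting component and keeps the tangential one,
so discs slide along walls rather than sticking to them. Diagonal steps
use the unit heading, i.e. a single scalar speed, not per-axis keyboard
steps that would make diagonals sqrt(2) faster.

The sheep *circles*: it traverses the rectangle inset from the walls by
its own radius (0.435 deg, so the disc edge grazes the frame) at
14.4 deg/s, clockwise or counterclockwise at random per trial. Internally
the engine tracks the sheep by arc length along this loop, so corner turns
conserve path length exactly. The wolf and distractors move at 9.6 deg/s
(2/3 of the sheep's speed). A trial ends when the wolf-sheep centre
distance falls to or below the sum of the disc radii
(0.65 + 0.435 = 1.085 deg, boundary inclusive) or after 30 s.

## Pursuit policies

* **Direct chasing** (`direct_chase`): head at the sheep's current
  position, re-quantized every frame.
* **Sheep mimicking** (`mimic`): copy the sheep's last realized compass
  heading while the sheep is 6 deg or more away; switch to direct chasing
  strictly below 6 deg. Wall clamping makes a mimicking wolf travel around
  edges and corners when the copied heading runs into the frame.
* **Sheep interception** (`intercept`): extrapolate the sheep's path
  (`predict_sheep_path`) over a 180-frame (3 s) horizon from its position
  and last heading, expecting it to turn at corners in the trial's
  circling orientation; target the earliest predicted point the wolf could
  reach in time (`distance <= wolf_speed * t * dt`), or the end of the
  horizon if none is reachable; below 6 deg, direct chase.

Distractors are matched to the wolf in size, colour and speed. Two regimes
exist: independent random walks re-drawn every 167 ms (the single-wolf
preset `exp1_cpu`), and *invisible-target chasers* (the algorithm presets):
each distractor direct-chases an unrendered target that circles a loop of
its own, so distractor kinematics resemble the wolf's. One distractor per
algorithm-preset trial is the **correlation-control wolf**: it applies the
trial's pursuit algorithm to the point-mirror image of the sheep
(`mirror_point`), giving it the same magnitude of motion correlation with
the sheep as the true wolf while it never approaches her.

## Choices the display description leaves open

Several details are not pinned down by the usual description of such
displays; the package fixes them once, as follows.

* **Perimeter margin.** The circling loop is inset by the sheep's radius.
  Any inset in the sub-degree range keeps the disc visible; the catch-rate
  estimates move by only a few points across insets of 0-4 deg.
* **Invisible-target loops.** The description only says the targets circle
  "like the sheep" but can start anywhere. A loop congruent to the sheep's
  cannot pass through most interior points, so each target circles the
  sheep's loop *scaled about the arena centre* until it passes through the
  spawn point (clipped to the frame). A spawn near the centre yields a tiny
  loop; its chaser catches it quickly and the target respawns uniformly,
  which is the documented respawn rule anyway.
* **Interception solver.** "Best intercept" is implemented as the exact
  earliest-reachable-point scan above. It is a strong solver: because the
  circling sheep is perfectly predictable, the interception wolf can lurk
  on the future path and converge on almost every trial. Weaker solvers
  (shorter horizons, straight-line extrapolation without corner turns)
  fail more often; this is the single engine detail the catch-rate
  comparison is most sensitive to, and the faithful solver is kept even
  though it compresses the gap between the mimicking and intercepting
  conditions (see Limitations).
* **Catch rule.** Centre distance at or below the sum of radii. The
  boundary is inclusive so that a grazing contact counts.
* **Update order.** All policies read the frame-t state, then all discs
  move to frame t+1 (synchronous update); results cannot depend on disc
  order. The control wolf is never catch-checked against the real sheep
  and cannot end a trial.
* **exp1_cpu sheep.** The single-wolf preset drives the sheep with the
  same circling policy (human play in that paradigm is emulated instead by
  `playback_policy()`, which replays recorded trajectories against live
  policies).

## Trial curation and labelling

`curate_exp1` keeps only simulations longer than 6 s and cuts them to a
uniform-random length in [5, min(15, duration - 1)] s, re-drawing the
endpoint (up to 50 times) whenever the wolf would be the non-sheep disc
nearest the sheep on the final frame. `curate_exp2` keeps trials with no
catch in the first 11 s and cuts them to exactly 10 s, so end-of-movie
proximity cannot reveal the wolf. `assign_labels` gives the candidate
discs (everything except the reference disc) a uniform-random permutation
of 1..m: labels 1-20 with 19 distractors, 1-11 with 10, which makes
uniform guessing succeed at the printed chance levels of 5% and 9%
(`chance_level`). `build_trial_set` crosses algorithm and distractor count,
fills each cell, orders trials into per-cell-balanced blocks, and records
every seed in a manifest from which `regenerate_trial` reproduces any
trial bit for bit.

## The synthetic observer

Human responses are emulated by `simulate_observer`: *oracle* and
*uniform_random* bracket performance, and three cue-based strategies score
every candidate against the reference disc — mean proximity, magnitude of
displacement correlation (`displacement_correlation`, Pearson correlation
of frame-to-frame displacements per axis, averaged; positions would
inherit spurious correlation from the shared bounds), and mean closing
rate. When the reference is invisible (the hidden-sheep preset `exp4`) the
cue is undefined and every cue strategy degrades to a uniform guess, which
is what the response-level analyses (`identification_rate`,
`test_vs_chance`, `control_choice_analysis`) should then report as chance
performance. The choice analysis conditions on error trials and tests the
control wolf's share of them against the uniform null `1/(m - 1)` with an
exact binomial test, pooled over candidate counts by default or stratified
via `stratify = "by_condition"`.

What the synthetic observers do *not* emulate: attention, memory, learning
across trials, or any perceptual noise beyond an optional lapse rate.
Passing tests therefore show that the pipeline recovers each strategy's
programmed accuracy, not that humans behave like any of the strategies.

## Problem sizes and numerical notes

The test suite and the acceptance script use 2000 trials per algorithm for
catch rates (Wilson 95% intervals via `prop.test(correct = FALSE)` are
about +-2 points wide at that size), 200 curated direct-chase trials for
the observer analyses, and 10,000 responses for the at-chance binomial
check. Trial regeneration, mirror equivalence and playback round-trips are
exact to floating-point (tested at 1e-9 deg). Zero-variance inputs are
handled explicitly: `displacement_correlation` returns 0 for a motionless
axis, and `test_vs_chance` flags a degenerate result instead of dividing
by zero.

## Limitations

The engine is a faithful but idealized re-implementation, and its
Monte-Carlo catch rates differ from those reported for comparable
displays: direct chasing here catches the circling sheep in roughly a
sixth of trials (all in the opening seconds, before the pursuit settles
into a stable trailing orbit about 7 deg behind the sheep), while
mimicking and interception both approach certainty. The comparison's
*qualitative* core — mimicking and interception catch far more often than
direct chasing, the mirror-chasing control keeps a large distance from the
sheep while matching the wolf's motion correlation, and correlation-only
observers are drawn to the control while proximity observers never are —
is robust and is what the test suite asserts. The quantitative rates are
sensitive to engine details that display descriptions rarely state (the
interception solver above all, and to a lesser degree frame rate, margin
and catch radius), so cross-implementation comparisons of the exact
percentages should be made with caution. A further consequence of the
fast-catching engine is that mimicking trials almost never survive the
11-s catch-free curation window, so curated stimulus sets are practical
only for the slower-catching conditions.
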