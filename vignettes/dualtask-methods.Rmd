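---
title: "Methods: a headless engine for cognitive-motor dual-task assessment and training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a headless engine for cognitive-motor dual-task assessment and training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualtask)
```

## Background

Cognitive-motor interference (CMI) is the performance decrement that appears
when a cognitive task and a motor task -- typically walking -- are performed
simultaneously rather than separately. In people with multiple sclerosis,
CMI is clinically relevant: attention, working memory and processing speed
are among the most affected cognitive domains, and their interaction with
gait predicts real-world mobility and fall risk. `dualtask` implements the
computational core of a tablet-supported assessment and training protocol
for this population as a headless, scriptable R package: everything a
therapist-facing app would compute -- item generation, scoring, dual-task
cost analytics, difficulty progression, feedback, outcome scoring -- without
any audio, graphics, or device integration.

## The assessment battery

Three cognitive tasks are crossed with four walking tasks (plain walking,
walking with a water-filled cup, walking over obstacles, walking crisscross
between cones) into **19 conditions**: 3 single cognitive, 4 single/dual
motor, and 12 combined cognitive-motor conditions. Each condition lasts a
fixed 60 seconds.

* **Titrated backwards digit span.** Strings of distinct digits are drawn
  by ordered sampling without replacement from 1--9 (at length 3 there are
  $9 \times 8 \times 7 = 504$ possible strings); the patient repeats them
  reversed. The individual span is found by a staircase: four trials per
  length starting at three digits, pass at $\ge 3/4$ correct, stop at the
  first failed length. Failure at length 3 is reported as a below-floor
  flag rather than an invented sub-floor span. We cap the staircase at
  length 9, where sampling without replacement exhausts the digit pool.
* **Auditory vigilance.** A 24-letter stream containing exactly 10
  occurrences of two target letters; the 14 non-targets are drawn with
  replacement from the remaining alphabet and interleaved by uniform
  shuffle (no adjacency constraints -- none are defined for the task). At
  one letter per 2.5 s the sequence fills the 60-s trial exactly. Target
  letters are locale-specific and therefore always supplied by the caller;
  the engine does no linguistic filtering.
* **Serial subtraction by 7** from a uniform random start in 101--199,
  scored with the carry-forward rule: a response is correct iff it equals
  the previous *accepted* value minus 7, and every response -- right or
  wrong -- becomes the new reference. A single slip therefore costs exactly
  one error (101, 95, 88, 81 scores one error, two correct). The rule has
  no floor: responses below zero are scored identically, although they are
  unreachable within 60 s from a start $\le 199$.

**Per-patient reproducible ordering.** The protocol requires the condition
order to be randomized once and then held fixed for a patient across
retests. The engine derives the shuffle seed from a deterministic 31-bit
polynomial hash of the patient code, randomizing both block order and
within-block order, and additionally stores the realized order in the
session log so that a future change of hashing scheme can never silently
reorder a retest. Plain seeded shuffling is used; no counterbalancing
scheme across patients is implied by the protocol, so none is imposed.

Pacing (one digit per second, one letter per 2.5 s) is metadata: the
headless engine does not enforce real-time delivery. One open point is how
many digit strings fit a 60-s trial; the engine administers a fixed count
(default 5) per condition rather than truncating a string mid-delivery.

## Dual-task cost

For every (cognitive, motor) pair with both single baselines and the dual
trial available, the dual-task cost is

$$\mathrm{DTC\,\%} = \frac{\text{single} - \text{dual}}{\text{single}} \times 100$$

on higher-is-better measures: steps per minute for the motor DTC, correct
answers per minute for the cognitive DTC. Positive values are a cost,
negative values a dual-task benefit; the sign is preserved. Rates rather
than raw counts keep unequal durations comparable (with fixed 60-s trials
they coincide). Errors and false positives are reported alongside but do
not enter the DTC, which is defined on the performance decrement only. A
complete assessment yields 12 pairs; pairs with missing baselines are
omitted and listed, not treated as errors.

## Training: catalog, scoring, progression

Eleven exercises train twelve cognitive functions (Words, Reverse, and
Think each carry two). The seven auditory exercises run while walking, the
four visual ones while stepping on the spot. Difficulty has three levels;
the printed ladders are encoded in `level_parameters()`: Tabooword
20 s/0, 30 s/1, 40 s/3 taboo words; Differences 15/20/30 s; Roadmap adds
roundabouts/houses/trees at level 2 and one-way streets at level 3, with
the orientation aid (head icon) removed above level 1. For exercises whose
levels are not printed, difficulty is carried by the item bank's per-level
stimuli; Noise maps its printed "two to four" target noises to 2/3/4
targets at levels 1--3.

Scoring engines: Tabooword deducts one third of the score per taboo-button
press and scores the assignment wrong at three presses or on timeout;
Differences compares the stated equality judgement against ground truth
within the time limit; Roadmap tracks the patient's heading and interprets
stated directions relative to it (backward reverses the heading), rejects
off-grid or one-way-violating moves as route mistakes without moving, and
passes only on correct location with a mistake-free route; the remaining
exercises score exact matches against the item bank's key, with Story's
three questions scored individually (and counted individually in the
composite denominator). Skips are excluded from correct/incorrect but stay
in the composite denominator.

**Feedback.** After every exercise the therapist enters the step count
(mandatory), and the engine computes the six bars: composite
$= \text{correct}/(\text{correct}+\text{incorrect}+\text{skipped}) \times 100$
(the simplest formula consistent with the three displayed outcome bars),
the three outcome percentages, and the steps/baseline pair in which the
smaller cadence is shown as a percentage of the larger, pinned at 100%.
Zero-assignment trials have no composite and never move the level.

**Progression.** A performance is GOOD iff cadence $\ge 70\%$ of baseline
*and* accuracy $\ge 70\%$ *and* the therapist's safety and quality
judgements hold; BAD iff cadence $< 50\%$ *or* accuracy $< 50\%$ *or* a
judgement fails. The band between (either measure in $[50, 70)$ with
neither below 50) is neutral and changes nothing -- the protocol defines
only the two thresholds. The 70% boundary is inclusive: the protocol's
progression rule says "$\ge 70\%$ of baseline" while the feedback display
speaks of "values above 70%", and the inclusive reading is adopted
everywhere for consistency. Level 1 promotes on a *single* GOOD (the
protocol adopts the second level as soon as the criteria are met); level 2
promotes after three GOODs and regresses after three BADs, not necessarily
consecutive; level 3 regresses one step to level 2 after three BADs --
symmetric single-step regression, adopted because only the 2→1 regression
is stated explicitly and level 3 should not be absorbing. Counters reset
on every level change so a stale count cannot trigger an immediate second
transition. A consequence used as a test oracle: an always-GOOD patient
reaches level 3 in exactly 4 performances of an exercise.

**Session planning.** Five of the twelve functions are trained per session
(20-session program, 30 dual-task minutes per session). Functions rotate
round-robin by least-recently-trained with ties broken by catalog order,
which guarantees every function appears in any three consecutive sessions;
the protocol gives an example session but no policy, so the simplest
policy with that coverage property was chosen. Exercises are instantiated
at their current progression level. The default exercise duration in the
session runner is 360 s (30 dual-task minutes over five exercises).

## Outcomes

Adherence is completed sessions over the 20 scheduled, in percent; cohorts
are summarized as the mean of per-patient percentages (the conventional
aggregation of a per-patient outcome). Perceived exertion is the Borg
15-point RPE scale, an integer in 6--20, collected once after each
session. The 30-item Intrinsic Motivation Inventory is scored on a 1--7
scale with reverse items scored $8 - x$; subscale scores are item sums
with the printed ranges 5--35 (four subscales), 6--42 (value/usefulness)
and 4--28 (perceived choice). The published subscale *sizes* constrain but
do not determine the item-to-subscale mapping, so the default mapping in
`imi_instrument()` is a synthetic, documented stand-in that satisfies the
sizes and ranges, and any alternative mapping can be loaded from a TSV
with `read_imi_instrument()`.

## Simulated responders and what they do (not) show

`responder_profile()` parameterizes a synthetic patient: per-function base
accuracy, a per-level accuracy penalty, cadence retention under dual task,
a per-session learning gain, an RPE center, and a dropout probability. The
responder answers an assignment of function $f$ at level $L$ in session
$s$ correctly with probability
$\mathrm{clip}_{[0,1]}\!\big(a_f - p\,(L-1) + r\,(s-1)\big)$, and produces
step counts centered on baseline $\times$ retention with a 5% coefficient
of variation (a minimal noise model; the protocol defines none). Cadence
retention applies uniformly across cognitive loads to keep the generator
minimal and its parameters identifiable -- the linear-probability
regression in the test suite recovers $p$ and $r$ from 10,000 simulated
trials. Simulated RPE is a clipped discrete draw centered at 13; no test
asserts any published cohort statistic, because those depend on real
patients.

What the simulation does **not** emulate: capacity-sharing dynamics of
real CMI, task prioritization strategies, fatigue within a session,
item-difficulty heterogeneity beyond the level structure, and therapist
judgement variability (safety/quality are boolean inputs). Passing tests
therefore demonstrate the correctness of the engines and the internal
consistency of the protocol rules, not clinical effect sizes.

`simulate_program()` runs the full 20-session schedule -- pre/post
assessment batteries, planning, execution through the real scoring
engines, progression, RPE, adherence -- as a deterministic function of the
profile seed; traces serialize bit-identically under a fixed seed.

## Numerical and design choices

* Thresholds (70 up, 50 down) are configuration (`engine_config()`), with
  `up > down` enforced; the defaults are the protocol's green and red
  lines.
* The composite treats skipped answers as misses in the denominator; the
  display distinguishes them, the progression rule does not.
* Battery hashing uses a 31-bit polynomial hash; collisions across
  patient codes are harmless (two patients sharing an order is expected
  under any finite randomization).
* Item banks are plain structured text (TSV; JSON for roadmap grids);
  picture pairs are metadata plus ground-truth labels, with no image
  content. Generated fixture banks use pseudo-word stimuli.
* Roadmap grids are validated at construction: exactly 7 locations and a
  destination reachable under the one-way constraints (breadth-first
  search); the fixture generator retries until reachability holds.
* Session logs are schema-versioned JSON with injectable timestamps so
  runs are reproducible byte-for-byte; an unknown schema version is an
  explicit error, never a silent partial read.
* Default problem sizes in examples and tests (banks of a few items per
  level, 4--6 assignments per exercise, 10--20 sessions) were chosen as
  the smallest sizes at which every rule of the protocol is exercised,
  including all level transitions.

## Known limitations

The engine models the patient-facing roadmap task with heading tracking;
therapist-side absolute entry is assumed pre-translated. Audio delivery,
voice capture, real-time pacing, rendering, translations, and device
integration are out of scope by design. The IMI mapping and the fixture
item banks are synthetic stand-ins, clearly labelled as such, and should
be replaced with validated instruments and curated banks before any
clinical use.
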