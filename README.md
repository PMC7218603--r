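# dualtask

A headless R engine for **cognitive-motor dual-task assessment and
training** in neurorehabilitation, aimed at researchers and engineers
working on dual-task protocols for people with multiple sclerosis and
similar populations. It implements, as testable library code, everything a
therapist-facing training app computes: cognitive task generation and
scoring, the single/dual assessment battery, dual-task cost analytics, an
11-exercise training catalog with a difficulty-progression state machine,
end-of-exercise feedback, program outcomes, and a simulated-patient
harness that exercises all of it end to end.

## What it computes

* **Assessment battery** — 3 cognitive tasks (titrated backwards digit
  span, auditory vigilance, serial subtraction by 7) × 4 walking tasks
  give 19 conditions (3 cognitive + 4 motor + 12 dual), each 60 s, in a
  per-patient randomized order that is a pure function of the patient code
  (identical at retest).
  - Digit strings are ordered samples without replacement from 1–9
    (9·8·7 = 504 possible 3-digit strings); the span staircase runs 4
    trials per length from length 3, passing at ≥ 3/4 correct.
  - Vigilance streams are 24 letters with exactly 10 targets.
  - Serial 7s use carry-forward scoring: one slip costs one error and
    correct continuations from the erroneous value count as accurate.
* **Dual-task cost** — for each (cognitive, motor) pair,
  `DTC% = (single − dual) / single × 100` on steps/min (motor) and correct
  answers/min (cognitive); positive = cost, negative = dual-task benefit.
* **Training** — 11 exercises covering 12 cognitive functions at 3
  difficulty levels (e.g. Tabooword: 20 s/0, 30 s/1, 40 s/3 taboo words,
  one third of the score lost per taboo press); 5 functions per session,
  rotated so all 12 appear in any 3 consecutive sessions; performances are
  GOOD when accuracy ≥ 70 % *and* cadence ≥ 70 % of baseline, BAD when
  either < 50 %; level 1→2 on one GOOD, 2→3 / 2→1 / 3→2 on three
  (not necessarily consecutive) GOODs/BADs.
* **Outcomes** — adherence (completed / 20 sessions), Borg RPE (6–20)
  summaries, and the 30-item Intrinsic Motivation Inventory with reverse
  items scored `8 − response` and subscale ranges 35/35/35/35/42/28.

## Worked example

```r
library(dualtask)

p <- patient_profile("MS-017", baseline_steps_walking = 112,
                     baseline_steps_stepping = 96)

# the patient's fixed assessment order (19 conditions)
b <- build_battery(p)
head(b[, c("position", "label", "block")], 5)
#>   position                label     block
#> 1        1 SERIAL_SUBTRACTION_7 cognitive
#> 2        2   AUDITORY_VIGILANCE cognitive
#> 3        3 DIGIT_SPAN_BACKWARDS cognitive
#> 4        4                 WALK     motor
#> 5        5      WALK_CRISSCROSS     motor

# titrate the span of a patient who manages strings up to 5 digits
set.seed(7)
titrate_span(function(s) if (length(s) <= 5) rev(s) else s)$span
#> [1] 5

# feedback after an exercise: 7 correct, 2 wrong, 1 skipped, 80 steps
# against a baseline cadence of 100/min
compute_feedback(7, 2, 1, steps = 80, baseline_steps_per_min = 100)
#> <dt_feedback>
#>   composite   70.0% |==============
#>   correct     70.0% |==============
#>   incorrect   20.0% |====
#>   skipped     10.0% |==
#>   steps       80.0% |================
#>   baseline   100.0% |====================
#>   level up candidate:   TRUE
#>   level down candidate: FALSE

# simulate a full 20-session program for an 85%-accurate responder
tr <- simulate_program(responder_profile(accuracy = 0.85, seed = 11), p,
                       n_sessions = 20, n_items = 6)
tr
#> <dt_program_trace> MS-017
#>   sessions completed: 20 / 20 (adherence 100.0%)
#>   final levels: NOISE=3 WORDS=3 APPLE=3 REVERSE=3 LISTEN=3 TABOOWORD=3
#>     STORY=3 DIFFERENCES=3 SEE=3 THINK=3 ROADMAP=3
#>   RPE mean 12.8 (SD 1.1) over 20 sessions

head(tr$pre_assessment$dtc, 3)
#>              cognitive          motor motor_dtc_percent cognitive_dtc_percent
#> 1 DIGIT_SPAN_BACKWARDS           WALK        12.3893805                   -25
#> 2 DIGIT_SPAN_BACKWARDS       WALK_CUP         5.4054054                   -25
#> 3 DIGIT_SPAN_BACKWARDS WALK_OBSTACLES        -0.9345794                     0
```

The composite bar is the correct fraction of all assignments; the steps
bar shows the exercise cadence relative to baseline (the slower of the two
is shown against the other pinned at 100 %). Here both feedback criteria
reach the 70 % green line, so the performance counts toward a level-up.
In the DTC table, positive motor percentages mean the patient stepped more
slowly under dual task; the negative cognitive values are a dual-task
benefit of that simulated responder.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/dualtask.R simulate --patient MS-017 --seed 11 --out out/
Rscript inst/cli/dualtask.R make-banks --n 12 --out banks/
```

## Documentation

The methods vignette (`vignettes/dualtask-methods.Rmd`) describes the
protocol rules, the design decisions taken where the protocol is silent,
the simulated-responder model and its limits, and the package's numerical
choices.
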