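make_test_patient <- function(code = "TEST-01") {
  patient_profile(code,
                  baseline_steps_walking = 110,
                  baseline_steps_stepping = 95,
                  span_length = 5L)
}

small_banks <- function(n_items = 4L, seed = 99L) {
  withr::with_seed(seed, generate_fixture_banks(n_items = n_items))
}

# feedback with the given accuracy percent and step percent of baseline,
# for driving the progression state machine in tests
fb_for <- function(accuracy_pct, steps_pct = 100) {
  compute_feedback(n_correct = accuracy_pct,
                   n_incorrect = 100 - accuracy_pct,
                   n_skipped = 0,
                   steps = steps_pct, baseline_steps_per_min = 100,
                   duration_s = 60)
}
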