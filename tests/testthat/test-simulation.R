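test_that("degenerate responder accuracies are exact", {
  states <- initial_progression_states()
  perfect <- make_responder(responder_profile(accuracy = 1,
                                              level_penalty = 0))
  never <- make_responder(responder_profile(accuracy = 0,
                                            learning_rate = 0))
  withr::with_seed(71, {
    expect_true(all(replicate(50, perfect$answer_correct("working_memory",
                                                         3L))))
    expect_false(any(replicate(50, never$answer_correct("working_memory",
                                                        1L))))
  })
})

test_that("simulated accuracy matches the profile's binomial rate", {
  r <- make_responder(responder_profile(accuracy = 0.7, level_penalty = 0,
                                        learning_rate = 0))
  hits <- withr::with_seed(72, {
    mean(replicate(10000, r$answer_correct("visual_memory", 1L)))
  })
  expect_lt(abs(hits - 0.7), 0.02)
})

test_that("level penalty and learning rate are recoverable by regression", {
  prof <- responder_profile(accuracy = 0.6, level_penalty = 0.08,
                            learning_rate = 0.01)
  r <- make_responder(prof)
  n <- 10000L
  dat <- withr::with_seed(73, {
    level <- sample(1:3, n, replace = TRUE)
    session <- sample(1:20, n, replace = TRUE)
    correct <- vapply(seq_len(n), function(i) {
      r$set_session(session[i])
      r$answer_correct("verbal_fluency", level[i])
    }, logical(1))
    data.frame(correct = as.numeric(correct), level = level,
               session = session)
  })
  fit <- lm(correct ~ level + session, data = dat)
  est <- coef(summary(fit))
  expect_lt(abs(est["level", "Estimate"] - (-prof$level_penalty)),
            2 * est["level", "Std. Error"])
  expect_lt(abs(est["session", "Estimate"] - prof$learning_rate),
            2 * est["session", "Std. Error"])
})

test_that("fixture banks are valid and solvable for all 11 exercises", {
  banks <- small_banks(n_items = 6L)
  expect_setequal(names(banks), exercise_catalog()$exercise)
  # every roadmap destination is reachable (breadth-first search oracle)
  for (m in banks$ROADMAP) {
    expect_s3_class(m, "dt_roadmap")
    expect_true(dualtask:::roadmap_reachable(m))
    expect_length(m$locations, 7L)
    route <- roadmap_solve(m)
    expect_true(score_roadmap(route, m)$pass)
  }
  # level-3 maps carry one-way streets, level-1 maps none
  lvls <- vapply(banks$ROADMAP, function(m) attr(m, "level"), integer(1))
  expect_true(all(vapply(banks$ROADMAP[lvls == 3],
                         function(m) !is.null(m$one_way), logical(1))))
  # Differences ground-truth labels balanced within 10%
  same_frac <- mean(banks$DIFFERENCES$is_same)
  expect_lt(abs(same_frac - 0.5), 0.1)
  # Reverse keys really are reversed stimuli
  expect_identical(
    banks$REVERSE$key,
    vapply(strsplit(banks$REVERSE$stimulus, ""), function(ch)
      paste(rev(ch), collapse = ""), character(1)))
})

test_that("empty banks raise a configuration error when drawn from", {
  banks <- withr::with_seed(1, generate_fixture_banks(n_items = 0L))
  expect_error(dualtask:::draw_bank_items(banks, "WORDS", 1L, 4L),
               "configuration error")
  expect_error(dualtask:::draw_bank_items(banks, "ROADMAP", 1L, 2L),
               "configuration error")
})

test_that("banks round-trip through their on-disk text formats", {
  banks <- small_banks(n_items = 3L)
  dir <- withr::local_tempdir()
  write_banks(banks, dir)
  back <- read_banks(dir)
  expect_identical(back$WORDS$key, banks$WORDS$key)
  expect_identical(back$DIFFERENCES$is_same, banks$DIFFERENCES$is_same)
  expect_length(back$ROADMAP, length(banks$ROADMAP))
  m0 <- banks$ROADMAP[[1]]; m1 <- back$ROADMAP[[1]]
  expect_identical(m1$locations, m0$locations)
  expect_identical(m1$start_cell, m0$start_cell)
  expect_identical(m1$destination, m0$destination)
})

test_that("a perfect responder reaches level 3 on its 4th performance and stays", {
  p <- make_test_patient()
  prof <- responder_profile(accuracy = 1, level_penalty = 0,
                            cadence_retention = 1, seed = 5L)
  tr <- simulate_program(prof, p, banks = small_banks(3L),
                         n_sessions = 20, n_items = 4, assess = FALSE)
  traj <- tr$progression
  for (ex in unique(traj$exercise)) {
    rows <- traj[traj$exercise == ex, ]
    # replay oracle: performance k is at level min(k-th step of 1,2,2,2,3...)
    expected <- pmin(c(1L, 2L, 2L, 2L, rep(3L, max(0, nrow(rows) - 4))),
                     3L)[seq_len(nrow(rows))]
    expect_identical(rows$level, expected)
    expect_true(all(rows$verdict == "good"))
  }
  expect_true(all(vapply(tr$final_states, function(s) s$level,
                         integer(1)) == 3L))
})

test_that("a zero-accuracy responder never leaves level 1", {
  p <- make_test_patient()
  prof <- responder_profile(accuracy = 0, learning_rate = 0,
                            cadence_retention = 1, seed = 6L)
  tr <- simulate_program(prof, p, banks = small_banks(3L),
                         n_sessions = 20, n_items = 4, assess = FALSE)
  expect_true(all(tr$progression$level == 1L))
  expect_true(all(vapply(tr$final_states, function(s) s$level,
                         integer(1)) == 1L))
})

test_that("final levels are non-decreasing in base accuracy", {
  p <- make_test_patient()
  banks <- small_banks(3L)
  final_levels <- function(acc) {
    tr <- simulate_program(responder_profile(accuracy = acc, seed = 17L),
                           p, banks = banks, n_sessions = 10,
                           n_items = 4, assess = FALSE)
    vapply(tr$final_states, function(s) s$level, integer(1))
  }
  lv <- lapply(c(0, 0.6, 1), final_levels)
  expect_true(all(lv[[3]] >= lv[[1]]))
  expect_true(mean(lv[[3]]) >= mean(lv[[2]]))
})

test_that("identical seeds give bit-identical program traces", {
  p <- make_test_patient()
  banks <- small_banks(3L)
  prof <- responder_profile(accuracy = 0.8, seed = 99L)
  t1 <- simulate_program(prof, p, banks = banks, n_sessions = 4,
                         n_items = 4)
  t2 <- simulate_program(prof, p, banks = banks, n_sessions = 4,
                         n_items = 4)
  expect_identical(serialize(t1, NULL), serialize(t2, NULL))
})

test_that("dropout truncates the program and lowers adherence", {
  p <- make_test_patient()
  prof0 <- responder_profile(accuracy = 0.8, dropout_prob = 0, seed = 3L)
  tr0 <- simulate_program(prof0, p, banks = small_banks(3L),
                          n_sessions = 6, n_items = 4, assess = FALSE)
  expect_equal(tr0$adherence_pct, 100)

  prof1 <- responder_profile(accuracy = 0.8, dropout_prob = 0.5, seed = 3L)
  tr1 <- simulate_program(prof1, p, banks = small_banks(3L),
                          n_sessions = 20, n_items = 4, assess = FALSE)
  expect_lt(tr1$adherence_pct, 100)
  expect_identical(tr1$completed_sessions, nrow(tr1$rpe))
})

test_that("session records log dosage: every exercise, level and score", {
  p <- make_test_patient()
  banks <- small_banks(3L)
  states <- initial_progression_states()
  plan <- plan_session(states, list(), 1L)
  r <- make_responder(responder_profile(accuracy = 0.9, seed = 2L))
  rec <- withr::with_seed(2, run_training_session(plan, states, banks, p, r,
                                                  n_items = 4))
  expect_identical(nrow(rec$exercises), nrow(plan$exercises))
  expect_true(all(c("exercise", "level", "n_correct", "n_incorrect",
                    "n_skipped", "steps", "composite_pct", "verdict")
                  %in% names(rec$exercises)))
  expect_true(rec$rpe$score >= 6 && rec$rpe$score <= 20)
  expect_length(rec$feedback, nrow(plan$exercises))
})
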