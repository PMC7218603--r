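test_that("level up requires both criteria at >= 70; level down below 50", {
  st <- progression_state("WORDS")
  # boundary sweep on accuracy with steps at 100%
  for (acc in c(0, 25, 49, 50, 69, 69.99, 70, 71, 100)) {
    v <- dualtask:::classify_performance(fb_for(acc, 100))
    expected <- if (acc >= 70) "good" else if (acc < 50) "bad" else "neutral"
    expect_identical(v, expected)
  }
  # boundary sweep on steps with accuracy at 100%
  for (sp in c(0, 49, 50, 69, 70, 100, 120)) {
    v <- dualtask:::classify_performance(fb_for(100, sp))
    expected <- if (sp >= 70) "good" else if (sp < 50) "bad" else "neutral"
    expect_identical(v, expected)
  }
  # failed therapist judgements force a bad performance
  expect_identical(
    dualtask:::classify_performance(fb_for(100, 100), safety_ok = FALSE),
    "bad")
  expect_identical(
    dualtask:::classify_performance(fb_for(100, 100), quality_ok = FALSE),
    "bad")
})

test_that("one good performance promotes level 1 to level 2", {
  st <- progression_state("TABOOWORD")
  st <- update_progression(st, fb_for(100, 100))
  expect_identical(st$level, 2L)
  expect_identical(st$good_count, 0L)  # counters reset on level change
})

test_that("three goods (not necessarily consecutive) promote level 2 to 3", {
  st <- progression_state("TABOOWORD", level = 2L)
  pattern <- c("good", "neutral", "good", "neutral", "good")
  for (v in pattern) {
    fb <- if (v == "good") fb_for(100, 100) else fb_for(60, 60)
    st <- update_progression(st, fb)
  }
  expect_identical(st$level, 3L)
})

test_that("three bads downgrade level 2 to 1 and level 3 to 2", {
  st <- progression_state("SEE", level = 2L)
  for (i in 1:3) st <- update_progression(st, fb_for(20, 100))
  expect_identical(st$level, 1L)

  st <- progression_state("SEE", level = 3L)
  for (i in 1:3) st <- update_progression(st, fb_for(20, 100))
  expect_identical(st$level, 2L)
})

test_that("the neutral band (50-70) leaves the state untouched", {
  st <- progression_state("LISTEN", level = 2L)
  st2 <- update_progression(st, fb_for(60, 60))
  expect_identical(st2$level, 2L)
  expect_identical(st2$good_count, 0L)
  expect_identical(st2$bad_count, 0L)
})

test_that("levels never escape 1..3 under any feedback sequence", {
  withr::with_seed(41, {
    st <- progression_state("NOISE")
    for (i in 1:200) {
      st <- update_progression(st, fb_for(sample(0:100, 1),
                                          sample(0:120, 1)))
      expect_true(st$level %in% 1:3)
    }
  })
})

test_that("an always-good run reaches level 3 in exactly 4 performances", {
  st <- progression_state("APPLE")
  levels <- integer(0)
  for (i in 1:6) {
    st <- update_progression(st, fb_for(100, 100))
    levels <- c(levels, st$level)
  }
  expect_identical(levels, c(2L, 2L, 2L, 3L, 3L, 3L))  # promoted at 1 and 4
})

test_that("an always-bad run never leaves level 1", {
  st <- progression_state("APPLE")
  for (i in 1:10) st <- update_progression(st, fb_for(0, 100))
  expect_identical(st$level, 1L)
})

test_that("progression is monotone in accuracy", {
  final_level <- function(accs) {
    st <- progression_state("THINK")
    for (a in accs) st <- update_progression(st, fb_for(a, 100))
    st$level
  }
  withr::with_seed(43, {
    for (rep in 1:20) {
      accs <- sample(0:100, 8, replace = TRUE)
      raised <- pmin(accs + sample(0:30, 8, replace = TRUE), 100)
      expect_gte(final_level(raised), final_level(accs))
    }
  })
})

test_that("session plans train five distinct functions and rotate fully", {
  states <- initial_progression_states()
  history <- list()
  windows <- list()
  for (s in 1:20) {
    plan <- plan_session(states, history, session_index = s)
    expect_length(plan$functions, 5L)
    expect_false(anyDuplicated(plan$functions) > 0)
    # exercise levels in the plan equal the progression-state levels
    expect_identical(plan$exercises$level,
                     vapply(plan$exercises$exercise,
                            function(e) states[[e]]$level, integer(1),
                            USE.NAMES = FALSE))
    history[[s]] <- plan
    windows[[s]] <- plan$functions
  }
  # sessions 1-3 jointly cover all 12 functions
  expect_setequal(unique(unlist(windows[1:3])), cognitive_functions())
  # every 3-session window covers all 12 functions
  for (s in 1:18) {
    expect_setequal(unique(unlist(windows[s:(s + 2)])),
                    cognitive_functions())
  }
})

test_that("planning fails without progression states", {
  expect_error(plan_session(list(), list(), 1L), "configuration error")
})
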