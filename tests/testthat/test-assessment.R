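test_that("digit strings are distinct digits 1-9 with the full ordered-sample support", {
  withr::with_seed(1, {
    for (len in c(1L, 5L, 9L)) {
      s <- generate_digit_string(len)
      expect_length(s, len)
      expect_true(all(s %in% 1:9))
      expect_false(anyDuplicated(s) > 0)
    }
    # length 9 exhausts the pool: a permutation of 1-9
    expect_setequal(generate_digit_string(9), 1:9)
  })
  expect_error(generate_digit_string(0), "length")
  expect_error(generate_digit_string(10), "length")
})

test_that("length-3 strings cover exactly the 504 ordered samples, uniformly", {
  # independent oracle: brute-force enumeration of ordered samples
  support <- apply(expand.grid(a = 1:9, b = 1:9, c = 1:9), 1, function(r) {
    if (anyDuplicated(r)) NA_character_ else paste(r, collapse = "")
  })
  support <- support[!is.na(support)]
  expect_length(support, 504L)  # 9 * 8 * 7

  draws <- withr::with_seed(42, {
    replicate(50400, paste(generate_digit_string(3), collapse = ""))
  })
  expect_true(all(draws %in% support))
  counts <- table(factor(draws, levels = support))
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.001)
})

test_that("digit span scoring accepts exactly the reversed string", {
  expect_true(score_digit_span(c(3, 2, 5, 7, 9), c(9, 7, 5, 2, 3)))
  expect_false(score_digit_span(c(3, 2, 5, 7, 9), c(3, 2, 5, 7, 9)))
  expect_true(score_digit_span(4, 4))             # length-1 reversal
  expect_false(score_digit_span(c(1, 2), c(2)))   # length mismatch
  expect_error(score_digit_span(integer(0), 1), "non-empty")
})

test_that("span titration follows the 4-trials, pass-at-3-of-4 staircase", {
  # correct up to length 6, always wrong at 7 -> span 6
  cap6 <- function(presented) {
    if (length(presented) <= 6) rev(presented) else presented
  }
  res <- withr::with_seed(5, titrate_span(cap6))
  expect_identical(res$span, 6L)
  expect_false(res$below_floor)
  expect_identical(max(res$log$length), 7L)

  # always wrong -> below floor, no numeric span
  res <- withr::with_seed(5, titrate_span(function(p) p))
  expect_true(res$below_floor)
  expect_true(is.na(res$span))

  # exactly 3 of 4 correct at lengths 3-5, 2 of 4 at 6 -> span 5
  counter <- local({
    n <- 0L
    function(presented) {
      n <<- n + 1L
      trial_in_block <- (n - 1L) %% 4L + 1L
      len <- length(presented)
      limit <- if (len <= 5L) 3L else 2L
      if (trial_in_block <= limit) rev(presented) else presented
    }
  })
  res <- withr::with_seed(5, titrate_span(counter))
  expect_identical(res$span, 5L)
})

test_that("titration is monotone in responder ability", {
  # responder B answers correctly on a superset of lengths vs responder A
  withr::with_seed(8, {
    for (cap in 3:7) {
      span_a <- withr::with_seed(cap, titrate_span(function(p) {
        if (length(p) <= cap) rev(p) else p
      }))$span
      span_b <- withr::with_seed(cap, titrate_span(function(p) {
        if (length(p) <= cap + 1L) rev(p) else p
      }))$span
      expect_gte(span_b, span_a)
    }
  })
})

test_that("an aborted titration preserves the partial log", {
  bomb <- local({
    n <- 0L
    function(presented) {
      n <<- n + 1L
      if (n > 5L) stop("patient walked away")
      rev(presented)
    }
  })
  err <- tryCatch(withr::with_seed(5, titrate_span(bomb)),
                  error = identity)
  expect_s3_class(err, "dt_aborted_titration")
  expect_s3_class(err$partial_log, "data.frame")
  expect_identical(nrow(err$partial_log), 5L)
})

test_that("vigilance sequences hold 24 letters with exactly 10 targets", {
  withr::with_seed(3, {
    for (i in 1:50) {
      s <- generate_vigilance_sequence(c("K", "Z"))
      expect_length(s$letters, 24L)
      expect_length(s$target_positions, 10L)
      expect_true(all(s$letters[s$target_positions] %in% c("K", "Z")))
      expect_false(any(s$letters[-s$target_positions] %in% c("K", "Z")))
    }
  })
  # 3-letter alphabet: the single remaining letter fills all 14 slots
  s <- withr::with_seed(4,
    generate_vigilance_sequence(c("A", "B"), alphabet = c("A", "B", "C")))
  expect_identical(unique(s$letters[-s$target_positions]), "C")
  expect_error(generate_vigilance_sequence(c("K", "1")), "target_letters")
  expect_error(generate_vigilance_sequence(c("A", "B"), alphabet = c("A", "B")),
               "target_letters|alphabet")
})

test_that("vigilance scoring splits yes responses into hits and false positives", {
  s <- withr::with_seed(6, generate_vigilance_sequence(c("K", "Z")))
  expect_identical(score_vigilance(s, s$target_positions),
                   c(hits = 10L, false_positives = 0L, omissions = 0L))
  expect_identical(score_vigilance(s, integer(0)),
                   c(hits = 0L, false_positives = 0L, omissions = 10L))
  expect_identical(score_vigilance(s, 1:24),
                   c(hits = 10L, false_positives = 14L, omissions = 0L))
  expect_error(score_vigilance(s, 25L), "1..24")

  # property: hits + omissions = 10 for arbitrary response sets
  withr::with_seed(7, {
    for (i in 1:25) {
      yes <- sample(1:24, sample(0:24, 1))
      sc <- score_vigilance(s, yes)
      expect_identical(sc[["hits"]] + sc[["omissions"]], 10L)
    }
  })
})

test_that("serial-7 start values are uniform on 101-199 and seed-stable", {
  draws <- withr::with_seed(11, replicate(10000, generate_serial7_start()))
  expect_true(all(draws >= 101 & draws <= 199))
  expect_identical(withr::with_seed(12, generate_serial7_start()),
                   withr::with_seed(12, generate_serial7_start()))
  counts <- table(factor(draws, levels = 101:199))
  expect_gt(chisq.test(counts)$p.value, 0.001)
})

test_that("serial-7 scoring carries the reference forward over mistakes", {
  expect_identical(score_serial7(101, c(94, 87)),
                   c(n_correct = 2L, n_errors = 0L))
  # one slip, then correct continuations from the erroneous value
  expect_identical(score_serial7(101, c(95, 88, 81)),
                   c(n_correct = 2L, n_errors = 1L))
  expect_identical(score_serial7(101, integer(0)),
                   c(n_correct = 0L, n_errors = 0L))
  # all-correct chains score zero errors from any valid start
  for (start in 101:199) {
    resp <- start - 7 * (1:8)
    expect_identical(score_serial7(start, resp)[["n_errors"]], 0L)
  }
  # the rule has no floor: responses below zero score by the same rule
  expect_identical(score_serial7(101, 101 - 7 * (1:20))[["n_errors"]], 0L)
})
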