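test_that("adherence is the completed fraction of scheduled sessions", {
  expect_equal(compute_adherence(20), 100)
  expect_equal(compute_adherence(16), 80)
  expect_equal(compute_adherence(0), 0)
  expect_error(compute_adherence(21), "invalid record")
  expect_error(compute_adherence(5, scheduled = 0), "scheduled")
  # scale invariance
  expect_equal(compute_adherence(7, 20), compute_adherence(14, 40))

  # cohort mean equals mean(counts)/20 * 100 (linearity oracle)
  counts <- c(20, 18, 15, 9, 20)
  res <- compute_adherence(counts)
  expect_equal(res$mean, sum(counts / 20 * 100) / length(counts))
  expect_equal(res$mean, mean(counts) / 20 * 100)
})

test_that("RPE records are integers in 6-20 and summaries are exact", {
  recs <- do.call(rbind, lapply(1:5, function(s) rpe_record(s, 13)))
  s <- summarize_rpe(recs)
  expect_equal(s$mean, 13)
  expect_equal(s$sd, 0)
  expect_equal(summarize_rpe(rbind(rpe_record(1, 8),
                                   rpe_record(2, 18)))$mean, 13)
  expect_error(rpe_record(1, 5), "invalid record")
  expect_error(rpe_record(1, 21), "invalid record")
  expect_error(summarize_rpe(data.frame(score = c(13, 25))),
               "invalid record")
})

test_that("the IMI instrument has 30 items in the six printed subscales", {
  inst <- imi_instrument()
  expect_identical(nrow(inst), 30L)
  sizes <- table(inst$subscale)
  expect_identical(as.integer(sizes[c("interest_enjoyment",
                                      "perceived_competence",
                                      "effort_importance",
                                      "pressure_tension",
                                      "value_usefulness",
                                      "perceived_choice")]),
                   as.integer(c(5, 5, 5, 5, 6, 4)))
})

test_that("reverse items score 8 minus the response", {
  inst <- imi_instrument()
  rev_item <- inst$item[inst$reverse][1]
  responses <- rep(4, 30)
  base <- score_imi(responses)
  responses[rev_item] <- 1  # response 1 on a reverse item scores 7
  bumped <- score_imi(responses)
  sub <- inst$subscale[inst$item == rev_item]
  expect_equal(bumped[[sub]] - base[[sub]], 3)  # 7 - 4

  # the reverse rule is an involution: 8 - (8 - x) = x
  for (x in 1:7) expect_equal(8 - (8 - x), x)
})

test_that("uniform responses of 4 hit every subscale midpoint", {
  sc <- score_imi(rep(4, 30))
  expect_equal(unname(sc["value_usefulness"]), 24)
  expect_equal(unname(sc["perceived_choice"]), 16)
  expect_true(all(sc[c("interest_enjoyment", "perceived_competence",
                       "effort_importance", "pressure_tension")] == 20))
})

test_that("per-item maximizing responses reach the printed subscale maxima", {
  inst <- imi_instrument()
  best <- ifelse(inst$reverse, 1, 7)
  worst <- ifelse(inst$reverse, 7, 1)
  expect_equal(unname(score_imi(best)[c(
    "interest_enjoyment", "perceived_competence", "effort_importance",
    "pressure_tension", "value_usefulness", "perceived_choice")]),
    c(35, 35, 35, 35, 42, 28))
  expect_equal(unname(score_imi(worst)[c(
    "interest_enjoyment", "perceived_competence", "effort_importance",
    "pressure_tension", "value_usefulness", "perceived_choice")]),
    c(5, 5, 5, 5, 6, 4))
})

test_that("every valid response vector stays inside the printed ranges", {
  lo <- c(interest_enjoyment = 5, perceived_competence = 5,
          effort_importance = 5, pressure_tension = 5,
          value_usefulness = 6, perceived_choice = 4)
  hi <- c(interest_enjoyment = 35, perceived_competence = 35,
          effort_importance = 35, pressure_tension = 35,
          value_usefulness = 42, perceived_choice = 28)
  withr::with_seed(61, {
    for (i in 1:50) {
      sc <- score_imi(sample(1:7, 30, replace = TRUE))
      expect_true(all(sc[names(lo)] >= lo & sc[names(hi)] <= hi))
    }
  })
})

test_that("invalid IMI responses are rejected naming the item", {
  r <- rep(4, 30); r[17] <- 9
  expect_error(score_imi(r), "17")
  expect_error(score_imi(rep(4, 29)), "30 responses")
  r2 <- rep(4, 30); r2[3] <- NA
  expect_error(score_imi(r2), "3")
})

test_that("a custom instrument file round-trips through TSV", {
  inst <- imi_instrument()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(inst, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_identical(read_imi_instrument(path), inst)
})
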