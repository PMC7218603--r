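#' Run one training session
#'
#' Executes each exercise of a session plan with a responder: draws
#' assignments from the item banks at the exercise's current level, routes
#' every answer through the exercise's real scoring engine (Tabooword
#' thirds, Differences time limits, Roadmap route scoring, keyed matching
#' for the rest), collects the therapist-entered step count, computes the
#' feedback report, and applies the progression rule. The session closes
#' with a Borg RPE prompt.
#'
#' @param plan A `dt_session_plan` from [plan_session()].
#' @param states Named list of `dt_progression` (updated copies are
#'   returned).
#' @param banks A `dt_banks`.
#' @param patient A `dt_patient` with baseline cadences for both motor
#'   modes.
#' @param responder A `dt_responder`.
#' @param n_items Assignments per exercise (default 10).
#' @param exercise_duration_s Duration of each exercise in seconds
#'   (default 360: the program's 30 dual-task minutes spread over the
#'   session's five exercises).
#' @param steps_provider Optional override `f(exercise, motor_mode,
#'   duration_s)` returning a step count; by default the responder's step
#'   model is used. A missing (`NA`) step count is an error: the therapist
#'   is obligated to enter the number of steps.
#' @return A list of class `dt_session_record`: `session_index`,
#'   `exercises` (data frame with counts, steps, feedback percentages,
#'   verdict, level before/after), `feedback` (list of `dt_feedback`),
#'   `states` (updated progression states), and `rpe`.
#' @export
run_training_session <- function(plan, states, banks, patient, responder,
                                 n_items = 10L, exercise_duration_s = 360,
                                 steps_provider = NULL) {
  stopifnot(inherits(plan, "dt_session_plan"),
            inherits(patient, "dt_patient"),
            inherits(responder, "dt_responder"))
  responder$set_session(plan$session_index)
  n_items <- check_int_range(n_items, 1L, 1000L, "n_items")
  rows <- list()
  fbs <- list()
  for (i in seq_len(nrow(plan$exercises))) {
    ex <- plan$exercises$exercise[i]
    level <- states[[ex]]$level
    mode <- plan$exercises$motor_mode[i]
    funs <- plan$exercises$functions[[i]]
    counts <- administer_exercise(ex, level, funs, banks, responder,
                                  n_items)
    baseline <- if (mode == "walking") patient$baseline_steps_walking
                else patient$baseline_steps_stepping
    if (is.na(baseline)) {
      stop("patient has no baseline cadence for motor mode '", mode, "'",
           call. = FALSE)
    }
    steps <- if (is.null(steps_provider)) {
      responder$steps(baseline, exercise_duration_s)
    } else {
      steps_provider(ex, mode, exercise_duration_s)
    }
    if (is.null(steps) || is.na(steps)) {
      stop("incomplete exercise: the therapist must enter the number of ",
           "steps for '", ex, "'", call. = FALSE)
    }
    fb <- compute_feedback(counts[["n_correct"]], counts[["n_incorrect"]],
                           counts[["n_skipped"]], steps = steps,
                           baseline_steps_per_min = baseline,
                           duration_s = exercise_duration_s)
    new_state <- update_progression(states[[ex]], fb,
                                    safety_ok = responder$safety_ok(),
                                    quality_ok = responder$quality_ok())
    verdict <- utils::tail(new_state$history, 1L)
    rows[[i]] <- data.frame(
      session = plan$session_index, exercise = ex,
      level = level, level_after = new_state$level,
      motor_mode = mode,
      n_correct = counts[["n_correct"]],
      n_incorrect = counts[["n_incorrect"]],
      n_skipped = counts[["n_skipped"]],
      steps = steps, duration_s = exercise_duration_s,
      composite_pct = fb$composite_pct,
      steps_rel_pct = fb$steps_rel_pct,
      verdict = verdict,
      stringsAsFactors = FALSE
    )
    fbs[[ex]] <- fb
    states[[ex]] <- new_state
  }
  exercises <- do.call(rbind, rows)
  rownames(exercises) <- NULL
  rpe <- responder$rpe()
  structure(
    list(session_index = plan$session_index, exercises = exercises,
         feedback = fbs, states = states, rpe = rpe_record(
           plan$session_index, rpe)),
    class = "dt_session_record"
  )
}

# Administer n assignments of one exercise through its scoring engine and
# return correct/incorrect/skipped counts. The responder decides per item
# whether the answer will be right; the engines turn that intent into the
# recorded outcome.
administer_exercise <- function(exercise, level, functions, banks,
                                responder, n_items) {
  n_correct <- n_incorrect <- n_skipped <- 0L
  items <- draw_bank_items(banks, exercise, level, n_items)
  tally <- function(res) {
    if (identical(res, "correct")) n_correct <<- n_correct + 1L
    else if (identical(res, "incorrect")) n_incorrect <<- n_incorrect + 1L
    else n_skipped <<- n_skipped + 1L
  }
  for (j in seq_len(n_items)) {
    ok <- responder$answer_correct(functions, level)
    if (exercise == "TABOOWORD") {
      res <- if (ok) score_tabooword("good_description", 0L)
             else score_tabooword("timeout")
      tally(res$result)
    } else if (exercise == "DIFFERENCES") {
      item <- items[j, , drop = FALSE]
      lim <- level_parameters("DIFFERENCES", level)$time_limit_s
      truth <- if (item$is_same) "same" else "different"
      ans <- if (ok) truth else setdiff(c("same", "different"), truth)
      tally(score_differences(list(is_same = item$is_same,
                                   time_limit_s = lim),
                              ans, elapsed_s = lim / 2))
    } else if (exercise == "ROADMAP") {
      map <- items[[j]]
      route <- roadmap_solve(map)
      if (ok && !is.null(route)) {
        res <- score_roadmap(route, map)
      } else {
        # a lost patient: truncate the route, ending off-destination
        res <- score_roadmap(utils::head(route, max(0L,
                                                    length(route) - 1L)),
                             map)
        res$pass <- FALSE
      }
      tally(if (res$pass) "correct" else "incorrect")
    } else if (exercise == "STORY") {
      item <- items[j, , drop = FALSE]
      key <- strsplit(item$key, ",")[[1]]
      ans <- vapply(key, function(k) {
        if (responder$answer_correct(functions, level)) k
        else setdiff(c("a", "b", "c"), k)[1L]
      }, character(1))
      sc <- score_generic(list(key = key), ans)
      n_correct <- n_correct + sc[["n_correct"]]
      n_incorrect <- n_incorrect + sc[["n_incorrect"]]
    } else {
      item <- items[j, , drop = FALSE]
      ans <- if (ok) item$key else paste0(item$key, "_wrong")
      tally(score_generic(list(key = item$key), ans))
    }
  }
  c(n_correct = n_correct, n_incorrect = n_incorrect,
    n_skipped = n_skipped)
}
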