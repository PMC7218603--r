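#' Create a fresh progression state for an exercise
#'
#' Every exercise starts the program at level 1. Good and bad performance
#' counters accumulate across sessions (not necessarily consecutively) and
#' are reset whenever the level changes.
#'
#' @param exercise Exercise id from [exercise_catalog()].
#' @param level Starting level (default 1).
#' @return A list of class `dt_progression`.
#' @export
progression_state <- function(exercise, level = 1L) {
  exercise <- match.arg(exercise, exercise_catalog()$exercise)
  level <- check_int_range(level, 1L, 3L, "level")
  structure(
    list(exercise = exercise, level = level,
         good_count = 0L, bad_count = 0L,
         history = character(0)),
    class = "dt_progression"
  )
}

# Classify a performance from its feedback and the therapist's safety and
# quality judgements. GOOD requires cadence >= 70% of baseline AND
# accuracy >= 70% AND both judgements satisfied; BAD is cadence < 50% of
# baseline OR accuracy < 50% OR a failed judgement. Everything in between
# is neutral and leaves the counters untouched.
classify_performance <- function(feedback, safety_ok = TRUE,
                                 quality_ok = TRUE) {
  stopifnot(inherits(feedback, "dt_feedback"))
  if (!isTRUE(feedback$has_assignments)) return("neutral")
  acc <- feedback$composite_pct
  steps <- feedback$steps_rel_pct
  steps_ok_up <- is.na(steps) || steps >= 70
  steps_bad <- !is.na(steps) && steps < 50
  if (!safety_ok || !quality_ok || acc < 50 || steps_bad) return("bad")
  if (acc >= 70 && steps_ok_up) return("good")
  "neutral"
}

#' Update an exercise's difficulty level after a performance
#'
#' Implements the difficulty-progression rules: every exercise starts at
#' level 1 and moves to level 2 as soon as one performance meets the
#' progression criteria (steps per minute >= 70% of baseline and accuracy
#' >= 70%, with therapist safety and quality judgements satisfied). From
#' level 2 the patient is advanced to level 3 after three good
#' performances, or downgraded to level 1 after three bad performances
#' (bad: steps < 50% of baseline or accuracy < 50% or a failed judgement);
#' the three need not be consecutive. From level 3, three bad performances
#' regress one level to 2. Counters reset on any level change; neutral
#' performances change nothing.
#'
#' @param state A `dt_progression`.
#' @param feedback A `dt_feedback` for the performance just completed.
#' @param safety_ok,quality_ok Therapist judgements (logical).
#' @return The updated `dt_progression`.
#' @examples
#' st <- progression_state("TABOOWORD")
#' fb <- compute_feedback(10, 0, 0, steps = 100,
#'                        baseline_steps_per_min = 100)
#' update_progression(st, fb)$level  # 2 after a single good performance
#' @export
update_progression <- function(state, feedback, safety_ok = TRUE,
                               quality_ok = TRUE) {
  stopifnot(inherits(state, "dt_progression"))
  verdict <- classify_performance(feedback, safety_ok, quality_ok)
  state$history <- c(state$history, verdict)
  if (verdict == "good") state$good_count <- state$good_count + 1L
  if (verdict == "bad") state$bad_count <- state$bad_count + 1L
  new_level <- state$level
  if (state$level == 1L) {
    if (verdict == "good") new_level <- 2L
  } else if (state$level == 2L) {
    if (state$good_count >= 3L) new_level <- 3L
    else if (state$bad_count >= 3L) new_level <- 1L
  } else {  # level 3 is a ceiling; only regression is possible
    if (state$bad_count >= 3L) new_level <- 2L
  }
  if (new_level != state$level) {
    state$level <- new_level
    state$good_count <- 0L
    state$bad_count <- 0L
  }
  state
}

#' Plan one training session
#'
#' To avoid overloading the patient, only five of the twelve cognitive
#' functions are trained per session. Functions are rotated round-robin by
#' least-recently-trained (ties broken by catalog order), which guarantees
#' every function is trained at least once in any three consecutive
#' sessions. Each selected function is covered by an exercise tagged with
#' it, instantiated at the exercise's current difficulty level; an
#' exercise tagged with two selected functions covers both.
#'
#' @param states Named list of `dt_progression`, one per exercise (as from
#'   [initial_progression_states()]).
#' @param history List of previous session plans (the `functions` element
#'   of each is used for recency); `list()` for session 1.
#' @param session_index 1-based session number (<= the program's session
#'   count, conventionally 20).
#' @param k Number of cognitive functions per session (default 5).
#' @return A list of class `dt_session_plan`: `session_index`, `functions`
#'   (length `k`), and `exercises` (data frame: exercise, level,
#'   motor_mode, functions covered).
#' @export
plan_session <- function(states, history = list(), session_index = 1L,
                         k = 5L) {
  cat_df <- exercise_catalog()
  if (is.null(states) || !length(states)) {
    stop("configuration error: no progression states (empty catalog?)",
         call. = FALSE)
  }
  session_index <- check_int_range(session_index, 1L, 1000L,
                                   "session_index")
  funs <- cognitive_functions()
  k <- check_int_range(k, 1L, length(funs), "k")
  # least-recently-trained: the session index at which each function last
  # appeared (0 = never)
  last_seen <- setNames(rep(0L, length(funs)), funs)
  for (j in seq_along(history)) {
    for (f in history[[j]]$functions) last_seen[f] <- j
  }
  ord <- order(last_seen, match(names(last_seen), funs))
  chosen <- names(last_seen)[ord][seq_len(k)]
  # cover each chosen function with an exercise tagged with it,
  # preferring the least-recently-used exercise, ties by catalog order
  ex_last <- setNames(rep(0L, nrow(cat_df)), cat_df$exercise)
  for (j in seq_along(history)) {
    for (e in history[[j]]$exercises$exercise) ex_last[e] <- j
  }
  picked <- character(0)
  covered <- character(0)
  for (f in chosen) {
    if (f %in% covered) next
    cands <- cat_df$exercise[vapply(cat_df$functions,
                                    function(fs) f %in% fs, logical(1))]
    fresh <- setdiff(cands, picked)
    if (length(fresh)) {
      pick <- fresh[order(ex_last[fresh], match(fresh, cat_df$exercise))][1L]
      picked <- c(picked, pick)
    } else {
      pick <- cands[1L]  # already in the plan; just extends coverage
    }
    covered <- union(covered,
                     cat_df$functions[[match(pick, cat_df$exercise)]])
  }
  ex_rows <- cat_df[match(picked, cat_df$exercise), , drop = FALSE]
  plan_df <- data.frame(
    exercise = ex_rows$exercise,
    level = vapply(ex_rows$exercise,
                   function(e) states[[e]]$level, integer(1)),
    motor_mode = ex_rows$motor_mode,
    stringsAsFactors = FALSE
  )
  plan_df$functions <- ex_rows$functions
  rownames(plan_df) <- NULL
  structure(
    list(session_index = session_index, functions = chosen,
         exercises = plan_df),
    class = "dt_session_plan"
  )
}

#' @rdname plan_session
#' @return `initial_progression_states()`: named list with a fresh level-1
#'   state for each of the 11 exercises.
#' @export
initial_progression_states <- function() {
  ex <- exercise_catalog()$exercise
  setNames(lapply(ex, progression_state), ex)
}
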