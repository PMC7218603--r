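#' Simulate a full training program
#'
#' Runs the 20-session dual-task training schedule end to end with a
#' simulated responder: pre-program assessment (full 19-condition battery
#' plus dual-task costs), session planning with the five-function
#' rotation, execution of every exercise through the real scoring engines
#' and the progression state machine, per-session RPE, a post-program
#' assessment, and program adherence. The entire trace is a deterministic
#' function of the responder profile's seed.
#'
#' @param profile A `dt_responder_profile`.
#' @param patient A `dt_patient` with both baseline cadences set.
#' @param banks A `dt_banks`; generated from the profile's seed when
#'   omitted.
#' @param n_sessions Scheduled sessions (default 20).
#' @param n_items Assignments per exercise (default 10).
#' @param assess Run the pre/post assessment batteries (default `TRUE`).
#' @return A list of class `dt_program_trace`: `patient`, `profile`,
#'   `pre_assessment` and `post_assessment` (trial results + DTC matrix),
#'   `sessions` (list of `dt_session_record`), `progression` (data frame
#'   of every level trajectory), `rpe` (data frame), `final_states`,
#'   `completed_sessions`, and `adherence_pct`.
#' @examples
#' p <- patient_profile("SIM-01", baseline_steps_walking = 110,
#'                      baseline_steps_stepping = 95)
#' tr <- simulate_program(responder_profile(seed = 42), p,
#'                        n_sessions = 2, n_items = 4, assess = FALSE)
#' tr$adherence_pct
#' @export
simulate_program <- function(profile, patient, banks = NULL,
                             n_sessions = 20L, n_items = 10L,
                             assess = TRUE) {
  stopifnot(inherits(profile, "dt_responder_profile"),
            inherits(patient, "dt_patient"))
  n_sessions <- check_int_range(n_sessions, 1L, 1000L, "n_sessions")
  set.seed(profile$seed)
  if (is.null(banks)) banks <- generate_fixture_banks()
  responder <- make_responder(profile)
  steps_for <- function(cond_row) {
    baseline <- patient$baseline_steps_walking
    retention <- if (is.na(cond_row$cognitive)) 1 else
      profile$cadence_retention
    max(0L, as.integer(round(baseline * retention *
                               (1 + stats::rnorm(1, 0, 0.05)))))
  }
  pre <- post <- NULL
  if (assess) {
    battery <- build_battery(patient)
    trials <- run_assessment(battery, responder, steps_for,
                             span_length = patient$span_length %na%
                               5L)
    pre <- list(trials = trials, dtc = dtc_matrix(trials))
  }
  states <- initial_progression_states()
  history <- list()
  sessions <- list()
  rpe <- list()
  completed <- 0L
  for (s in seq_len(n_sessions)) {
    if (profile$dropout_prob > 0 &&
        stats::runif(1) < profile$dropout_prob) {
      break  # patient abandons the program; later sessions never run
    }
    plan <- plan_session(states, history, session_index = s)
    rec <- run_training_session(plan, states, banks, patient, responder,
                                n_items = n_items)
    states <- rec$states
    history[[length(history) + 1L]] <- plan
    sessions[[length(sessions) + 1L]] <- rec
    rpe[[length(rpe) + 1L]] <- rec$rpe
    completed <- completed + 1L
  }
  if (assess) {
    responder$set_session(n_sessions + 1L)
    battery <- build_battery(patient)
    trials <- run_assessment(battery, responder, steps_for,
                             span_length = patient$span_length %na% 5L)
    post <- list(trials = trials, dtc = dtc_matrix(trials))
  }
  progression <- do.call(rbind, lapply(sessions, function(r) r$exercises))
  structure(
    list(patient = patient, profile = profile,
         pre_assessment = pre, post_assessment = post,
         sessions = sessions,
         progression = progression,
         rpe = if (length(rpe)) do.call(rbind, rpe) else
           data.frame(session_index = integer(0), score = integer(0)),
         final_states = states,
         completed_sessions = completed,
         scheduled_sessions = n_sessions,
         adherence_pct = compute_adherence(completed, n_sessions)),
    class = "dt_program_trace"
  )
}

`%na%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.dt_program_trace <- function(x, ...) {
  cat("<dt_program_trace>", x$patient$patient_code, "\n")
  cat("  sessions completed:", x$completed_sessions, "/",
      x$scheduled_sessions,
      sprintf("(adherence %.1f%%)\n", x$adherence_pct))
  lv <- vapply(x$final_states, function(s) s$level, integer(1))
  cat("  final levels:", paste(names(lv), lv, sep = "=",
                               collapse = " "), "\n")
  if (nrow(x$rpe)) {
    s <- summarize_rpe(x$rpe)
    cat(sprintf("  RPE mean %.1f (SD %.1f) over %d sessions\n",
                s$mean, s$sd, s$n))
  }
  invisible(x)
}
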