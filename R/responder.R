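#' Define a simulated responder profile
#'
#' A responder profile parameterizes a synthetic patient used to exercise
#' every engine without human input: a base probability of answering an
#' assignment correctly per cognitive function, a per-level accuracy
#' penalty, the fraction of baseline cadence retained under dual task, a
#' per-session learning gain, and a center for the simulated end-of-session
#' Borg RPE rating. All probabilities are clipped to `[0, 1]` after
#' penalties and gains are applied.
#'
#' @param accuracy Either a single base accuracy applied to every
#'   cognitive function or a named vector over (a subset of)
#'   [cognitive_functions()]; unnamed functions fall back to `0.7`.
#' @param level_penalty Accuracy decrement per difficulty level above 1.
#' @param cadence_retention Fraction of baseline steps/min retained under
#'   dual task, in `[0, 1.5]`.
#' @param learning_rate Additive accuracy gain per completed session.
#' @param rpe_center Center of the simulated Borg RPE draw (6-20 scale).
#' @param dropout_prob Per-session probability of abandoning the program.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return A list of class `dt_responder_profile`.
#' @examples
#' responder_profile(accuracy = 0.8, seed = 1)
#' @export
responder_profile <- function(accuracy = 0.7, level_penalty = 0.05,
                              cadence_retention = 0.9,
                              learning_rate = 0.005, rpe_center = 13,
                              dropout_prob = 0, seed = 1L) {
  funs <- cognitive_functions()
  if (is.null(names(accuracy))) {
    if (length(accuracy) != 1L) {
      stop("unnamed accuracy must be a single value", call. = FALSE)
    }
    acc <- setNames(rep(accuracy, length(funs)), funs)
  } else {
    unknown <- setdiff(names(accuracy), funs)
    if (length(unknown)) {
      stop("configuration error: unknown cognitive function(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    acc <- setNames(rep(0.7, length(funs)), funs)
    acc[names(accuracy)] <- accuracy
  }
  stopifnot(all(acc >= 0 & acc <= 1), level_penalty >= 0,
            cadence_retention >= 0, cadence_retention <= 1.5,
            learning_rate >= 0, rpe_center >= 6, rpe_center <= 20,
            dropout_prob >= 0, dropout_prob <= 1)
  structure(
    list(accuracy_by_function = acc, level_penalty = level_penalty,
         cadence_retention = cadence_retention,
         learning_rate = learning_rate, rpe_center = rpe_center,
         dropout_prob = dropout_prob, seed = as.integer(seed)),
    class = "dt_responder_profile"
  )
}

#' Build an answer provider from a responder profile
#'
#' The returned responder answers any assignment of function `f` at level
#' `L` in session `s` correctly with probability
#' `clip(accuracy[f] - level_penalty * (L - 1) + learning_rate * (s - 1))`,
#' produces step counts centered on `baseline * cadence_retention` with a
#' 5% coefficient of variation, and draws end-of-session RPE ratings
#' around `rpe_center` clipped into 6-20. It also implements the
#' assessment-task interfaces (digit span responses, vigilance yes
#' responses, serial-7 responses) so the same object drives
#' [run_assessment()]. Randomness comes from the session RNG; seed it (or
#' use [simulate_program()], which seeds from the profile) for
#' reproducibility.
#'
#' @param profile A `dt_responder_profile`.
#' @param target_letters Vigilance target letters used in assessments.
#' @return A list of closures (class `dt_responder`); see Details.
#' @export
make_responder <- function(profile, target_letters = c("K", "Z")) {
  stopifnot(inherits(profile, "dt_responder_profile"))
  env <- new.env(parent = emptyenv())
  env$session <- 1L

  p_correct <- function(functions, level = 1L) {
    base <- mean(profile$accuracy_by_function[functions])
    p <- base - profile$level_penalty * (level - 1) +
      profile$learning_rate * (env$session - 1L)
    min(1, max(0, p))
  }
  # assessment tasks are scored at level 1 of their underlying functions
  assess_p <- function(fn) p_correct(fn, 1L)

  responder <- list(
    profile = profile,
    target_letters = target_letters,
    set_session = function(s) env$session <- as.integer(s),
    get_session = function() env$session,
    p_correct = p_correct,
    answer_correct = function(functions, level) {
      stats::runif(1) < p_correct(functions, level)
    },
    steps = function(baseline_steps_per_min, duration_s = 60) {
      mu <- baseline_steps_per_min * profile$cadence_retention *
        duration_s / 60
      max(0L, as.integer(round(mu * (1 + stats::rnorm(1, 0, 0.05)))))
    },
    rpe = function() {
      as.integer(min(20, max(6, round(stats::rnorm(1, profile$rpe_center,
                                                   1.5)))))
    },
    safety_ok = function() TRUE,
    quality_ok = function() TRUE,
    digit_response = function(presented) {
      if (stats::runif(1) < assess_p("working_memory")) rev(presented)
      else presented  # forward repetition: a typical span error
    },
    vigilance_yes = function(sequence) {
      p <- assess_p("sustained_attention")
      hits <- sequence$target_positions[
        stats::runif(length(sequence$target_positions)) < p]
      nontarget <- setdiff(seq_along(sequence$letters),
                           sequence$target_positions)
      fps <- nontarget[stats::runif(length(nontarget)) < (1 - p) * 0.2]
      sort(c(hits, fps))
    },
    serial7_responses = function(start, n = 15L) {
      p <- assess_p("information_processing_speed")
      ref <- start
      out <- integer(n)
      for (i in seq_len(n)) {
        out[i] <- if (stats::runif(1) < p) ref - 7L
                  else ref - 7L + sample(c(-2L, -1L, 1L, 2L), 1L)
        ref <- out[i]
      }
      out
    }
  )
  structure(responder, class = "dt_responder")
}

#' Deterministic scripted responder
#'
#' A responder that is always correct (or always wrong): useful for
#' titration tests, hand-scored oracles, and progression-rule checks.
#'
#' @param correct Logical; answer every assignment correctly?
#' @param cadence_retention Fraction of baseline cadence produced as step
#'   counts (deterministic, no noise).
#' @param target_letters Vigilance target letters.
#' @return A `dt_responder`.
#' @examples
#' r <- scripted_responder(correct = TRUE)
#' r$digit_response(c(3, 1, 4))  # 4 1 3
#' @export
scripted_responder <- function(correct = TRUE, cadence_retention = 1,
                               target_letters = c("K", "Z")) {
  env <- new.env(parent = emptyenv())
  env$session <- 1L
  structure(list(
    profile = NULL,
    target_letters = target_letters,
    set_session = function(s) env$session <- as.integer(s),
    get_session = function() env$session,
    p_correct = function(functions, level) as.numeric(correct),
    answer_correct = function(functions, level) correct,
    steps = function(baseline_steps_per_min, duration_s = 60) {
      as.integer(round(baseline_steps_per_min * cadence_retention *
                         duration_s / 60))
    },
    rpe = function() 13L,
    safety_ok = function() TRUE,
    quality_ok = function() TRUE,
    digit_response = function(presented) {
      if (correct) rev(presented) else presented
    },
    vigilance_yes = function(sequence) {
      if (correct) sequence$target_positions else integer(0)
    },
    serial7_responses = function(start, n = 15L) {
      if (correct) start - 7L * seq_len(n) else start - seq_len(n)
    }
  ), class = "dt_responder")
}
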