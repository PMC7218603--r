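#' Score a Tabooword assignment
#'
#' The patient describes a guess word without using the word itself, its
#' derivatives, gestures, clues, or the forbidden taboo words. The
#' therapist presses the taboo button each time a rule is broken: every
#' press removes one third of the score, and at three presses the whole
#' assignment is scored as wrong. A timeout scores the assignment as
#' incorrect; a skip (patient declines without trying) is excluded from
#' the correct/incorrect counts.
#'
#' @param outcome One of `"good_description"`, `"timeout"`, `"skipped"`.
#' @param presses Number of taboo-button presses (>= 0).
#' @return List with `score` in `[0, 1]` (or `NA` for a skip) and `result`
#'   (`"correct"`, `"incorrect"`, or `"skipped"`). An assignment is counted
#'   correct only when its score is positive.
#' @examples
#' score_tabooword("good_description", 0)$score  # 1
#' score_tabooword("good_description", 1)$score  # 2/3
#' score_tabooword("good_description", 3)$score  # 0: scored wrong
#' @export
score_tabooword <- function(outcome = c("good_description", "timeout",
                                        "skipped"),
                            presses = 0L) {
  outcome <- match.arg(outcome)
  if (!is.numeric(presses) || length(presses) != 1L || is.na(presses) ||
      presses < 0) {
    stop("presses must be a non-negative count", call. = FALSE)
  }
  if (outcome == "skipped") {
    return(list(score = NA_real_, result = "skipped"))
  }
  if (outcome == "timeout") {
    return(list(score = 0, result = "incorrect"))
  }
  score <- max(0, 1 - presses / 3)
  list(score = score, result = if (score > 0) "correct" else "incorrect")
}

#' Score a Differences assignment
#'
#' The patient judges whether two pictures are the same or different
#' within the level's time limit (15 / 20 / 30 s at levels 1-3). Running
#' out of time scores the assignment as incorrect; a skip is recorded as
#' skipped, not incorrect.
#'
#' @param assignment List with logical `is_same` (ground truth) and
#'   `time_limit_s`.
#' @param answer One of `"same"`, `"different"`, `"skipped"`.
#' @param elapsed_s Seconds taken to answer (>= 0).
#' @return `"correct"`, `"incorrect"`, or `"skipped"`.
#' @examples
#' a <- list(is_same = FALSE, time_limit_s = 15)
#' score_differences(a, "different", 10)  # "correct"
#' score_differences(a, "different", 16)  # "incorrect": over the limit
#' @export
score_differences <- function(assignment,
                              answer = c("same", "different", "skipped"),
                              elapsed_s = 0) {
  answer <- match.arg(answer)
  stopifnot(is.list(assignment), is.logical(assignment$is_same),
            is.numeric(assignment$time_limit_s))
  if (!is.numeric(elapsed_s) || elapsed_s < 0) {
    stop("elapsed_s must be >= 0", call. = FALSE)
  }
  if (answer == "skipped") return("skipped")
  if (elapsed_s > assignment$time_limit_s) return("incorrect")
  said_same <- answer == "same"
  if (said_same == assignment$is_same) "correct" else "incorrect"
}

#' Score a generic keyed assignment
#'
#' Exact-match scoring against the item bank's answer key within the time
#' limit, used by the exercises whose assignments have a single keyed
#' answer (Noise, Words, Apple, Reverse, Listen, See, Think) and, per
#' question, by Story. Matching is case-insensitive and whitespace-trimmed.
#' Story items carry three multiple-choice questions and yield up to three
#' correct answers per item.
#'
#' @param item List with `key` (character; for Story a vector of 3) and
#'   optionally `time_limit_s`.
#' @param answer Character answer (same length as `key`), or `"skipped"`.
#' @param elapsed_s Seconds taken (default 0).
#' @return For single-key items `"correct"`, `"incorrect"` or `"skipped"`;
#'   for multi-key (Story) items a named integer vector
#'   `c(n_correct, n_incorrect)`.
#' @examples
#' score_generic(list(key = "tac"), "tac")  # reverse-spelling of "cat"
#' score_generic(list(key = c("a", "b", "c")), c("a", "b", "x"))
#' @export
score_generic <- function(item, answer, elapsed_s = 0) {
  if (!is.list(item) || is.null(item$key) || !length(item$key) ||
      any(is.na(item$key))) {
    stop("malformed bank item: missing answer key", call. = FALSE)
  }
  norm <- function(x) tolower(trimws(as.character(x)))
  limit <- item$time_limit_s %||% Inf
  multi <- length(item$key) > 1L
  if (!multi) {
    if (identical(norm(answer), "skipped")) return("skipped")
    if (elapsed_s > limit) return("incorrect")
    if (length(answer) == 1L && norm(answer) == norm(item$key)) "correct"
    else "incorrect"
  } else {
    if (elapsed_s > limit) {
      return(c(n_correct = 0L, n_incorrect = length(item$key)))
    }
    answer <- rep_len(as.character(answer), length(item$key))
    ok <- norm(answer) == norm(item$key)
    c(n_correct = sum(ok), n_incorrect = sum(!ok))
  }
}
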