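#' Compute the end-of-exercise feedback report
#'
#' Mirrors the six feedback bars shown to the therapist after each
#' exercise: a composite cognitive score plus the percentages of correct,
#' incorrect and skipped answers, and the step/baseline pair. The
#' composite is `correct / (correct + incorrect + skipped) * 100`. For the
#' step bars, whichever of the exercise cadence and the baseline cadence
#' is smaller is expressed as a percentage of the larger, which is pinned
#' at 100%: with fewer steps than baseline the baseline bar is 100% and
#' the steps bar is steps relative to baseline; with more steps the steps
#' bar is 100% and the baseline bar shrinks. The 70% (green) and 50% (red)
#' lines drive the level-up / level-down candidate flags; both criteria --
#' composite score and steps relative to baseline -- must be >= 70 for
#' level-up, and either < 50 triggers level-down.
#'
#' @param n_correct,n_incorrect,n_skipped Answer counts (>= 0).
#' @param steps Steps counted during the exercise (>= 0), or `NA` if the
#'   exercise had no motor component.
#' @param baseline_steps_per_min Patient's baseline cadence (> 0) for the
#'   exercise's motor mode.
#' @param duration_s Exercise duration in seconds (> 0, default 60).
#' @return A list of class `dt_feedback`: `composite_pct`, `correct_pct`,
#'   `incorrect_pct`, `skipped_pct` (each `NA` with `has_assignments =
#'   FALSE` when no assignment was given), `steps_pct`, `baseline_pct`,
#'   `steps_rel_pct` (exercise cadence as a percentage of baseline,
#'   uncapped -- the quantity the progression rule thresholds), and the
#'   flags `level_up_candidate`, `level_down_candidate`.
#' @examples
#' fb <- compute_feedback(7, 2, 1, steps = 80,
#'                        baseline_steps_per_min = 100)
#' fb$composite_pct  # 70
#' fb$steps_pct      # 80; baseline bar 100
#' @export
compute_feedback <- function(n_correct, n_incorrect = 0L, n_skipped = 0L,
                             steps = NA, baseline_steps_per_min,
                             duration_s = 60) {
  for (v in list(n_correct, n_incorrect, n_skipped)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("answer counts must be non-negative numbers", call. = FALSE)
    }
  }
  if (!is.numeric(baseline_steps_per_min) || is.na(baseline_steps_per_min) ||
      baseline_steps_per_min <= 0) {
    stop("undefined baseline: baseline_steps_per_min must be > 0",
         call. = FALSE)
  }
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop("duration_s must be > 0", call. = FALSE)
  }
  total <- n_correct + n_incorrect + n_skipped
  has_assignments <- total > 0
  if (has_assignments) {
    correct_pct <- n_correct / total * 100
    incorrect_pct <- n_incorrect / total * 100
    skipped_pct <- n_skipped / total * 100
    composite_pct <- correct_pct
  } else {
    correct_pct <- incorrect_pct <- skipped_pct <- composite_pct <- NA_real_
  }
  if (!is.na(steps)) {
    steps_rate <- steps * 60 / duration_s
    steps_rel_pct <- steps_rate / baseline_steps_per_min * 100
    if (steps_rate <= baseline_steps_per_min) {
      baseline_pct <- 100
      steps_pct <- steps_rel_pct
    } else {
      steps_pct <- 100
      baseline_pct <- baseline_steps_per_min / steps_rate * 100
    }
  } else {
    steps_pct <- baseline_pct <- steps_rel_pct <- NA_real_
  }
  # zero-assignment trials have no composite and never move the level
  up <- has_assignments && composite_pct >= 70 &&
    (is.na(steps_rel_pct) || steps_rel_pct >= 70)
  down <- has_assignments &&
    (composite_pct < 50 || (!is.na(steps_rel_pct) && steps_rel_pct < 50))
  structure(
    list(composite_pct = composite_pct, correct_pct = correct_pct,
         incorrect_pct = incorrect_pct, skipped_pct = skipped_pct,
         steps_pct = steps_pct, baseline_pct = baseline_pct,
         steps_rel_pct = steps_rel_pct,
         has_assignments = has_assignments,
         level_up_candidate = isTRUE(up),
         level_down_candidate = isTRUE(down)),
    class = "dt_feedback"
  )
}

#' @export
print.dt_feedback <- function(x, ...) {
  bar <- function(p) {
    if (is.na(p)) return("   --")
    sprintf("%5.1f%% |%s", p, strrep("=", round(p / 5)))
  }
  cat("<dt_feedback>\n")
  cat("  composite ", bar(x$composite_pct), "\n")
  cat("  correct   ", bar(x$correct_pct), "\n")
  cat("  incorrect ", bar(x$incorrect_pct), "\n")
  cat("  skipped   ", bar(x$skipped_pct), "\n")
  cat("  steps     ", bar(x$steps_pct), "\n")
  cat("  baseline  ", bar(x$baseline_pct), "\n")
  cat("  level up candidate:  ", x$level_up_candidate, "\n")
  cat("  level down candidate:", x$level_down_candidate, "\n")
  invisible(x)
}
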