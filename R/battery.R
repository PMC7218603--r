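#' Enumerate the 19 assessment conditions
#'
#' The battery crosses 3 cognitive tasks and 4 walking tasks: 3 single
#' cognitive conditions, 4 single (or dual, for the more complex walks)
#' motor conditions, and 12 combined cognitive-motor conditions, giving 19
#' conditions in total.
#'
#' @return Data frame with columns `cognitive`, `motor` (task ids or `NA`),
#'   `block` (`"cognitive"`, `"motor"`, `"dual"`), and `label`.
#' @examples
#' nrow(assessment_conditions())  # 19
#' @export
assessment_conditions <- function() {
  cg <- cognitive_tasks()
  mt <- motor_tasks()
  single_cog <- data.frame(cognitive = cg, motor = NA_character_,
                           block = "cognitive", stringsAsFactors = FALSE)
  single_mot <- data.frame(cognitive = NA_character_, motor = mt,
                           block = "motor", stringsAsFactors = FALSE)
  dual <- expand.grid(cognitive = cg, motor = mt,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dual$block <- "dual"
  out <- rbind(single_cog, single_mot, dual)
  out$label <- ifelse(
    is.na(out$motor), out$cognitive,
    ifelse(is.na(out$cognitive), out$motor,
           paste(out$cognitive, out$motor, sep = "+"))
  )
  rownames(out) <- NULL
  out
}

#' Build a patient's assessment battery in reproducible order
#'
#' The condition order is randomized once per patient and then kept fixed:
#' the shuffle is seeded from a stable hash of `patient_code`, so repeated
#' calls (and retests) yield the identical order. Both the order of the
#' three blocks (cognitive-only, motor-only, dual) and the order within
#' each block are randomized. A subset battery preserves the patient's
#' full-battery relative order.
#'
#' @param patient A `dt_patient`, or a patient code string.
#' @param subset One of `"full"`, `"cognitive"`, `"motor"`, `"dual"`, or a
#'   character vector of those block names.
#' @return Data frame of conditions (see [assessment_conditions()]) in the
#'   patient's administration order, with a `position` column.
#' @examples
#' b <- build_battery("P001")
#' nrow(b)                                 # 19
#' identical(b, build_battery("P001"))     # TRUE: per-patient determinism
#' @export
build_battery <- function(patient, subset = "full") {
  code <- if (inherits(patient, "dt_patient")) patient$patient_code
          else as.character(patient)
  if (length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop("patient must be a dt_patient or a non-empty code string",
         call. = FALSE)
  }
  blocks <- if (identical(subset, "full")) c("cognitive", "motor", "dual")
            else unique(subset)
  if (length(blocks) == 0L ||
      !all(blocks %in% c("cognitive", "motor", "dual"))) {
    stop("subset must be 'full' or blocks from cognitive/motor/dual",
         call. = FALSE)
  }
  cond <- assessment_conditions()
  ord <- withr::with_seed(stable_hash(code), {
    block_order <- sample(c("cognitive", "motor", "dual"))
    idx <- integer(0)
    for (b in block_order) {
      in_block <- which(cond$block == b)
      idx <- c(idx, in_block[sample.int(length(in_block))])
    }
    idx
  })
  out <- cond[ord, , drop = FALSE]
  out <- out[out$block %in% blocks, , drop = FALSE]
  out$position <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Run an assessment battery with a responder
#'
#' Administers each condition of a battery for a fixed 60-second trial and
#' scores it. Cognitive answers come from a responder object; step counts
#' for conditions with a motor component come from a steps provider. The
#' engine does not enforce real-time pacing; item counts per trial reflect
#' the task's nominal delivery rate (one vigilance sequence of 24 letters
#' fills the 60 s exactly).
#'
#' @param battery Data frame from [build_battery()].
#' @param responder A responder as returned by [make_responder()] or
#'   [scripted_responder()]: a list providing `digit_response(presented)`,
#'   `vigilance_yes(sequence)`, and `serial7_responses(start)`.
#' @param steps_provider Function `f(condition_row)` returning a
#'   non-negative step count for the 60-s trial. Required (and consulted)
#'   only for conditions with a motor component; a missing or `NA` step
#'   count raises an incomplete-trial error, because the therapist must
#'   enter the number of steps before a trial can be stored.
#' @param span_length Digit string length used in the digit span trials
#'   (defaults to 5 when the patient's titrated span is unknown).
#' @param n_digit_trials Number of digit strings presented in a 60-s digit
#'   span condition (default 5).
#' @return Data frame of trial results: one row per condition with
#'   `n_correct`, `n_incorrect`, `n_skipped`, `steps` (`NA` for
#'   cognitive-only conditions), and `duration_s` (always 60).
#' @export
run_assessment <- function(battery, responder, steps_provider = NULL,
                           span_length = 5L, n_digit_trials = 5L) {
  stopifnot(is.data.frame(battery), nrow(battery) >= 1L)
  span_length <- check_int_range(span_length, 1L, 9L, "span_length")
  rows <- vector("list", nrow(battery))
  for (i in seq_len(nrow(battery))) {
    cnd <- battery[i, , drop = FALSE]
    counts <- c(n_correct = 0L, n_incorrect = 0L, n_skipped = 0L)
    if (!is.na(cnd$cognitive)) {
      counts <- administer_cognitive(cnd$cognitive, responder,
                                     span_length, n_digit_trials)
    }
    steps <- NA_integer_
    if (!is.na(cnd$motor)) {
      if (is.null(steps_provider)) {
        stop("incomplete trial: no steps provider for motor condition '",
             cnd$label, "'", call. = FALSE)
      }
      steps <- steps_provider(cnd)
      if (is.null(steps) || length(steps) != 1L || is.na(steps) || steps < 0) {
        stop("incomplete trial: missing step count for condition '",
             cnd$label, "'", call. = FALSE)
      }
      steps <- as.integer(round(steps))
    }
    rows[[i]] <- data.frame(
      cognitive = cnd$cognitive, motor = cnd$motor, block = cnd$block,
      label = cnd$label,
      n_correct = counts[["n_correct"]],
      n_incorrect = counts[["n_incorrect"]],
      n_skipped = counts[["n_skipped"]],
      steps = steps, duration_s = ASSESSMENT_DURATION_S,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Administer one cognitive task for a single 60-s condition and return
# correct/incorrect/skipped counts.
administer_cognitive <- function(task, responder, span_length,
                                 n_digit_trials) {
  if (task == "DIGIT_SPAN_BACKWARDS") {
    n_ok <- 0L
    for (k in seq_len(n_digit_trials)) {
      presented <- generate_digit_string(span_length)
      resp <- responder$digit_response(presented)
      if (score_digit_span(presented, resp)) n_ok <- n_ok + 1L
    }
    c(n_correct = n_ok, n_incorrect = n_digit_trials - n_ok, n_skipped = 0L)
  } else if (task == "AUDITORY_VIGILANCE") {
    seqn <- generate_vigilance_sequence(responder$target_letters %||%
                                          c("K", "Z"))
    sc <- score_vigilance(seqn, responder$vigilance_yes(seqn))
    # false positives and omissions both count as incorrect
    c(n_correct = sc[["hits"]],
      n_incorrect = sc[["false_positives"]] + sc[["omissions"]],
      n_skipped = 0L)
  } else if (task == "SERIAL_SUBTRACTION_7") {
    start <- generate_serial7_start()
    sc <- score_serial7(start, responder$serial7_responses(start))
    c(n_correct = sc[["n_correct"]], n_incorrect = sc[["n_errors"]],
      n_skipped = 0L)
  } else {
    stop("unknown cognitive task: ", task, call. = FALSE)
  }
}
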