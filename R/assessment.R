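#' Cognitive and motor task enumerations
#'
#' The assessment battery crosses three cognitive tasks (titrated backwards
#' digit span, auditory vigilance with letters, serial subtraction by 7)
#' with four walking tasks (plain walking, walking while carrying a cup,
#' walking over obstacles, walking crisscross between cones).
#'
#' @return Character vector of task identifiers.
#' @examples
#' cognitive_tasks()
#' motor_tasks()
#' @export
cognitive_tasks <- function() {
  c("DIGIT_SPAN_BACKWARDS", "AUDITORY_VIGILANCE", "SERIAL_SUBTRACTION_7")
}

#' @rdname cognitive_tasks
#' @export
motor_tasks <- function() {
  c("WALK", "WALK_CUP", "WALK_OBSTACLES", "WALK_CRISSCROSS")
}

# Fixed trial duration in seconds for every assessment condition.
ASSESSMENT_DURATION_S <- 60

#' Generate a digit string for the backwards digit span task
#'
#' Draws `length` digits by ordered sampling without replacement from 1-9,
#' so all digits in a string are distinct and every ordered sample of the
#' given length is equally likely (for length 3 there are 9*8*7 = 504
#' possible strings). Digits are presented to the patient at one per
#' second; pacing is metadata only, the engine does not play audio.
#'
#' @param length Number of digits, between 1 and 9.
#' @return Integer vector of distinct digits in 1-9.
#' @examples
#' set.seed(1)
#' generate_digit_string(3)
#' @export
generate_digit_string <- function(length) {
  length <- check_int_range(length, 1L, 9L, "length")
  sample(1:9, size = length, replace = FALSE)
}

#' Score one backwards digit span trial
#'
#' The patient must repeat the presented string in exactly reversed order.
#' A response of the wrong length is simply incorrect, not an error.
#'
#' @param presented Integer vector, the presented digits (non-empty).
#' @param response Integer vector, the patient's response.
#' @return `TRUE` if `response` equals `rev(presented)`, else `FALSE`.
#' @examples
#' score_digit_span(c(3, 2, 5, 7, 9), c(9, 7, 5, 2, 3))  # TRUE
#' score_digit_span(c(3, 2, 5, 7, 9), c(3, 2, 5, 7, 9))  # FALSE
#' @export
score_digit_span <- function(presented, response) {
  if (length(presented) == 0L) {
    stop("presented string must be non-empty", call. = FALSE)
  }
  length(response) == length(presented) &&
    all(as.integer(response) == rev(as.integer(presented)))
}

#' Titrate the backwards digit span length
#'
#' Runs the adaptive staircase that determines a patient's individual span:
#' starting at a string length of three digits, four trials are
#' administered per length; a length is passed when at least three of the
#' four trials are correct, in which case the length increases by one. The
#' procedure stops at the first failed length (or after passing length 9,
#' the longest string of distinct digits 1-9). The reported span is the
#' largest passed length. If length 3 itself is failed no numeric span
#' exists and `below_floor` is set.
#'
#' @param responder A function `f(presented)` returning the patient's
#'   response as an integer vector. An error raised by the responder aborts
#'   the titration; the partial trial log is attached to the condition.
#' @param start_length First string length (default 3).
#' @param trials_per_length Trials administered per length (default 4).
#' @param pass_threshold Correct trials required to pass a length
#'   (default 3).
#' @return A list with elements `span` (integer or `NA`), `below_floor`
#'   (logical), and `log` (data frame of every trial: length, presented and
#'   response strings, correct flag).
#' @examples
#' perfect <- function(presented) rev(presented)
#' set.seed(7)
#' titrate_span(perfect)$span  # 9: passes every length
#' @export
titrate_span <- function(responder, start_length = 3L,
                         trials_per_length = 4L, pass_threshold = 3L) {
  stopifnot(is.function(responder))
  start_length <- check_int_range(start_length, 1L, 9L, "start_length")
  log <- list()
  len <- start_length
  last_passed <- NA_integer_
  repeat {
    n_correct <- 0L
    for (trial in seq_len(trials_per_length)) {
      presented <- generate_digit_string(len)
      response <- tryCatch(responder(presented), error = function(e) {
        cond <- simpleError(paste0("titration aborted by responder: ",
                                   conditionMessage(e)))
        cond$partial_log <- do.call(rbind, log)
        class(cond) <- c("dt_aborted_titration", class(cond))
        stop(cond)
      })
      ok <- score_digit_span(presented, response)
      log[[length(log) + 1L]] <- data.frame(
        length = len, trial = trial,
        presented = paste(presented, collapse = "-"),
        response = paste(response, collapse = "-"),
        correct = ok, stringsAsFactors = FALSE
      )
      if (ok) n_correct <- n_correct + 1L
    }
    if (n_correct >= pass_threshold) {
      last_passed <- len
      if (len == 9L) break  # cannot extend beyond the nine distinct digits
      len <- len + 1L
    } else {
      break
    }
  }
  list(
    span = last_passed,
    below_floor = is.na(last_passed),
    log = do.call(rbind, log)
  )
}

#' Generate an auditory vigilance letter sequence
#'
#' Builds the 60-second vigilance stream: 24 letters of which exactly 10
#' are occurrences of the two target letters. Construction mirrors the
#' task's two-stage routine: first 14 non-target letters are drawn with
#' replacement from the alphabet minus the targets, then the 14 non-targets
#' and 10 targets are interleaved by a uniform shuffle. Target identities
#' within the 10 target slots are drawn uniformly from the two targets.
#' Letters are delivered at one per 2.5 s (24 x 2.5 s = 60 s); pacing is
#' metadata, not enforced.
#'
#' @param target_letters Character vector of exactly 2 distinct letters,
#'   both present in `alphabet`. Target letters are locale-specific and are
#'   therefore always supplied by the caller (or the engine config).
#' @param alphabet Character vector of at least 3 distinct letters
#'   (default `LETTERS`).
#' @return A list of class `dt_vigilance` with `letters` (length 24),
#'   `target_letters`, and `target_positions` (the 10 indices, 1-based).
#' @examples
#' set.seed(2)
#' seq <- generate_vigilance_sequence(c("K", "Z"))
#' length(seq$letters)            # 24
#' length(seq$target_positions)   # 10
#' @export
generate_vigilance_sequence <- function(target_letters, alphabet = LETTERS) {
  alphabet <- unique(as.character(alphabet))
  target_letters <- as.character(target_letters)
  if (length(target_letters) != 2L ||
      anyDuplicated(target_letters) ||
      !all(target_letters %in% alphabet)) {
    stop("target_letters must be 2 distinct letters contained in alphabet",
         call. = FALSE)
  }
  if (length(alphabet) < 3L) {
    stop("alphabet must contain at least 3 letters", call. = FALSE)
  }
  pool <- setdiff(alphabet, target_letters)
  nontargets <- sample(pool, 14L, replace = TRUE)
  targets <- sample(target_letters, 10L, replace = TRUE)
  positions <- sample.int(24L)
  letters_out <- character(24L)
  target_positions <- sort(positions[1:10])
  letters_out[positions[1:10]] <- targets
  letters_out[positions[11:24]] <- nontargets
  structure(
    list(letters = letters_out,
         target_letters = target_letters,
         target_positions = target_positions),
    class = "dt_vigilance"
  )
}

#' Score an auditory vigilance trial
#'
#' The patient says "yes" whenever a target letter is heard. Hits are yes
#' responses at target positions; false positives are yes responses at
#' non-target positions; omissions are the missed targets. False positives
#' and omissions both count as incorrect.
#'
#' @param sequence A `dt_vigilance` object.
#' @param yes_indices Integer vector of 1-based positions (within 1..24) at
#'   which the patient responded "yes". Duplicates are ignored.
#' @return Named integer vector `c(hits, false_positives, omissions)`.
#' @examples
#' set.seed(3)
#' s <- generate_vigilance_sequence(c("K", "Z"))
#' score_vigilance(s, s$target_positions)  # 10 hits, 0 FP, 0 omissions
#' @export
score_vigilance <- function(sequence, yes_indices = integer()) {
  stopifnot(inherits(sequence, "dt_vigilance"))
  yes_indices <- unique(as.integer(yes_indices))
  if (length(yes_indices) &&
      (any(is.na(yes_indices)) || any(yes_indices < 1L | yes_indices > 24L))) {
    stop("yes_indices must lie in 1..24", call. = FALSE)
  }
  hits <- length(intersect(yes_indices, sequence$target_positions))
  fp <- length(setdiff(yes_indices, sequence$target_positions))
  c(hits = hits, false_positives = fp,
    omissions = length(sequence$target_positions) - hits)
}

#' Draw a starting number for serial subtraction by 7
#'
#' Uniform integer in 101-199, as the task samples a fresh start value at
#' each measurement time point.
#'
#' @return Integer in `[101, 199]`.
#' @examples
#' set.seed(4)
#' generate_serial7_start()
#' @export
generate_serial7_start <- function() {
  sample(101:199, 1L)
}

#' Score serial subtraction by 7 with carry-forward
#'
#' Each response is compared against the previous accepted value minus 7.
#' After every response -- correct or not -- the reference moves to that
#' response, so a single slip is counted as one mistake and correct
#' continuations from the erroneous value are considered accurate (e.g.
#' from 101: 95, 88, 81 scores one error and two correct).
#'
#' @param start Starting integer.
#' @param responses Integer vector of the patient's successive responses
#'   (may be empty).
#' @return Named integer vector `c(n_correct, n_errors)`.
#' @examples
#' score_serial7(101, c(94, 87))      # 2 correct, 0 errors
#' score_serial7(101, c(95, 88, 81))  # 2 correct, 1 error
#' @export
score_serial7 <- function(start, responses = integer()) {
  stopifnot(is.numeric(start), length(start) == 1L, !is.na(start))
  responses <- as.integer(responses)
  ref <- as.integer(start)
  n_correct <- 0L
  for (r in responses) {
    if (!is.na(r) && !is.na(ref) && r == ref - 7L) n_correct <- n_correct + 1L
    ref <- r
  }
  c(n_correct = n_correct, n_errors = length(responses) - n_correct)
}
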