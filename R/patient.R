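#' Create a patient profile
#'
#' A patient profile carries the identifiers and baseline step cadences the
#' engine needs to administer assessments and training sessions: the
#' therapist enters the patient's baseline steps per minute for free walking
#' and for stepping on the spot, and (once titrated) the patient's backwards
#' digit span length.
#'
#' @param patient_code Non-empty string uniquely identifying the patient.
#'   The assessment battery order is derived deterministically from this
#'   code, so the same patient always receives the same condition order.
#' @param therapist_code Optional string identifying the therapist.
#' @param baseline_steps_walking Baseline cadence while walking, in steps
#'   per minute (> 0), or `NA` if not yet measured.
#' @param baseline_steps_stepping Baseline cadence while stepping on the
#'   spot, in steps per minute (> 0), or `NA`.
#' @param span_length Titrated backwards digit span length (integer in
#'   3..9), or `NA` if not yet titrated.
#' @param notes Free-text notes.
#'
#' @return An object of class `dt_patient` (a named list).
#' @examples
#' p <- patient_profile("P001", baseline_steps_walking = 110,
#'                      baseline_steps_stepping = 95)
#' p$patient_code
#' @export
patient_profile <- function(patient_code,
                            therapist_code = NA_character_,
                            baseline_steps_walking = NA_real_,
                            baseline_steps_stepping = NA_real_,
                            span_length = NA_integer_,
                            notes = "") {
  if (!is.character(patient_code) || length(patient_code) != 1L ||
      is.na(patient_code) || !nzchar(patient_code)) {
    stop("patient_code must be a non-empty string", call. = FALSE)
  }
  for (nm in c("baseline_steps_walking", "baseline_steps_stepping")) {
    v <- get(nm)
    if (!is.na(v) && (!is.numeric(v) || v <= 0)) {
      stop(nm, " must be > 0 when set", call. = FALSE)
    }
  }
  if (!is.na(span_length)) {
    span_length <- check_int_range(span_length, 1L, 9L, "span_length")
  }
  structure(
    list(
      patient_code = patient_code,
      therapist_code = as.character(therapist_code),
      baseline_steps_walking = as.numeric(baseline_steps_walking),
      baseline_steps_stepping = as.numeric(baseline_steps_stepping),
      span_length = as.integer(span_length),
      notes = notes
    ),
    class = "dt_patient"
  )
}

#' @export
print.dt_patient <- function(x, ...) {
  cat("<dt_patient>", x$patient_code, "\n")
  cat("  baseline walking:  ", x$baseline_steps_walking, "steps/min\n")
  cat("  baseline stepping: ", x$baseline_steps_stepping, "steps/min\n")
  cat("  span length:       ",
      if (is.na(x$span_length)) "not titrated" else x$span_length, "\n")
  invisible(x)
}
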