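SESSION_LOG_SCHEMA <- "1.0"

#' Create, extend, persist and load session logs
#'
#' A session log is the engine's append-only record for one patient:
#' assessment trials, exercise results, feedback reports, progression
#' transitions, RPE entries and free-text notes, each as a typed,
#' timestamped event. Logs are schema-versioned JSON documents; the
#' realized battery order is stored explicitly so a change to the hashing
#' scheme can never silently reorder a patient's retest.
#'
#' @param patient A `dt_patient` or patient code.
#' @return `session_log()`: a `dt_session_log`.
#' @examples
#' log <- session_log("P001")
#' log <- log_event(log, "note", list(text = "baseline day"),
#'                  timestamp = "2026-01-05T10:00:00Z")
#' @export
session_log <- function(patient) {
  code <- if (inherits(patient, "dt_patient")) patient$patient_code
          else as.character(patient)
  structure(
    list(schema_version = SESSION_LOG_SCHEMA,
         patient_code = code,
         battery_order = build_battery(code)$label,
         events = list()),
    class = "dt_session_log"
  )
}

#' @rdname session_log
#' @param log A `dt_session_log`.
#' @param type Event type: one of `"assessment_trial"`, `"exercise"`,
#'   `"feedback"`, `"progression"`, `"rpe"`, `"note"`.
#' @param data Named list payload (must be JSON-serializable).
#' @param timestamp ISO-8601 string; injectable so tests and batch runs
#'   are deterministic. Defaults to the current time.
#' @export
log_event <- function(log, type, data, timestamp = NULL) {
  stopifnot(inherits(log, "dt_session_log"))
  type <- match.arg(type, c("assessment_trial", "exercise", "feedback",
                            "progression", "rpe", "note"))
  log$events[[length(log$events) + 1L]] <- list(
    type = type,
    timestamp = timestamp %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
    data = data
  )
  log
}

#' @rdname session_log
#' @param path File path for the JSON document.
#' @export
save_session_log <- function(log, path) {
  stopifnot(inherits(log, "dt_session_log"))
  jsonlite::write_json(unclass(log), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname session_log
#' @export
load_session_log <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::read_json(path),
    error = function(e) stop("parse error in session log '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ver <- raw$schema_version
  if (is.null(ver) || !identical(as.character(ver), SESSION_LOG_SCHEMA)) {
    stop("unsupported session-log schema version '", ver %||% "<none>",
         "' (this build reads ", SESSION_LOG_SCHEMA,
         "; migrate the file first)", call. = FALSE)
  }
  structure(
    list(schema_version = as.character(ver),
         patient_code = raw$patient_code,
         battery_order = as.character(unlist(raw$battery_order)),
         events = raw$events),
    class = "dt_session_log"
  )
}

#' Export tabular views of a session log or program trace
#'
#' Writes one CSV row per record with a stable column order and
#' locale-independent (dot-decimal) formatting.
#'
#' @param x A `dt_program_trace` (or a trial-result data frame for
#'   `kind = "trials"` / `"dtc"`).
#' @param kind One of `"trials"` (assessment trial results), `"exercises"`
#'   (per-exercise training rows), `"dtc"` (dual-task cost pairs),
#'   `"outcomes"` (per-session RPE plus adherence).
#' @param path Output CSV path.
#' @return The exported data frame, invisibly.
#' @export
export_csv <- function(x, kind = c("trials", "exercises", "dtc",
                                   "outcomes"), path) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("usage error: unknown export ",
                                            "kind", call. = FALSE))
  df <- if (inherits(x, "dt_program_trace")) {
    switch(kind,
           trials = x$pre_assessment$trials,
           exercises = x$progression,
           dtc = x$pre_assessment$dtc,
           outcomes = {
             out <- x$rpe
             out$adherence_pct <- x$adherence_pct
             out
           })
  } else {
    switch(kind,
           trials = x,
           dtc = dtc_matrix(x),
           stop("usage error: ", kind, " export needs a program trace",
                call. = FALSE))
  }
  if (is.null(df)) df <- data.frame()
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
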