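#' Engine configuration
#'
#' Bundles the tunables of a deployment: locale tag, the locale-specific
#' vigilance target letters, the level-up/level-down thresholds (70% and
#' 50% by default, matching the green and red feedback lines), and the
#' program schedule (20 sessions, five cognitive functions per session, 30
#' dual-task minutes per session).
#'
#' @param locale BCP-47-ish locale tag (used to label the deployment; no
#'   translations ship with the engine).
#' @param target_letters Two vigilance target letters for the locale.
#' @param threshold_up,threshold_down Percent thresholds; `threshold_up`
#'   must exceed `threshold_down`, both in `(0, 100]`.
#' @param sessions Scheduled training sessions (> 0).
#' @param functions_per_session Cognitive functions trained per session.
#' @param dtt_minutes Dual-task training minutes per session.
#' @param bank_dir Optional item-bank directory.
#' @return A list of class `dt_config`.
#' @examples
#' cfg <- engine_config()
#' cfg$threshold_up
#' @export
engine_config <- function(locale = "en", target_letters = c("K", "Z"),
                          threshold_up = 70, threshold_down = 50,
                          sessions = 20L, functions_per_session = 5L,
                          dtt_minutes = 30, bank_dir = NULL) {
  if (!is.numeric(threshold_up) || !is.numeric(threshold_down) ||
      threshold_up <= 0 || threshold_up > 100 ||
      threshold_down <= 0 || threshold_down > 100 ||
      threshold_up <= threshold_down) {
    stop("thresholds must satisfy 0 < down < up <= 100", call. = FALSE)
  }
  sessions <- check_int_range(sessions, 1L, 1000L, "sessions")
  functions_per_session <- check_int_range(
    functions_per_session, 1L, length(cognitive_functions()),
    "functions_per_session")
  if (length(target_letters) != 2L) {
    stop("target_letters must be exactly 2 letters", call. = FALSE)
  }
  structure(
    list(locale = locale, target_letters = as.character(target_letters),
         threshold_up = threshold_up, threshold_down = threshold_down,
         sessions = sessions,
         functions_per_session = functions_per_session,
         dtt_minutes = dtt_minutes, bank_dir = bank_dir),
    class = "dt_config"
  )
}

#' @rdname engine_config
#' @param path YAML file.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(engine_config, raw)
}

#' @rdname engine_config
#' @param config A `dt_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "dt_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
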