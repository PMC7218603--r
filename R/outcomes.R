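#' Program adherence
#'
#' Adherence is the number of completed training sessions expressed as a
#' percentage of the scheduled sessions (20 for the standard program). For
#' a cohort, the summary is the mean of the per-patient percentages.
#'
#' @param completed_sessions Completed session count(s); a vector is
#'   treated as one patient per element.
#' @param scheduled Scheduled sessions (default 20).
#' @return For a single count, the adherence percent; for a vector, a list
#'   with `per_patient` percents and their `mean`.
#' @examples
#' compute_adherence(16)          # 80
#' compute_adherence(c(20, 16))$mean
#' @export
compute_adherence <- function(completed_sessions, scheduled = 20L) {
  if (!is.numeric(scheduled) || scheduled <= 0) {
    stop("scheduled must be > 0", call. = FALSE)
  }
  if (any(is.na(completed_sessions)) || any(completed_sessions < 0) ||
      any(completed_sessions > scheduled)) {
    stop("invalid record: completed_sessions must lie in [0, scheduled]",
         call. = FALSE)
  }
  pct <- completed_sessions / scheduled * 100
  if (length(pct) == 1L) pct else list(per_patient = pct, mean = mean(pct))
}

#' Record and summarize Borg RPE ratings
#'
#' Perceived exertion is rated after each training session on the Borg
#' 15-point RPE scale, an integer from 6 ("no exertion at all") to 20
#' ("maximal exertion").
#'
#' @param session_index Session number (1-based).
#' @param score Integer RPE in 6-20.
#' @return `rpe_record()`: a one-row data frame. `summarize_rpe()`: list
#'   with `mean`, `sd`, `n`.
#' @examples
#' summarize_rpe(rbind(rpe_record(1, 8), rpe_record(2, 18)))$mean  # 13
#' @export
rpe_record <- function(session_index, score) {
  session_index <- check_int_range(session_index, 1L, 1000L,
                                   "session_index")
  score <- tryCatch(check_int_range(score, 6L, 20L, "RPE score"),
                    error = function(e) stop(
                      "invalid record: RPE score must be an integer in ",
                      "[6, 20]", call. = FALSE))
  data.frame(session_index = session_index, score = score)
}

#' @rdname rpe_record
#' @param records Data frame with a `score` column (rows from
#'   `rpe_record()`), possibly across patients for a cohort summary.
#' @export
summarize_rpe <- function(records) {
  stopifnot(is.data.frame(records), "score" %in% names(records))
  s <- records$score
  if (length(s) == 0L) return(list(mean = NA_real_, sd = NA_real_, n = 0L))
  if (any(is.na(s)) || any(s < 6 | s > 20) || any(s != round(s))) {
    stop("invalid record: RPE scores must be integers in [6, 20]",
         call. = FALSE)
  }
  list(mean = mean(s), sd = stats::sd(s), n = length(s))
}

#' The 30-item Intrinsic Motivation Inventory instrument
#'
#' Six subscales over 30 seven-point items: interest/enjoyment (5 items,
#' score range 5-35), perceived competence (5, 5-35), effort/importance
#' (5, 5-35), pressure/tension (5, 5-35), value/usefulness (6, 6-42), and
#' perceived choice (4, 4-28). Several items are reverse-worded; their
#' item score is 8 minus the response. The subscale sizes constrain but do
#' not fully determine the item-to-subscale mapping, so the mapping ships
#' as data and can be replaced by a custom instrument file with the same
#' columns.
#'
#' @return Data frame with columns `item` (1-30), `subscale`, `reverse`.
#' @examples
#' table(imi_instrument()$subscale)
#' @export
imi_instrument <- function() {
  data.frame(
    item = 1:30,
    subscale = rep(c("interest_enjoyment", "perceived_competence",
                     "effort_importance", "pressure_tension",
                     "value_usefulness", "perceived_choice"),
                   times = c(5L, 5L, 5L, 5L, 6L, 4L)),
    reverse = c(
      FALSE, FALSE, TRUE,  FALSE, FALSE,   # interest/enjoyment
      FALSE, FALSE, FALSE, TRUE,  FALSE,   # perceived competence
      FALSE, TRUE,  FALSE, FALSE, FALSE,   # effort/importance
      TRUE,  TRUE,  FALSE, FALSE, FALSE,   # pressure/tension
      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,  # value/usefulness
      TRUE,  TRUE,  FALSE, TRUE             # perceived choice
    ),
    stringsAsFactors = FALSE
  )
}

#' Read an instrument definition from a TSV file
#'
#' @param path TSV with columns `item`, `subscale`, `reverse`.
#' @return Instrument data frame as from [imi_instrument()].
#' @export
read_imi_instrument <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("item", "subscale", "reverse")
  if (!all(need %in% names(df))) {
    stop("instrument file must have columns item, subscale, reverse",
         call. = FALSE)
  }
  df$reverse <- as.logical(df$reverse)
  df[order(df$item), need]
}

#' Score the Intrinsic Motivation Inventory
#'
#' Responses are on a 1-7 scale ("not at all true" to "very true").
#' Reverse items are scored as 8 minus the response; all other items
#' verbatim. Each subscale score is the sum of its item scores; higher
#' scores indicate a more positive subjective experience.
#'
#' @param responses Numeric vector of 30 responses in 1-7, ordered by item
#'   number (or named `item1`...`item30`).
#' @param instrument Instrument definition (default [imi_instrument()]).
#' @return Named numeric vector of the six subscale scores.
#' @examples
#' score_imi(rep(4, 30))  # every subscale at its midpoint
#' @export
score_imi <- function(responses, instrument = imi_instrument()) {
  n <- nrow(instrument)
  if (length(responses) != n) {
    stop("invalid response: expected ", n, " responses, got ",
         length(responses), call. = FALSE)
  }
  bad <- which(is.na(responses) | responses < 1 | responses > 7 |
                 responses != round(responses))
  if (length(bad)) {
    stop("invalid response at item(s) ",
         paste(instrument$item[bad], collapse = ", "),
         ": responses must be integers in 1-7", call. = FALSE)
  }
  item_scores <- ifelse(instrument$reverse, 8 - responses, responses)
  sums <- tapply(item_scores, instrument$subscale, sum)
  subs <- unique(instrument$subscale)
  setNames(as.numeric(sums[subs]), subs)
}
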