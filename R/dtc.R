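#' Dual-task cost of a performance measure
#'
#' Performance in a motor or cognitive task typically decreases under dual
#' tasking relative to single tasking; the dual-task cost (DTC) expresses
#' that decrement as a percentage of the single-task value:
#' `DTC% = (single - dual) / single * 100`, for higher-is-better measures
#' (steps per minute, correct answers per minute). Positive values are a
#' cost; negative values a dual-task benefit.
#'
#' @param single_value Single-task performance (> 0).
#' @param dual_value Dual-task performance on the same scale.
#' @return DTC in percent.
#' @examples
#' compute_dtc(100, 80)   # 20
#' compute_dtc(100, 110)  # -10: dual-task benefit
#' @export
compute_dtc <- function(single_value, dual_value) {
  if (!is.numeric(single_value) || any(is.na(single_value)) ||
      any(single_value <= 0)) {
    stop("undefined baseline: single_value must be > 0", call. = FALSE)
  }
  (single_value - dual_value) / single_value * 100
}

#' Dual-task cost matrix from a completed assessment
#'
#' For every (cognitive, motor) pair with a dual trial and both single
#' baselines available, computes the motor DTC from step cadence
#' (steps per minute) and the cognitive DTC from correct answers per
#' minute. Pairs with a missing single baseline or missing dual trial are
#' omitted and listed in the `missing` attribute rather than treated as an
#' error. A complete 19-condition assessment yields 12 pairs.
#'
#' @param results Trial-result data frame from [run_assessment()].
#' @return Data frame with one row per available pair: `cognitive`,
#'   `motor`, `motor_dtc_percent`, `cognitive_dtc_percent`. Attribute
#'   `missing` holds labels of omitted pairs.
#' @export
dtc_matrix <- function(results) {
  stopifnot(is.data.frame(results))
  rate <- function(x, dur) x * 60 / dur
  single_cog <- results[results$block == "cognitive", , drop = FALSE]
  single_mot <- results[results$block == "motor", , drop = FALSE]
  dual <- results[results$block == "dual", , drop = FALSE]
  out <- list()
  missing <- character(0)
  for (cg in cognitive_tasks()) {
    for (mt in motor_tasks()) {
      d <- dual[!is.na(dual$cognitive) & dual$cognitive == cg &
                  !is.na(dual$motor) & dual$motor == mt, , drop = FALSE]
      sc <- single_cog[single_cog$cognitive == cg, , drop = FALSE]
      sm <- single_mot[single_mot$motor == mt, , drop = FALSE]
      lbl <- paste(cg, mt, sep = "+")
      if (nrow(d) < 1L || nrow(sc) < 1L || nrow(sm) < 1L) {
        missing <- c(missing, lbl)
        next
      }
      d <- d[1L, ]; sc <- sc[1L, ]; sm <- sm[1L, ]
      single_steps <- rate(sm$steps, sm$duration_s)
      dual_steps <- rate(d$steps, d$duration_s)
      single_rate <- rate(sc$n_correct, sc$duration_s)
      motor_dtc <- if (single_steps > 0) {
        compute_dtc(single_steps, dual_steps)
      } else NA_real_
      cog_dtc <- if (single_rate > 0) {
        compute_dtc(single_rate, rate(d$n_correct, d$duration_s))
      } else NA_real_
      if (is.na(motor_dtc) && is.na(cog_dtc)) {
        missing <- c(missing, lbl)
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        cognitive = cg, motor = mt,
        motor_dtc_percent = motor_dtc,
        cognitive_dtc_percent = cog_dtc,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cognitive = character(0), motor = character(0),
               motor_dtc_percent = numeric(0),
               cognitive_dtc_percent = numeric(0))
  rownames(res) <- NULL
  attr(res, "missing") <- missing
  res
}
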