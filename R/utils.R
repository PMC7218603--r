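#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-patient randomization seeds from patient codes so that
# a patient's battery order is stable across sessions and machines. Base R
# only; result is always a valid `set.seed()` argument.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Validate a scalar whole number in an inclusive range.
check_int_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < lo || x > hi) {
    stop(sprintf("%s must be a single integer in [%s, %s]", what, lo, hi),
         call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
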