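# Round half away from zero, matching the usual clinical-report convention
# (base round() uses banker's rounding, which prints 0.5 cases "down").
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage of a count over a total, rounded half-up to 2 dp.
as_pct <- function(count, total, digits = 2) {
  round_half_up(100 * count / total, digits)
}

`%na%` <- function(x, y) if (is.null(x) || length(x) == 0 || all(is.na(x))) y else x

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Canonical string normalization used for drug names and symptom terms:
# lower case, trimmed, internal whitespace collapsed.
normalize_term <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}
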