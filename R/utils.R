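# Internal helpers shared across modules.

# Half-up (away from zero) rounding; base round() is round-half-even, which
# would print 19.05 -> 19.0 where the field convention prints 19.1.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  trunc(x * p + 0.5 * sign(x)) / p
}

# Canonical form used for case-insensitive, whitespace-normalized level
# matching of questionnaire exports.
norm_label <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

# Match raw values against a set of canonical levels; returns canonical
# labels, NA where the input is missing. Unmatched values raise with row and
# column context.
match_levels <- function(x, levels, column = "<unknown>") {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  idx <- match(norm_label(x[ok]), norm_label(levels))
  bad <- which(ok)[is.na(idx)]
  if (length(bad) > 0) {
    stop(sprintf(
      "invalid level in column '%s', row %d: '%s' (expected one of: %s)",
      column, bad[1], x[bad[1]], paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  out[ok] <- levels[idx]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Affirmative/negative coding used by all yes/no questionnaire items.
yn_to_logical <- function(x) {
  out <- rep(NA, length(x))
  out[norm_label(x) == "yes"] <- TRUE
  out[norm_label(x) == "no"] <- FALSE
  out
}
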