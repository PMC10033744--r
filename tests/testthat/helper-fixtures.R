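# Shared fixture builders and independent oracles used across the suite.

freq_levels <- c(
  "never or only occasionally",
  "once or twice per week",
  "most or all days per week"
)

# Minimal hand-built cohort data.frame covering the classification rules.
make_tiny_cohort <- function() {
  as_cohort(data.frame(
    subject_id = c("a", "b", "c", "d", "e"),
    gender = c("female", "male", "female", "male", "female"),
    ever_asthma = c("yes", "yes", "no", "yes", NA),
    wheeze_12m = c("yes", "no", "yes", NA, "no"),
    exercise_wheeze_12m = c("yes", "no", "yes", NA, "no"),
    dry_night_cough_12m = c("no", "no", "no", NA, "no"),
    exacerbation_12m = c("no", "no", "no", NA, "no"),
    spt_blo_mm = c(4, 2.9, NA, 3, 0),
    spt_der_mm = c(0, 2.9, NA, NA, 0),
    spt_hist_mm = c(5, 5, 5, 5, 5),
    spt_saline_mm = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  ))
}

# Independent naive diet-score oracle: straight lookup-and-sum, sharing no
# code with compute_qdgis().
naive_qdgis <- function(freqs) {
  w <- c("never or only occasionally" = 0, "once or twice per week" = 2,
         "most or all days per week" = 7)
  high <- c("fastfood", "cereals", "rice", "potatoes")
  low <- c("fruits", "vegetables", "pulses", "nuts", "milk", "probiotic")
  s <- 0
  for (f in names(freqs)) {
    if (is.na(freqs[[f]])) return(NA_integer_)
    if (f %in% high) s <- s - w[[freqs[[f]]]]
    else if (f %in% low) s <- s + w[[freqs[[f]]]]
  }
  as.integer(s)
}

# Build a diet-only data.frame from a named list of frequencies over the ten
# scored foods.
scored_foods <- c("fastfood", "cereals", "rice", "potatoes",
                  "fruits", "vegetables", "pulses", "nuts", "milk", "probiotic")

diet_row <- function(...) {
  freqs <- list(...)
  out <- as.list(stats::setNames(rep(freq_levels[1], length(scored_foods)),
                                 paste0("food_", scored_foods)))
  for (f in names(freqs)) out[[paste0("food_", f)]] <- freqs[[f]]
  as.data.frame(out, stringsAsFactors = FALSE)
}

# Cross-product OR pieces computed independently of the package.
naive_or <- function(a, b, c, d) (a * d) / (b * c)

# Extract a level x outcome counts matrix for one exposure from the packaged
# reference counts.
counts_for <- function(exposure, outcome = "ever") {
  x <- diet_asthma_counts(outcome)
  sub <- x[x$exposure == exposure, c("level", "n_no", "n_yes")]
  m <- as.matrix(sub[, c("n_no", "n_yes")])
  rownames(m) <- sub$level
  m
}
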