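test_that("contingency tables tally complete cases with column-wise percentages", {
  m <- counts_for("food_pulses", "ever")
  d <- expand_printed_table(m, exposure = "food_pulses", outcome = "ever_asthma")
  # add rows with missing exposure / outcome to exercise the exclusion logic
  d <- rbind(d,
             data.frame(food_pulses = NA, ever_asthma = c(TRUE, FALSE)),
             data.frame(food_pulses = "never or only occasionally",
                        ever_asthma = NA))
  ct <- build_contingency(d, "food_pulses", "ever_asthma")
  expect_equal(unname(ct$counts[, "n_no"]), c(1397, 3929, 1249))
  expect_equal(unname(ct$counts[, "n_yes"]), c(486, 1097, 447))
  expect_equal(ct$n_missing, 2)       # missing exposure, non-missing outcome
  expect_equal(ct$n_total, 8605)
  # column percentages match the printed table to one decimal
  expect_equal(unname(ct$column_percent[, "n_no"]), c(21.2, 59.8, 19.0))
  expect_equal(unname(ct$column_percent[, "n_yes"]), c(23.9, 54.0, 22.0))
  expect_equal(colSums(ct$column_percent), c(n_no = 100, n_yes = 100),
               tolerance = 0.2)

  # degenerate exposure
  expect_error(
    build_contingency(data.frame(x = "a", y = c(TRUE, FALSE)), "x", "y"),
    "fewer than 2"
  )
})

test_that("contingency counts equal a brute-force tally on random synthetic cohorts", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 1500, seed = 23))
  ph <- phenotype(sim$cohort)
  d <- as.data.frame(sim$cohort)
  d$ever <- ph$ever_asthma
  ct <- build_contingency(d, "food_rice", "ever")
  for (l in ct$levels) {
    keep <- !is.na(d$ever) & !is.na(d$food_rice) & d$food_rice == l
    expect_equal(unname(ct$counts[l, "n_yes"]), sum(d$ever[keep]))
    expect_equal(unname(ct$counts[l, "n_no"]), sum(!d$ever[keep]))
  }
  expect_equal(ct$n_missing, sum(!is.na(d$ever) & is.na(d$food_rice)))
})

test_that("unadjusted odds ratios reproduce printed values and degenerate identities", {
  ct <- build_contingency(
    expand_printed_table(counts_for("food_pulses", "ever"),
                         exposure = "e", outcome = "y"), "e", "y")
  or1 <- unadjusted_or(ct, "once or twice per week")
  expect_equal(round(or1$estimate, 3), 0.803)
  expect_equal(round(or1$ci_low, 3), 0.710)
  expect_equal(round(or1$ci_high, 3), 0.908)
  expect_lt(or1$p_value, 0.001)

  # symmetric table: identity OR with CI containing 1
  sym <- build_contingency(
    expand_printed_table(matrix(c(10, 10, 10, 10), 2, byrow = TRUE,
                                dimnames = list(c("r", "l"), NULL))),
    "exposure", "outcome")
  u <- unadjusted_or(sym, "l")
  expect_equal(u$estimate, 1)
  expect_true(u$ci_low < 1 && u$ci_high > 1)

  expect_error(unadjusted_or(ct, "never or only occasionally"), "reference")
})

test_that("zero cells error unless the Haldane-Anscombe correction is enabled", {
  ct <- build_contingency(
    expand_printed_table(matrix(c(10, 0, 8, 5), 2, byrow = TRUE,
                                dimnames = list(c("r", "l"), NULL))),
    "exposure", "outcome")
  expect_error(unadjusted_or(ct, "l"), "0\\.5")
  u <- unadjusted_or(ct, "l", correction = TRUE)
  expect_equal(u$estimate, (10.5 * 5.5) / (0.5 * 8.5))
})

test_that("exp(single-predictor logistic coefficient) equals the cross-product OR", {
  set.seed(31)
  for (i in 1:10) {
    cells <- sample(5:500, 4)
    m <- matrix(cells, 2, byrow = TRUE, dimnames = list(c("r", "l"), NULL))
    d <- expand_printed_table(m)
    fit <- logit_fit(outcome ~ exposure, d)
    want <- naive_or(cells[1], cells[2], cells[3], cells[4])
    expect_equal(unname(exp(coef(fit)["exposurel"])), want, tolerance = 1e-6)
    # and adjusted_or on the exposure-only fit matches unadjusted_or
    ct <- build_contingency(d, "exposure", "outcome")
    u <- unadjusted_or(ct, "l")
    a <- adjusted_or(fit, "exposure")[[1]]
    expect_equal(a$estimate, u$estimate, tolerance = 1e-6)
    expect_equal(a$ci_low, u$ci_low, tolerance = 1e-4)
    expect_equal(a$p_value, u$p_value, tolerance = 1e-4)
  }
})

test_that("adjusted odds ratios recover a known effect and report the adjustment set", {
  set.seed(77)
  n <- 10000
  d <- data.frame(
    exposure = factor(sample(c("ref", "mid", "hi"), n, TRUE, c(0.5, 0.3, 0.2)),
                      levels = c("ref", "mid", "hi")),
    g = factor(sample(c("f", "m"), n, TRUE), levels = c("f", "m"))
  )
  eta <- -1.2 + log(1.5) * (d$exposure == "mid") + log(0.7) * (d$exposure == "hi") +
    0.4 * (d$g == "m")
  d$y <- runif(n) < plogis(eta)
  fit <- logit_fit(y ~ exposure + g, d)
  aors <- adjusted_or(fit, "exposure")
  mid <- aors[[1]]
  expect_equal(mid$exposure_level, "mid")
  expect_equal(mid$adjusted_for, "g")
  # estimates land within 3 SE of the generating log odds ratios
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(log(mid$estimate) - log(1.5)), 3 * se[["exposuremid"]])
  hi <- aors[[2]]
  expect_lt(abs(log(hi$estimate) - log(0.7)), 3 * se[["exposurehi"]])
})

test_that("relabeling levels permutes results and swapping the outcome inverts every OR", {
  m <- counts_for("food_butter", "ever")
  d <- expand_printed_table(m, exposure = "e", outcome = "y")
  ct <- build_contingency(d, "e", "y")
  ors <- lapply(ct$levels[-1], function(l) unadjusted_or(ct, l))

  # permute the two non-reference rows: same values, swapped order
  perm <- m[c(1, 3, 2), ]
  ctp <- build_contingency(expand_printed_table(perm, exposure = "e", outcome = "y"),
                           "e", "y")
  orsp <- lapply(ctp$levels[-1], function(l) unadjusted_or(ctp, l))
  expect_equal(orsp[[1]]$estimate, ors[[2]]$estimate)
  expect_equal(orsp[[2]]$estimate, ors[[1]]$estimate)
  expect_equal(orsp[[1]]$p_value, ors[[2]]$p_value)

  # swap outcome yes/no: ORs invert, p-values unchanged
  swap <- m[, c(2, 1)]
  colnames(swap) <- c("n_no", "n_yes")
  cts <- build_contingency(expand_printed_table(swap, exposure = "e", outcome = "y"),
                           "e", "y")
  for (i in seq_along(ors)) {
    s <- unadjusted_or(cts, ct$levels[-1][i])
    expect_equal(s$estimate, 1 / ors[[i]]$estimate, tolerance = 1e-12)
    expect_equal(s$p_value, ors[[i]]$p_value, tolerance = 1e-12)
  }
})

test_that("the association screen emits the forest schema and consistent columns", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 2500, seed = 41))
  ph <- phenotype(sim$cohort)
  d <- as.data.frame(sim$cohort)
  d$ever <- ph$ever_asthma
  ft <- association_screen(d, "ever", c("food_pulses", "food_butter"),
                           adjust = c("gender", "parental_asthma"))
  expect_s3_class(ft, "forest_table")
  expect_named(ft, c("exposure", "level", "reference", "n_no", "n_yes",
                     "or", "or_lo", "or_hi", "or_p", "aor", "aor_lo",
                     "aor_hi", "aor_p", "adjusted_for", "n_used",
                     "significant", "p_bh"))
  expect_equal(nrow(ft), 4)  # two exposures x two non-reference levels
  expect_true(all(ft$or_lo <= ft$or & ft$or <= ft$or_hi))
  expect_true(all(ft$aor_lo <= ft$aor & ft$aor <= ft$aor_hi))
  expect_true(all(ft$adjusted_for == "gender;parental_asthma"))
  expect_equal(ft$significant, ft$aor_p < 0.05)
  # BH never reorders significance below raw p
  expect_true(all(ft$p_bh >= ft$aor_p - 1e-12))

  # empty exposure list -> empty table with the same schema
  e <- association_screen(d, "ever", character(0))
  expect_equal(nrow(e), 0)
  expect_named(e, names(ft))
})
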