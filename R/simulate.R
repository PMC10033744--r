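#' Specify a synthetic cross-sectional cohort
#'
#' Bundles and validates everything needed to simulate a questionnaire
#' cohort with the statistical structure the analysis pipeline assumes:
#' categorical marginals (defaults anchored to the published demographic and
#' dietary frequencies of the Singapore young-Chinese-adult cohort), a
#' logistic model generating the lifetime-asthma outcome from chosen
#' covariates, a symptom submodel conditioning the four 12-month symptom
#' answers on a latent current-asthma state among lifetime cases, a
#' skin-prick-test submodel generating wheal diameters by latent atopy
#' status, and per-variable missing-completely-at-random rates.
#'
#' @param n_subjects Number of subjects (default 10,736, the published
#'   analyzed sample size).
#' @param marginals Named list of level-probability vectors per categorical
#'   variable, plus `age = list(mean, sd, min)`; see [default_marginals()].
#' @param outcome_model List with `intercept` (log-odds) and `coefficients`,
#'   a named list mapping covariates to named per-level log-odds vectors;
#'   see [default_outcome_model()].
#' @param symptom_model List of conditional probabilities; see
#'   [default_symptom_model()].
#' @param spt_model Wheal-size and atopy-prevalence parameters; see
#'   [default_spt_model()].
#' @param missingness Named vector of MCAR missingness rates in `[0, 1)`.
#' @param seed Default random seed for [simulate_cohort()].
#' @return A validated list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 10736,
                        marginals = default_marginals(),
                        outcome_model = default_outcome_model(),
                        symptom_model = default_symptom_model(),
                        spt_model = default_spt_model(),
                        missingness = default_missingness(),
                        seed = 0) {
  spec <- structure(list(
    n_subjects = n_subjects, marginals = marginals,
    outcome_model = outcome_model, symptom_model = symptom_model,
    spt_model = spt_model, missingness = missingness, seed = seed
  ), class = "cohort_spec")
  problems <- character(0)
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    problems <- c(problems, "n_subjects must be >= 1")
  }
  for (v in setdiff(names(marginals), "age")) {
    p <- marginals[[v]]
    if (abs(sum(p) - 1) > 1e-9) {
      problems <- c(problems, sprintf("marginals for '%s' do not sum to 1", v))
    }
    if (any(p < 0)) problems <- c(problems, sprintf("negative probability for '%s'", v))
  }
  if (any(missingness < 0 | missingness >= 1)) {
    problems <- c(problems, "missingness rates must lie in [0, 1)")
  }
  probs <- unlist(symptom_model[grepl("^p_", names(symptom_model))])
  if (any(probs < 0 | probs > 1)) {
    problems <- c(problems, "symptom_model probabilities must lie in [0, 1]")
  }
  if (length(problems) > 0) {
    stop(paste0("invalid cohort spec:\n  - ",
                paste(problems, collapse = "\n  - ")), call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Cohort spec: n = %d, seed = %s, %d categorical marginals\n",
              x$n_subjects, format(x$seed),
              length(setdiff(names(x$marginals), "age"))))
  invisible(x)
}

#' Default categorical marginals
#'
#' Demographic marginals follow the published summary of the cohort (57.6%
#' female; income bands 22.7/34.0/19.5/23.8%; housing 67.5/19.0/13.5%; 69.1%
#' born in Singapore; 11.7% drug allergy; mean age 22.5, SD 5.2 years).
#' Dietary marginals are the row totals of the published diet-by-asthma
#' counts (see [diet_asthma_counts()]). Lifestyle and family-history
#' marginals are not printed as full tables and use plausible defaults for a
#' young-adult university cohort.
#'
#' @return Named list of probability vectors (and an `age` component).
#' @export
default_marginals <- function() {
  freq3 <- c("never or only occasionally", "once or twice per week",
             "most or all days per week")
  yn <- function(p_yes) c(no = 1 - p_yes, yes = p_yes)
  m <- list(
    age = list(mean = 22.5, sd = 5.2, min = 18),
    gender = c(female = 0.576, male = 0.424),
    income = stats::setNames(c(0.227, 0.340, 0.195, 0.238),
                             c("< SGD2000", "SGD2000 to < SGD4000",
                               "SGD4000 to < SGD6000", ">= SGD6000")),
    housing = stats::setNames(c(0.675, 0.190, 0.135),
                              c("HDB", "Condominium/Private apartments",
                                "Landed property")),
    born_in_singapore = yn(0.691),
    drug_allergy = yn(0.117),
    physical_activity = stats::setNames(c(0.35, 0.45, 0.20), freq3),
    screen_time = stats::setNames(c(0.10, 0.45, 0.25, 0.20),
                                  c("less than 1 h", "1 to 3 h",
                                    "more than 3 to 5 h", "more than 5 h")),
    alcohol = c(never = 0.60, occasionally = 0.35, frequently = 0.05),
    smoking = c("non-smoker" = 0.93, "ex-smoker" = 0.03, "current smoker" = 0.04),
    secondhand_smoke = yn(0.25),
    ever_pets = yn(0.40),
    maternal_ad = yn(0.05), maternal_ar = yn(0.06), maternal_asthma = yn(0.05),
    paternal_ad = yn(0.04), paternal_ar = yn(0.05), paternal_asthma = yn(0.05),
    sibling_ad = yn(0.12), sibling_ar = yn(0.12), sibling_asthma = yn(0.12)
  )
  counts <- diet_asthma_counts("ever")
  for (ex in unique(counts$exposure)) {
    if (!startsWith(ex, "food_")) next
    sub <- counts[counts$exposure == ex, ]
    tot <- sub$n_no + sub$n_yes
    m[[ex]] <- stats::setNames(tot / sum(tot), sub$level)
  }
  m
}

#' Default lifetime-asthma outcome model
#'
#' Logistic model for ever asthma with an intercept giving roughly the
#' published 19.1% prevalence, plus published-scale effects for the two
#' default adjustment covariates: parental asthma (log-odds of the crude OR
#' 4.78 attenuated to 1.35 to allow for its low prevalence) and male gender
#' (log of 1.387).
#'
#' @return List with `intercept` and named `coefficients`.
#' @export
default_outcome_model <- function() {
  list(
    intercept = -1.65,
    coefficients = list(
      parental_asthma = c(yes = 1.35),
      gender = c(male = log(1.387))
    )
  )
}

#' Default 12-month symptom submodel
#'
#' Among lifetime cases a latent current-asthma state is drawn with the
#' published conditional prevalence 33.1%; current cases report at least one
#' of the three defining symptoms, with marginal rates matching the
#' published variant fractions (wheeze 69.4%, dry night cough 60.7%) and
#' exercise wheeze conditioned on wheeze at 47.1%. Non-current subjects
#' answer all symptom questions "no".
#'
#' @return Named list of probabilities.
#' @export
default_symptom_model <- function() {
  list(
    p_current_given_ever = 0.331,
    p_wheeze = 0.694,
    p_cough = 0.607,
    p_exacerbation = 0.30,
    p_exercise_given_wheeze = 0.471
  )
}

#' Default skin-prick-test submodel
#'
#' Latent atopy prevalence is 75.2% among lifetime-asthma cases (the
#' published atopic fraction) and 55% otherwise (typical of this
#' mite-sensitized tropical population). Atopic subjects raise a wheal of at
#' least 3 mm to each allergen with probability 0.8 (mean 6 mm, SD 1.5,
#' truncated at 3); non-positive wheals are sub-threshold (mean 1 mm, SD
#' 0.7, truncated to `[0, 2.9]`). Controls are drawn valid: histamine about
#' 5 mm, saline 0 mm.
#'
#' @return Named list of parameters.
#' @export
default_spt_model <- function() {
  list(
    p_atopy_ever = 0.752,
    p_atopy_other = 0.55,
    p_allergen_pos = 0.8,
    wheal_pos = c(mean = 6, sd = 1.5),
    wheal_neg = c(mean = 1, sd = 0.7)
  )
}

#' Default MCAR missingness rates
#'
#' Anchored to the published per-variable NA counts: about 0.2% for gender,
#' 3.4% for income, 5.5% for housing, 0.5-0.9% for each food item, 5% for
#' the 12-month symptom questions (yielding roughly the published fraction
#' of current cases with complete variant data), and 5% for SPT wheals.
#'
#' @return Named numeric vector of rates.
#' @export
default_missingness <- function() {
  r <- c(
    age = 0.006, gender = 0.002, income = 0.034, housing = 0.055,
    born_in_singapore = 0.005, drug_allergy = 0.067,
    physical_activity = 0.01, screen_time = 0.01, alcohol = 0.01,
    smoking = 0.01, secondhand_smoke = 0.02, ever_pets = 0.01,
    wheeze_12m = 0.05, exercise_wheeze_12m = 0.05,
    dry_night_cough_12m = 0.05, exacerbation_12m = 0.05,
    spt_blo_mm = 0.05, spt_der_mm = 0.05
  )
  fam <- paste(rep(c("maternal", "paternal", "sibling"), each = 3),
               c("ad", "ar", "asthma"), sep = "_")
  r[fam] <- 0.02
  r[paste0("food_", food_groups())] <- 0.008
  r
}

#' Simulate a synthetic questionnaire cohort
#'
#' Draws covariates independently from the spec's marginals, the
#' lifetime-asthma outcome from the logistic outcome model, 12-month
#' symptoms from the symptom submodel conditioned on a latent current-asthma
#' state, skin-prick-test wheals from the SPT submodel conditioned on latent
#' atopy, and finally applies MCAR missingness. Identical spec and seed give
#' identical cohorts.
#'
#' @param spec A `"cohort_spec"`.
#' @param seed Random seed (default: the spec's seed).
#' @return A list with components `cohort` (a `"cohort"` data.frame) and
#'   `truth` (data.frame of latent per-subject states `true_ever`,
#'   `true_current`, `true_atopy`, with the generating coefficients stored
#'   in its `"coefficients"` attribute). The truth is for recovery testing
#'   only and is never read by the analysis operations.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 500, seed = 42))
#' mean(sim$truth$true_ever)
#' @export
simulate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_subjects
  m <- spec$marginals

  dat <- data.frame(subject_id = sprintf("S%06d", seq_len(n)),
                    stringsAsFactors = FALSE)
  if (!is.null(m$age)) {
    age <- stats::rnorm(n, m$age$mean, m$age$sd)
    dat$age <- round(pmax(age, m$age$min), 1)
  }
  for (v in setdiff(names(m), "age")) {
    dat[[v]] <- sample(names(m[[v]]), n, replace = TRUE, prob = m[[v]])
  }
  # derived convenience covariate used as the default adjustment term
  if (all(c("maternal_asthma", "paternal_asthma") %in% names(dat))) {
    dat$parental_asthma <- ifelse(
      dat$maternal_asthma == "yes" | dat$paternal_asthma == "yes", "yes", "no"
    )
  }

  om <- spec$outcome_model
  eta <- rep(om$intercept, n)
  for (v in names(om$coefficients)) {
    cf <- om$coefficients[[v]]
    if (is.null(dat[[v]])) {
      stop(sprintf("outcome model references unknown covariate '%s'", v),
           call. = FALSE)
    }
    for (lev in names(cf)) {
      eta <- eta + cf[[lev]] * (dat[[v]] == lev)
    }
  }
  true_ever <- stats::runif(n) < stats::plogis(eta)

  sm <- spec$symptom_model
  true_current <- true_ever & (stats::runif(n) < sm$p_current_given_ever)
  wh <- co <- exa <- rep(FALSE, n)
  cur <- which(true_current)
  if (length(cur) > 0) {
    wh[cur] <- stats::runif(length(cur)) < sm$p_wheeze
    co[cur] <- stats::runif(length(cur)) < sm$p_cough
    exa[cur] <- stats::runif(length(cur)) < sm$p_exacerbation
    # current cases report at least one defining symptom: redraw empty rows
    empty <- cur[!(wh[cur] | co[cur] | exa[cur])]
    guard <- 0
    while (length(empty) > 0 && guard < 1000) {
      wh[empty] <- stats::runif(length(empty)) < sm$p_wheeze
      co[empty] <- stats::runif(length(empty)) < sm$p_cough
      exa[empty] <- stats::runif(length(empty)) < sm$p_exacerbation
      empty <- empty[!(wh[empty] | co[empty] | exa[empty])]
      guard <- guard + 1
    }
    if (length(empty) > 0) wh[empty] <- TRUE
  }
  ew <- rep(FALSE, n)
  ew[wh] <- stats::runif(sum(wh)) < sm$p_exercise_given_wheeze
  to_yn <- function(x) ifelse(x, "yes", "no")
  dat$ever_asthma <- to_yn(true_ever)
  dat$wheeze_12m <- to_yn(wh)
  dat$exercise_wheeze_12m <- to_yn(ew)
  dat$dry_night_cough_12m <- to_yn(co)
  dat$exacerbation_12m <- to_yn(exa)

  pm <- spec$spt_model
  p_atopy <- ifelse(true_ever, pm$p_atopy_ever, pm$p_atopy_other)
  true_atopy <- stats::runif(n) < p_atopy
  draw_wheal <- function(pos) {
    w <- numeric(length(pos))
    np <- sum(pos)
    if (np > 0) {
      w[pos] <- pmax(stats::rnorm(np, pm$wheal_pos["mean"], pm$wheal_pos["sd"]), 3)
    }
    if (np < length(pos)) {
      w[!pos] <- pmin(pmax(stats::rnorm(length(pos) - np,
                                        pm$wheal_neg["mean"],
                                        pm$wheal_neg["sd"]), 0), 2.9)
    }
    round(w, 1)
  }
  pos_blo <- true_atopy & (stats::runif(n) < pm$p_allergen_pos)
  pos_der <- true_atopy & (stats::runif(n) < pm$p_allergen_pos)
  neither <- true_atopy & !pos_blo & !pos_der
  pos_blo[neither] <- TRUE   # atopy implies at least one positive allergen
  dat$spt_blo_mm <- draw_wheal(pos_blo)
  dat$spt_der_mm <- draw_wheal(pos_der)
  dat$spt_hist_mm <- round(pmax(stats::rnorm(n, 5, 0.8), 3), 1)
  dat$spt_saline_mm <- 0

  for (v in names(spec$missingness)) {
    if (is.null(dat[[v]])) next
    rate <- spec$missingness[[v]]
    if (rate > 0) dat[[v]][stats::runif(n) < rate] <- NA
  }

  cohort <- as_cohort(dat, provenance = sprintf("simulated (seed %s)", format(seed)))
  truth <- data.frame(
    subject_id = dat$subject_id,
    true_ever = true_ever,
    true_current = true_current,
    true_atopy = true_atopy,
    stringsAsFactors = FALSE
  )
  attr(truth, "coefficients") <- om
  list(cohort = cohort, truth = truth)
}

#' Expand printed contingency counts into per-subject records
#'
#' Turns a levels-by-outcome table of counts into a minimal cohort of one
#' record per count unit carrying only the exposure level and the outcome
#' flag, so that published contingency tables can be re-analyzed: running
#' [build_contingency()] on the expansion reproduces the input counts
#' exactly.
#'
#' @param counts A matrix or data.frame with one row per exposure level and
#'   columns `n_no`, `n_yes` (level labels as rownames or in a `level`
#'   column). All counts must be non-negative integers.
#' @param exposure Column name for the exposure in the output (default
#'   `"exposure"`).
#' @param outcome Column name for the logical outcome (default `"outcome"`).
#' @param levels Optional explicit level labels.
#' @return A data.frame with one row per subject: the exposure as a factor
#'   with the input level order, and the outcome as logical.
#' @examples
#' m <- matrix(c(234, 91, 903, 448, 225, 138), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("never", "once/twice", "most days"),
#'                             c("n_no", "n_yes")))
#' nrow(expand_printed_table(m))  # 2039
#' @export
expand_printed_table <- function(counts, exposure = "exposure",
                                 outcome = "outcome", levels = NULL) {
  if (is.data.frame(counts)) {
    if (is.null(levels)) {
      levels <- if (!is.null(counts$level)) as.character(counts$level) else rownames(counts)
    }
    counts <- as.matrix(counts[, c("n_no", "n_yes")])
  } else {
    if (is.null(levels)) levels <- rownames(counts)
    colnames(counts) <- c("n_no", "n_yes")
  }
  if (is.null(levels)) {
    stop("level labels must be supplied via rownames, a 'level' column, or 'levels'",
         call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  lev_rep <- rep(rep(levels, 2), times = c(counts[, "n_no"], counts[, "n_yes"]))
  out_rep <- rep(rep(c(FALSE, TRUE), each = length(levels)),
                 times = c(counts[, "n_no"], counts[, "n_yes"]))
  out <- data.frame(
    x = factor(lev_rep, levels = levels),
    y = out_rep,
    stringsAsFactors = FALSE
  )
  names(out) <- c(exposure, outcome)
  out
}
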