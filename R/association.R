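#' Build an exposure-by-outcome contingency table
#'
#' Cross-tabulates a categorical exposure against a boolean outcome flag on
#' the per-analysis complete cases (subjects with a non-missing outcome and
#' exposure), with the reference level first, column-wise percentages to one
#' decimal, and the count of subjects excluded for a missing exposure.
#'
#' @param data A data.frame containing the exposure column and outcome
#'   column (the outcome may be logical or yes/no coded).
#' @param exposure Name of the exposure column.
#' @param outcome Name of the outcome flag column.
#' @param levels Optional explicit level order (reference first); defaults
#'   to the factor levels or order of first appearance.
#' @return An object of class `"contingency_table"`: list with `exposure`,
#'   `outcome`, `levels`, `counts` (levels x c(n_no, n_yes)),
#'   `column_percent`, `n_missing`, `n_total`.
#' @examples
#' d <- expand_printed_table(
#'   matrix(c(1397, 486, 3929, 1097, 1249, 447), nrow = 3, byrow = TRUE,
#'          dimnames = list(c("never or only occasionally",
#'                            "once or twice per week",
#'                            "most or all days per week"),
#'                          c("n_no", "n_yes"))),
#'   exposure = "food_pulses", outcome = "ever_asthma")
#' build_contingency(d, "food_pulses", "ever_asthma")
#' @export
build_contingency <- function(data, exposure, outcome, levels = NULL) {
  ex <- data[[exposure]]
  if (is.null(ex)) stop(sprintf("unknown exposure '%s'", exposure), call. = FALSE)
  out <- data[[outcome]]
  if (is.null(out)) stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE)
  if (!is.logical(out)) out <- yn_to_logical(out)

  keep_out <- !is.na(out)
  ex <- ex[keep_out]
  out <- out[keep_out]
  n_missing <- sum(is.na(ex))
  cc <- !is.na(ex)
  ex <- ex[cc]
  out <- out[cc]

  if (is.null(levels)) {
    levels <- if (is.factor(ex)) base::levels(droplevels(ex)) else unique(as.character(ex))
  }
  ex <- factor(as.character(ex), levels = levels)
  if (anyNA(ex)) stop("exposure values outside the declared levels", call. = FALSE)
  observed <- levels[levels %in% unique(as.character(ex))]
  if (length(observed) < 2) {
    stop(sprintf("exposure '%s' has fewer than 2 observed levels", exposure),
         call. = FALSE)
  }

  counts <- t(vapply(levels, function(l) {
    c(n_no = sum(ex == l & !out), n_yes = sum(ex == l & out))
  }, c(n_no = 0, n_yes = 0)))
  pct <- sweep(counts, 2, colSums(counts), "/") * 100
  pct <- round_half_up(pct, 1)

  structure(list(
    exposure = exposure,
    outcome = outcome,
    levels = levels,
    counts = counts,
    column_percent = pct,
    n_missing = n_missing,
    n_total = sum(counts)
  ), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("%s x %s (N = %d analyzed, %d missing)\n",
              x$exposure, x$outcome, x$n_total, x$n_missing))
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$column_percent),
                 nrow = nrow(x$counts),
                 dimnames = dimnames(x$counts))
  print(as.data.frame(disp))
  invisible(x)
}

# Cross-product odds ratio with Wald CI/p from a 2x2 cell layout:
# a = reference & outcome-no, b = reference & outcome-yes,
# c = level & outcome-no,     d = level & outcome-yes.
or_from_cells <- function(a, b, c, d, level, reference,
                          conf_level = 0.95, correction = FALSE,
                          adjusted_for = character(0)) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) {
    if (!correction) {
      stop(paste0(
        "zero cell in 2x2 sub-table for level '", level,
        "'; enable the Haldane-Anscombe correction (correction = TRUE) to add 0.5 to all cells"
      ), call. = FALSE)
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(log(est) - zq * se)
  hi <- exp(log(est) + zq * se)
  p <- 2 * stats::pnorm(-abs(log(est) / se))
  structure(list(
    exposure_level = level, reference_level = reference,
    estimate = est, ci_low = lo, ci_high = hi, p_value = p,
    adjusted_for = adjusted_for, n_used = sum(a + b + c + d)
  ), class = "odds_ratio")
}

#' Unadjusted odds ratio from a contingency table
#'
#' Computes the cross-product odds ratio of the outcome for one exposure
#' level against the reference level, with the 95% Wald confidence interval
#' `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` and the two-sided Wald
#' p-value. A zero cell is an error unless the Haldane-Anscombe +0.5
#' correction is enabled.
#'
#' @param table A `"contingency_table"`.
#' @param level Exposure level to contrast (not the reference).
#' @param conf_level Confidence level (default 0.95).
#' @param correction Add 0.5 to all four cells when any is zero.
#' @return An `"odds_ratio"` object: `exposure_level`, `reference_level`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `adjusted_for` (empty),
#'   `n_used`.
#' @examples
#' d <- expand_printed_table(
#'   matrix(c(1397, 486, 3929, 1097), nrow = 2, byrow = TRUE,
#'          dimnames = list(c("never", "once or twice"), c("n_no", "n_yes"))))
#' ct <- build_contingency(d, "exposure", "outcome")
#' unadjusted_or(ct, "once or twice")  # OR 0.803, CI 0.710-0.908
#' @export
unadjusted_or <- function(table, level, conf_level = 0.95, correction = FALSE) {
  ref <- table$levels[1]
  if (identical(level, ref)) {
    stop("requested level is the reference level", call. = FALSE)
  }
  if (!level %in% table$levels) {
    stop(sprintf("unknown exposure level '%s'", level), call. = FALSE)
  }
  or_from_cells(
    a = table$counts[ref, "n_no"], b = table$counts[ref, "n_yes"],
    c = table$counts[level, "n_no"], d = table$counts[level, "n_yes"],
    level = level, reference = ref,
    conf_level = conf_level, correction = correction
  )
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf(
    "%s vs %s: OR %.3f (95%% CI %.3f-%.3f), p = %.3g%s [n = %d]\n",
    x$exposure_level, x$reference_level, x$estimate, x$ci_low, x$ci_high,
    x$p_value,
    if (length(x$adjusted_for)) paste0(", adjusted for ",
                                       paste(x$adjusted_for, collapse = ", "))
    else "",
    x$n_used
  ))
  invisible(x)
}

#' Adjusted odds ratios from a fitted logistic model
#'
#' Exponentiates the treatment-coded coefficients of one exposure from a
#' multivariable [logit_fit()] to obtain its adjusted odds ratios, Wald
#' confidence intervals, and p-values, one per non-reference level.
#'
#' @param fit A `"logit_fit"` object whose terms include `exposure`.
#' @param exposure Name of the exposure variable in the fit.
#' @param conf_level Confidence level (default 0.95).
#' @return List of `"odds_ratio"` objects, one per non-reference level;
#'   `adjusted_for` lists the other model terms.
#' @export
adjusted_or <- function(fit, exposure, conf_level = 0.95) {
  term_labels <- attr(fit$terms, "term.labels")
  if (!exposure %in% term_labels) {
    stop(sprintf("exposure '%s' is not a term of the fit", exposure), call. = FALSE)
  }
  lev <- fit$xlevels[[exposure]]
  if (is.null(lev)) {
    stop(sprintf("exposure '%s' is not categorical in the fit", exposure),
         call. = FALSE)
  }
  other <- setdiff(term_labels, exposure)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_all <- sqrt(diag(fit$vcov))
  lapply(lev[-1], function(l) {
    nm <- paste0(exposure, l)
    if (!nm %in% names(fit$coefficients)) {
      stop(sprintf("coefficient '%s' not found in fit", nm), call. = FALSE)
    }
    b <- fit$coefficients[[nm]]
    se <- se_all[[nm]]
    structure(list(
      exposure_level = l, reference_level = lev[1],
      estimate = exp(b),
      ci_low = exp(b - zq * se), ci_high = exp(b + zq * se),
      p_value = 2 * stats::pnorm(-abs(b / se)),
      adjusted_for = other, n_used = fit$n_used
    ), class = "odds_ratio")
  })
}

#' Screen exposures against an asthma outcome
#'
#' For each exposure, builds the per-exposure complete-case contingency
#' table, computes unadjusted odds ratios per non-reference level, and fits
#' a logistic model containing that exposure plus the adjustment set only
#' (mirroring per-exposure adjusted models), yielding adjusted odds ratios.
#' Significance is flagged at `alpha` on the adjusted p-value when an
#' adjustment set is given, otherwise on the unadjusted p-value; a
#' Benjamini-Hochberg column is emitted as supplementary output but never
#' gates the flag.
#'
#' @param data A data.frame holding the outcome flag, exposures, and
#'   adjustment covariates.
#' @param outcome Name of the boolean outcome flag column.
#' @param exposures Character vector of exposure column names.
#' @param adjust Character vector of adjustment covariates (default empty =
#'   unadjusted models only, in which case the "adjusted" columns repeat the
#'   exposure-only fit).
#' @param alpha Significance level (default 0.05).
#' @param correction Haldane-Anscombe +0.5 for zero cells (default off).
#' @return A data.frame with class `"forest_table"` and columns `exposure`,
#'   `level`, `reference`, `n_no`, `n_yes`, `or`, `or_lo`, `or_hi`, `or_p`,
#'   `aor`, `aor_lo`, `aor_hi`, `aor_p`, `adjusted_for`, `n_used`,
#'   `significant`, `p_bh`.
#' @export
association_screen <- function(data, outcome, exposures,
                               adjust = character(0), alpha = 0.05,
                               correction = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  rows <- list()
  for (ex in exposures) {
    ct <- build_contingency(data, ex, outcome)
    fit_data <- data[, unique(c(outcome, ex, adjust)), drop = FALSE]
    if (!is.logical(fit_data[[outcome]])) {
      fit_data[[outcome]] <- yn_to_logical(fit_data[[outcome]])
    }
    if (is.character(fit_data[[ex]])) {
      fit_data[[ex]] <- factor(fit_data[[ex]], levels = ct$levels)
    }
    fml <- stats::reformulate(c(ex, adjust), response = outcome)
    fit <- logit_fit(fml, fit_data)
    aors <- adjusted_or(fit, ex)
    names(aors) <- vapply(aors, `[[`, "", "exposure_level")
    for (l in ct$levels[-1]) {
      u <- unadjusted_or(ct, l, correction = correction)
      a <- aors[[l]]
      rows[[length(rows) + 1]] <- data.frame(
        exposure = ex, level = l, reference = ct$levels[1],
        n_no = ct$counts[l, "n_no"], n_yes = ct$counts[l, "n_yes"],
        or = u$estimate, or_lo = u$ci_low, or_hi = u$ci_high, or_p = u$p_value,
        aor = if (is.null(a)) NA_real_ else a$estimate,
        aor_lo = if (is.null(a)) NA_real_ else a$ci_low,
        aor_hi = if (is.null(a)) NA_real_ else a$ci_high,
        aor_p = if (is.null(a)) NA_real_ else a$p_value,
        adjusted_for = paste(adjust, collapse = ";"),
        n_used = fit$n_used,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(
      exposure = character(0), level = character(0), reference = character(0),
      n_no = integer(0), n_yes = integer(0),
      or = numeric(0), or_lo = numeric(0), or_hi = numeric(0), or_p = numeric(0),
      aor = numeric(0), aor_lo = numeric(0), aor_hi = numeric(0),
      aor_p = numeric(0), adjusted_for = character(0), n_used = integer(0),
      significant = logical(0), p_bh = numeric(0),
      stringsAsFactors = FALSE
    )
    return(structure(out, class = c("forest_table", "data.frame")))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  gate_p <- if (length(adjust) > 0) out$aor_p else out$or_p
  out$significant <- gate_p < alpha
  out$p_bh <- stats::p.adjust(gate_p, method = "BH")
  structure(out, class = c("forest_table", "data.frame"))
}
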