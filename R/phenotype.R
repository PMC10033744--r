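#' Classify atopy from skin-prick-test wheal diameters
#'
#' A subject is atopic when any tested allergen (here the house-dust-mite
#' species Blomia tropicalis and Dermatophagoides pteronyssinus) raises a
#' wheal of at least `wheal_threshold_mm` millimetres. If every allergen
#' wheal is missing the result is missing. With `strict_qc = TRUE`, tests
#' whose controls fail (saline negative control at or above the threshold,
#' or histamine positive control below it) are set to missing; the default
#' is off because the source analyses describe no control-based exclusions.
#'
#' @param data A cohort or data.frame with columns `spt_blo_mm`,
#'   `spt_der_mm`, and (for strict QC) `spt_hist_mm`, `spt_saline_mm`.
#' @param wheal_threshold_mm Positivity threshold in mm (default 3).
#' @param strict_qc Invalidate records with failed SPT controls.
#' @return Logical vector (`NA` = missing).
#' @export
classify_atopy <- function(data, wheal_threshold_mm = 3, strict_qc = FALSE) {
  blo <- data$spt_blo_mm
  der <- data$spt_der_mm
  if (is.null(blo) && is.null(der)) {
    stop("no allergen wheal columns (spt_blo_mm / spt_der_mm) present", call. = FALSE)
  }
  w <- cbind(as.numeric(blo %||% rep(NA_real_, nrow(data))),
             as.numeric(der %||% rep(NA_real_, nrow(data))))
  if (any(w < 0, na.rm = TRUE)) {
    stop("negative wheal diameter encountered", call. = FALSE)
  }
  any_pos <- apply(w >= wheal_threshold_mm, 1, function(r) {
    if (any(r, na.rm = TRUE)) TRUE else if (all(is.na(r))) NA else FALSE
  })
  if (strict_qc) {
    sal <- as.numeric(data$spt_saline_mm %||% rep(NA_real_, nrow(data)))
    his <- as.numeric(data$spt_hist_mm %||% rep(NA_real_, nrow(data)))
    invalid <- (!is.na(sal) & sal >= wheal_threshold_mm) |
      (!is.na(his) & his < wheal_threshold_mm)
    any_pos[invalid] <- NA
  }
  any_pos
}

#' Classify lifetime ("ever") asthma
#'
#' True when the subject answered the lifetime-asthma question
#' ("Have you ever had asthma?") affirmatively; missing propagates.
#'
#' @param data A cohort or data.frame with an `ever_asthma` column.
#' @return Logical vector (`NA` = missing).
#' @export
classify_ever_asthma <- function(data) {
  yn_to_logical(data$ever_asthma)
}

#' Classify current asthma among lifetime cases
#'
#' Current asthma requires lifetime asthma plus any asthma symptom in the
#' past 12 months: wheezing, dry night cough in the absence of a cold or
#' flu, or an asthma exacerbation. Subjects without lifetime asthma are not
#' current cases regardless of symptoms; lifetime cases with all three
#' symptom answers missing are missing.
#'
#' @param data A cohort or data.frame with columns `wheeze_12m`,
#'   `dry_night_cough_12m`, `exacerbation_12m`.
#' @param ever Logical vector of lifetime-asthma status (from
#'   [classify_ever_asthma()]).
#' @return Logical vector (`NA` = missing).
#' @export
classify_current_asthma <- function(data, ever = classify_ever_asthma(data)) {
  wh <- yn_to_logical(data$wheeze_12m)
  co <- yn_to_logical(data$dry_night_cough_12m)
  ex <- yn_to_logical(data$exacerbation_12m)
  any_sym <- wh | co | ex   # Kleene: TRUE|NA = TRUE, FALSE|NA = NA
  ever & any_sym            # FALSE & NA = FALSE
}

#' Classify asthma variants among current cases
#'
#' Among current asthma cases the non-mutually-exclusive variants are:
#' wheeze-variant asthma (WVA; any wheeze in the past 12 months),
#' exercise-induced asthma (EIA; exercise-provoked wheeze in the past 12
#' months, constrained to WVA cases), and cough-variant asthma (CVA; dry
#' night cough not associated with a cold or chest infection). Variants are
#' undefined (missing) for subjects who are not current cases.
#'
#' @param data A cohort or data.frame with the 12-month symptom columns.
#' @param current Logical vector of current-asthma status.
#' @return A data.frame with logical columns `wva`, `eia`, `cva`.
#' @export
classify_variants <- function(data, current) {
  wh <- yn_to_logical(data$wheeze_12m)
  ew <- yn_to_logical(data$exercise_wheeze_12m)
  co <- yn_to_logical(data$dry_night_cough_12m)
  wva <- wh
  eia <- wva & ew  # EIA is reported as a subset of WVA
  cva <- co
  undef <- is.na(current) | !current
  wva[undef] <- NA
  eia[undef] <- NA
  cva[undef] <- NA
  data.frame(wva = wva, eia = eia, cva = cva)
}

#' Derive the full asthma phenotype profile for a cohort
#'
#' Applies the whole taxonomy: atopy (SPT wheal >= threshold), ever asthma,
#' atopic asthma (ever and atopic), current asthma (ever plus any 12-month
#' symptom), current atopic asthma (current and atopic), and the WVA / EIA /
#' CVA variants among current cases.
#'
#' @param cohort A `"cohort"` data.frame (see [read_cohort()]).
#' @param wheal_threshold_mm SPT positivity threshold in mm (default 3).
#' @param strict_spt_qc Passed to [classify_atopy()].
#' @return A data.frame with class `"phenotype_profile"`: `subject_id` plus
#'   logical columns `atopy`, `ever_asthma`, `atopic_asthma`,
#'   `current_asthma`, `current_atopic_asthma`, `wva`, `eia`, `cva`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 200, seed = 1))
#' ph <- phenotype(sim$cohort)
#' table(ph$ever_asthma, useNA = "ifany")
#' @export
phenotype <- function(cohort, wheal_threshold_mm = 3, strict_spt_qc = FALSE) {
  atopy <- classify_atopy(cohort, wheal_threshold_mm, strict_spt_qc)
  ever <- classify_ever_asthma(cohort)
  current <- classify_current_asthma(cohort, ever)
  var <- classify_variants(cohort, current)
  out <- data.frame(
    subject_id = cohort$subject_id %||% sprintf("S%06d", seq_len(nrow(cohort))),
    atopy = atopy,
    ever_asthma = ever,
    atopic_asthma = ever & atopy,
    current_asthma = current,
    current_atopic_asthma = current & atopy,
    stringsAsFactors = FALSE
  )
  out$wva <- var$wva
  out$eia <- var$eia
  out$cva <- var$cva
  structure(out, class = c("phenotype_profile", "data.frame"))
}

#' Prevalence of a phenotype flag
#'
#' Counts subjects with the flag true over subjects with a non-missing flag,
#' optionally restricted to a sub-denominator flag (e.g. atopic asthma among
#' ever-asthma cases). Percentages are rounded half-up to one decimal, the
#' convention of the printed estimates (2049/10736 = 19.085... -> 19.1).
#'
#' @param profile A `"phenotype_profile"` data.frame (or any data.frame of
#'   logical flags).
#' @param flag Name of the flag column for the numerator.
#' @param denominator_flag Optional flag column; the denominator is
#'   restricted to subjects where it is `TRUE`.
#' @return A list with class `"prevalence_report"`: `numerator`,
#'   `denominator`, `proportion`, `percent_1dp`.
#' @examples
#' ph <- reconstruct_phenotypes()
#' prevalence(ph, "ever_asthma")                      # 19.1%
#' prevalence(ph, "atopic_asthma", "ever_asthma")     # 75.2%
#' @export
prevalence <- function(profile, flag, denominator_flag = NULL) {
  x <- profile[[flag]]
  if (is.null(x)) stop(sprintf("unknown flag '%s'", flag), call. = FALSE)
  keep <- !is.na(x)
  if (!is.null(denominator_flag)) {
    d <- profile[[denominator_flag]]
    if (is.null(d)) stop(sprintf("unknown flag '%s'", denominator_flag), call. = FALSE)
    keep <- keep & !is.na(d) & d
  }
  denom <- sum(keep)
  if (denom == 0) stop("prevalence denominator is zero", call. = FALSE)
  num <- sum(x[keep])
  structure(list(
    flag = flag,
    denominator_flag = denominator_flag,
    numerator = num,
    denominator = denom,
    proportion = num / denom,
    percent_1dp = round_half_up(100 * num / denom, 1)
  ), class = "prevalence_report")
}

#' @export
print.prevalence_report <- function(x, ...) {
  cat(sprintf(
    "%s%s: %.1f%% (%d/%d)\n", x$flag,
    if (is.null(x$denominator_flag)) "" else paste0(" | ", x$denominator_flag),
    x$percent_1dp, x$numerator, x$denominator
  ))
  invisible(x)
}

#' Variant overlap among current asthma cases
#'
#' Cross-tabulates the 2^3 combinations of the WVA, EIA, and CVA flags among
#' current asthma cases with complete variant data. The complete-data
#' sub-denominator is always reported next to the current-case count, never
#' silently substituted for it.
#'
#' @param profile A `"phenotype_profile"` data.frame.
#' @return A data.frame with class `"variant_overlap"`: logical columns
#'   `wva`, `eia`, `cva` and a `count` column over the eight disjoint cells;
#'   attributes `n_current` (current cases) and `n_complete` (current cases
#'   with all three variant flags non-missing). Cell counts sum to
#'   `n_complete`.
#' @export
variant_overlap <- function(profile) {
  cur <- !is.na(profile$current_asthma) & profile$current_asthma
  complete <- cur & !is.na(profile$wva) & !is.na(profile$eia) & !is.na(profile$cva)
  cells <- expand.grid(wva = c(FALSE, TRUE), eia = c(FALSE, TRUE),
                       cva = c(FALSE, TRUE))
  cnt <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cnt[i] <- sum(
      profile$wva[complete] == cells$wva[i] &
      profile$eia[complete] == cells$eia[i] &
      profile$cva[complete] == cells$cva[i]
    )
  }
  out <- cbind(cells, count = cnt)
  structure(out,
            n_current = sum(cur),
            n_complete = sum(complete),
            class = c("variant_overlap", "data.frame"))
}

#' @export
print.variant_overlap <- function(x, ...) {
  cat(sprintf(
    "Asthma variant overlap: %d complete of %d current cases\n",
    attr(x, "n_complete"), attr(x, "n_current")
  ))
  print.data.frame(x)
  cat(sprintf(
    "Marginals: WVA %d, EIA %d, CVA %d\n",
    sum(x$count[x$wva]), sum(x$count[x$eia]), sum(x$count[x$cva])
  ))
  invisible(x)
}
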