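#' Published diet-by-asthma contingency counts
#'
#' Reference contingency counts for the 16 food-frequency exposures and the
#' categorized dietary GI level against lifetime ("ever") and current asthma,
#' as published for the Singapore young-Chinese-adult cohort (10,736
#' subjects analyzed; 2,049 ever-asthma cases of whom 679 are current
#' cases). Each exposure carries counts per level split by outcome column,
#' plus a row with level `"NA"` holding the per-outcome-column counts of
#' subjects missing that exposure. These counts are the fixture for
#' exact-reproduction tests of the unadjusted odds ratios: expanded to
#' per-subject records with [expand_printed_table()], they reproduce the
#' published ORs to three decimals.
#'
#' @param outcome `"ever"` (counts against ever asthma, column totals
#'   6,633 / 2,049) or `"current"` (current vs non-current among ever cases,
#'   column totals 1,370 / 679).
#' @param drop_na Drop the `"NA"` missingness rows (default `TRUE`).
#' @return A data.frame with columns `exposure`, `level`, `n_no`, `n_yes`.
#' @examples
#' head(diet_asthma_counts("ever"))
#' @export
diet_asthma_counts <- function(outcome = c("ever", "current"), drop_na = TRUE) {
  outcome <- match.arg(outcome)
  path <- system.file(
    "extdata",
    sprintf("diet_%s_counts.csv", outcome),
    package = "epiasthma", mustWork = TRUE
  )
  x <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = NULL)
  if (drop_na) x <- x[x$level != "NA", , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Published asthma phenotype flow counts
#'
#' The participant flow of the Singapore young-Chinese-adult cohort:
#' 10,736 analyzed subjects; 2,049 ever-asthma cases; 1,541 atopic-asthma
#' and 679 current-asthma cases among them; 512 current atopic cases; and,
#' among the 588 current cases with complete variant data, 408 wheeze-variant
#' (WVA), 192 exercise-induced (EIA), and 357 cough-variant (CVA) cases,
#' with 177 having both CVA and WVA and 106 having all three.
#'
#' @return Named list of counts.
#' @export
asthma_flow_counts <- function() {
  list(
    analyzed = 10736L,
    ever = 2049L,
    atopic_asthma = 1541L,
    current = 679L,
    current_atopic = 512L,
    variant_complete = 588L,
    wva = 408L,
    eia = 192L,
    cva = 357L,
    cva_and_wva = 177L,
    wva_eia_cva = 106L
  )
}

#' Reconstruct a phenotype profile realizing published flow counts
#'
#' Builds a per-subject phenotype-flag table whose marginal counts equal the
#' published participant flow, so that [prevalence()], [variant_overlap()],
#' and [summarize_flow()] can be exercised against the printed fractions
#' without individual-level data. The eight-cell variant overlap is uniquely
#' determined by the published marginals together with the EIA-within-WVA
#' hierarchy: (WVA,EIA,CVA) cells TTT = 106, TTF = 86, TFT = 71, TFF = 145,
#' FFT = 180, and no complete-data current case with neither WVA nor CVA.
#'
#' @param flow Named list of counts, default [asthma_flow_counts()].
#' @return A `"phenotype_profile"` data.frame (one row per subject).
#' @examples
#' ph <- reconstruct_phenotypes()
#' prevalence(ph, "ever_asthma")   # 19.1% (2049/10736)
#' @export
reconstruct_phenotypes <- function(flow = asthma_flow_counts()) {
  n <- flow$analyzed
  ever <- rep(c(TRUE, FALSE), c(flow$ever, n - flow$ever))
  atopy <- rep(NA, n)
  current <- rep(FALSE, n)
  current[seq_len(flow$current)] <- TRUE
  # atopy among ever: current_atopic among current, rest among non-current ever
  atopy[seq_len(flow$current_atopic)] <- TRUE
  atopy[(flow$current_atopic + 1):flow$current] <- FALSE
  n_noncur_atopic <- flow$atopic_asthma - flow$current_atopic
  noncur_ever <- (flow$current + 1):flow$ever
  atopy[noncur_ever] <- rep(c(TRUE, FALSE),
                            c(n_noncur_atopic, length(noncur_ever) - n_noncur_atopic))

  # Variant cells among complete-data current cases (derived from marginals).
  ttt <- flow$wva_eia_cva
  ttf <- flow$eia - ttt
  tft <- flow$cva_and_wva - ttt
  tff <- flow$wva - flow$eia - tft
  fft <- flow$cva - flow$cva_and_wva
  fff <- flow$variant_complete - flow$wva - fft
  cells <- data.frame(
    wva = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    eia = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    cva = c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE),
    count = c(ttt, ttf, tft, tff, fft, fff)
  )
  if (any(cells$count < 0) || sum(cells$count) != flow$variant_complete) {
    stop("flow counts are inconsistent with the EIA-within-WVA hierarchy",
         call. = FALSE)
  }
  wva <- rep(NA, n); eia <- rep(NA, n); cva <- rep(NA, n)
  idx <- 1L
  for (i in seq_len(nrow(cells))) {
    k <- cells$count[i]
    if (k > 0) {
      rows <- idx:(idx + k - 1L)
      wva[rows] <- cells$wva[i]
      eia[rows] <- cells$eia[i]
      cva[rows] <- cells$cva[i]
      idx <- idx + k
    }
  }
  # remaining current cases lack complete variant data
  structure(data.frame(
    subject_id = sprintf("S%06d", seq_len(n)),
    atopy = atopy,
    ever_asthma = ever,
    atopic_asthma = ever & atopy,
    current_asthma = current,
    current_atopic_asthma = current & atopy,
    wva = wva, eia = eia, cva = cva,
    stringsAsFactors = FALSE
  ), class = c("phenotype_profile", "data.frame"))
}
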