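#' Summarize the participant flow of a phenotype profile
#'
#' Computes the nested flow counts (analyzed, ever asthma, atopic and
#' current asthma among ever cases, current atopic cases, and the WVA / EIA
#' / CVA counts among current cases with complete variant data), each
#' derivable from the profile by independent recount.
#'
#' @param profile A `"phenotype_profile"` data.frame.
#' @return Named list of counts in the same shape as [asthma_flow_counts()].
#' @export
summarize_flow <- function(profile) {
  tr <- function(x) sum(!is.na(x) & x)
  ov <- variant_overlap(profile)
  list(
    analyzed = nrow(profile),
    ever = tr(profile$ever_asthma),
    atopic_asthma = tr(profile$atopic_asthma),
    current = tr(profile$current_asthma),
    current_atopic = tr(profile$current_atopic_asthma),
    variant_complete = attr(ov, "n_complete"),
    wva = sum(ov$count[ov$wva]),
    eia = sum(ov$count[ov$eia]),
    cva = sum(ov$count[ov$cva]),
    cva_and_wva = sum(ov$count[ov$cva & ov$wva]),
    wva_eia_cva = sum(ov$count[ov$wva & ov$eia & ov$cva])
  )
}

#' Run the full analysis pipeline
#'
#' Executes read -> phenotype -> diet score -> association screen and writes
#' a reproducible report bundle: `phenotypes.csv` (per-subject flags),
#' `qdgis.csv` (diet scores), `forest_ever.csv` and `forest_current.csv`
#' (unadjusted and adjusted odds ratios per exposure level),
#' `prevalence.json` (flow counts and headline prevalences), and `run.log`.
#' Identical config and inputs produce identical outputs.
#'
#' The current-asthma screen compares current against non-current cases
#' within lifetime-asthma cases (the convention of the published tables);
#' set `current_within_ever = FALSE` in the config to compare against all
#' non-current subjects.
#'
#' @param config A named list, or path to a YAML file, with fields:
#'   `input` (cohort CSV path) or `cohort` (an in-memory cohort);
#'   `codebook` (optional codebook YAML/JSON path); `exposures` (character
#'   vector; default: the 16 food items plus `gi_level`); `adjust`
#'   (default `c("gender", "parental_asthma")`); `alpha` (default 0.05);
#'   `missing_policy` for the diet score; `out_dir` (default a fresh temp
#'   directory); `current_within_ever` (default `TRUE`);
#'   `strict_spt_qc` (default `FALSE`).
#' @return Invisibly, a named list of output file paths (class
#'   `"pipeline_bundle"`).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 400, seed = 7))
#' bundle <- run_pipeline(list(cohort = sim$cohort,
#'                             exposures = c("food_pulses", "food_butter"),
#'                             out_dir = tempfile("run")))
#' file.exists(bundle$prevalence)
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) {
      stop(sprintf("[config] file not found: '%s'", config), call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  alpha <- config$alpha %||% 0.05
  stopifnot(alpha > 0, alpha < 1)
  adjust <- config$adjust %||% c("gender", "parental_asthma")
  exposures <- config$exposures %||% c(paste0("food_", food_groups()), "gi_level")
  out_dir <- config$out_dir %||% tempfile("epiasthma_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_con <- file(log_path, open = "w")
  on.exit(close(log_con))
  logmsg <- function(...) {
    writeLines(sprintf(...), log_con)
  }
  logmsg("epiasthma %s | R %s.%s",
         as.character(utils::packageVersion("epiasthma")),
         R.version$major, R.version$minor)

  cohort <- stage("read", {
    if (!is.null(config$cohort)) {
      config$cohort
    } else {
      if (is.null(config$input)) stop("config needs 'input' or 'cohort'")
      cb <- if (!is.null(config$codebook)) {
        read_codebook(config$codebook)
      } else {
        default_codebook()
      }
      read_cohort(config$input, codebook = cb,
                  missing_token = config$missing_token %||% "")
    }
  })
  logmsg("read: %d subjects (%s)", nrow(cohort),
         attr(cohort, "provenance") %||% "in-memory")

  profile <- stage("phenotype", {
    phenotype(cohort, strict_spt_qc = isTRUE(config$strict_spt_qc))
  })
  flow <- summarize_flow(profile)
  logmsg("phenotype: ever %d / analyzed %d; current %d; variant-complete %d",
         flow$ever, flow$analyzed, flow$current, flow$variant_complete)

  qd <- stage("qdgis", {
    compute_qdgis(cohort, missing_policy = config$missing_policy %||% "propagate")
  })
  logmsg("qdgis: %d scored, %d missing",
         sum(!is.na(qd$qdgis_score)), sum(is.na(qd$qdgis_score)))

  dat <- as.data.frame(cohort, stringsAsFactors = FALSE)
  dat$gi_level <- factor(qd$qdgis_category[match(dat$subject_id, qd$subject_id)],
                         levels = c("poor", "moderate", "good"))
  # declared level order from the codebook, so references match the printed tables
  cb <- attr(cohort, "codebook") %||% default_codebook()
  for (v in intersect(names(dat), names(cb))) {
    if (!is.null(cb[[v]]$levels)) {
      ref <- cb[[v]]$reference
      lv <- union(ref, cb[[v]]$levels)
      dat[[v]] <- factor(dat[[v]], levels = lv)
    }
  }
  idx <- match(dat$subject_id, profile$subject_id)
  dat$ever_asthma_flag <- profile$ever_asthma[idx]
  dat$current_asthma_flag <- profile$current_asthma[idx]

  exposures <- intersect(exposures, names(dat))
  forest_ever <- stage("associate-ever", {
    association_screen(dat, "ever_asthma_flag", exposures,
                       adjust = adjust, alpha = alpha)
  })
  dat_cur <- if (isTRUE(config$current_within_ever %||% TRUE)) {
    dat[!is.na(dat$ever_asthma_flag) & dat$ever_asthma_flag, , drop = FALSE]
  } else {
    dat
  }
  forest_current <- stage("associate-current", {
    association_screen(dat_cur, "current_asthma_flag", exposures,
                       adjust = adjust, alpha = alpha)
  })
  for (ex in exposures) {
    logmsg("associate: %s complete-case N = %d (ever), %d (current)",
           ex,
           sum(!is.na(dat[[ex]]) & !is.na(dat$ever_asthma_flag)),
           sum(!is.na(dat_cur[[ex]]) & !is.na(dat_cur$current_asthma_flag)))
  }

  paths <- list(
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    qdgis = file.path(out_dir, "qdgis.csv"),
    forest_ever = file.path(out_dir, "forest_ever.csv"),
    forest_current = file.path(out_dir, "forest_current.csv"),
    prevalence = file.path(out_dir, "prevalence.json"),
    log = log_path
  )
  stage("write", {
    write_table(profile, paths$phenotypes)
    write_table(qd, paths$qdgis)
    write_table(forest_ever, paths$forest_ever)
    write_table(forest_current, paths$forest_current)
    prev <- list(
      flow = flow,
      ever_asthma = unclass(prevalence(profile, "ever_asthma")),
      current_asthma = unclass(prevalence(profile, "current_asthma"))
    )
    if (flow$ever > 0) {
      prev$atopic_among_ever <-
        unclass(prevalence(profile, "atopic_asthma", "ever_asthma"))
      prev$current_among_ever <-
        unclass(prevalence(profile, "current_asthma", "ever_asthma"))
    }
    jsonlite::write_json(prev, paths$prevalence, auto_unbox = TRUE,
                         digits = NA, null = "null")
  })
  logmsg("done: %d output files", length(paths))
  invisible(structure(paths, class = "pipeline_bundle"))
}
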