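#' Questionnaire variable codebook
#'
#' A codebook describes every questionnaire variable the pipeline understands:
#' its kind (binary, ordinal or nominal categorical, or numeric), its ordered
#' level labels, the reference level used for odds-ratio contrasts, and units
#' for numeric variables. [default_codebook()] encodes the ISAAC-style
#' questionnaire used by the Singapore young-adult cohort analyses: basic
#' demographics, familial history of atopic diseases, lifestyle habits, a
#' 16-item food-frequency block, the asthma questions, and skin-prick-test
#' wheal measurements.
#'
#' Level labels are matched case-insensitively after whitespace
#' normalization, so `"Female"` and `"female "` both map onto the canonical
#' label. Reference levels are the first printed category of each variable
#' (e.g. "never or only occasionally" for food frequencies, "< SGD2000" for
#' income); the gender reference defaults to `"female"` and can be changed
#' with `set_reference()` since lifetime- and current-asthma contrasts are
#' conventionally reported in opposite directions.
#'
#' @return A named list of variable definitions with class `"codebook"`.
#'   Each element has fields `kind`, `levels`, `reference`, and `units`.
#' @examples
#' cb <- default_codebook()
#' cb$food_pulses$levels
#' cb$gender$reference
#' @export
default_codebook <- function() {
  freq3 <- c(
    "never or only occasionally",
    "once or twice per week",
    "most or all days per week"
  )
  yn <- c("no", "yes")

  cat_var <- function(kind, levels, reference = levels[1], units = NULL) {
    list(kind = kind, levels = levels, reference = reference, units = units)
  }
  num_var <- function(units) {
    list(kind = "numeric", levels = NULL, reference = NULL, units = units)
  }
  binary <- function() cat_var("binary", yn)

  cb <- list(
    age = num_var("years"),
    gender = cat_var("binary", c("female", "male")),
    income = cat_var("ordinal-categorical", c(
      "< SGD2000", "SGD2000 to < SGD4000", "SGD4000 to < SGD6000", ">= SGD6000"
    ), units = "SGD bands"),
    housing = cat_var("nominal-categorical", c(
      "HDB", "Condominium/Private apartments", "Landed property"
    )),
    born_in_singapore = binary(),
    years_in_singapore = num_var("years"),
    drug_allergy = binary(),
    physical_activity = cat_var("ordinal-categorical", freq3),
    screen_time = cat_var("ordinal-categorical", c(
      "less than 1 h", "1 to 3 h", "more than 3 to 5 h", "more than 5 h"
    ), units = "hours/day"),
    alcohol = cat_var("ordinal-categorical", c("never", "occasionally", "frequently")),
    smoking = cat_var("nominal-categorical", c("non-smoker", "ex-smoker", "current smoker")),
    secondhand_smoke = binary(),
    ever_pets = binary(),
    ever_asthma = binary(),
    wheeze_12m = binary(),
    exercise_wheeze_12m = binary(),
    dry_night_cough_12m = binary(),
    exacerbation_12m = binary(),
    spt_blo_mm = num_var("mm"),
    spt_der_mm = num_var("mm"),
    spt_hist_mm = num_var("mm"),
    spt_saline_mm = num_var("mm")
  )

  for (rel in c("maternal", "paternal", "sibling")) {
    for (dis in c("ad", "ar", "asthma")) {
      cb[[paste(rel, dis, sep = "_")]] <- binary()
    }
  }
  cb$parental_asthma <- binary()

  for (f in food_groups()) {
    cb[[paste0("food_", f)]] <- cat_var("ordinal-categorical", freq3)
  }

  structure(cb, class = "codebook")
}

#' The 16 food groups of the dietary block
#'
#' @return Character vector of food-group identifiers; cohort columns are
#'   named `food_<group>`.
#' @export
food_groups <- function() {
  c(
    "meat", "seafood", "fruits", "vegetables", "pulses", "cereals", "pasta",
    "rice", "butter", "margarine", "nuts", "potatoes", "milk", "eggs",
    "fastfood", "probiotic"
  )
}

#' Read a codebook from a YAML or JSON configuration file
#'
#' The file maps variable names to definitions with fields `kind`, `levels`,
#' `reference` (defaults to the first level), and optional `units`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `"codebook"` object.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("codebook file not found: '%s'", path), call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cb <- lapply(raw, function(v) {
    list(
      kind = v$kind %||% if (is.null(v$levels)) "numeric" else "nominal-categorical",
      levels = if (is.null(v$levels)) NULL else as.character(v$levels),
      reference = v$reference %||% if (is.null(v$levels)) NULL else as.character(v$levels)[1],
      units = v$units %||% NULL
    )
  })
  validate_codebook(structure(cb, class = "codebook"))
}

validate_codebook <- function(cb) {
  for (nm in names(cb)) {
    v <- cb[[nm]]
    if (!is.null(v$levels)) {
      if (anyDuplicated(norm_label(v$levels))) {
        stop(sprintf("codebook variable '%s' has duplicate levels", nm), call. = FALSE)
      }
      if (!norm_label(v$reference) %in% norm_label(v$levels)) {
        stop(sprintf(
          "codebook variable '%s': reference '%s' is not among its levels",
          nm, v$reference
        ), call. = FALSE)
      }
    }
  }
  cb
}

#' Change a variable's reference level
#'
#' @param codebook A `"codebook"` object.
#' @param variable Variable name.
#' @param reference New reference level (must be one of the variable's levels).
#' @return The modified codebook.
#' @export
set_reference <- function(codebook, variable, reference) {
  if (is.null(codebook[[variable]])) {
    stop(sprintf("unknown codebook variable '%s'", variable), call. = FALSE)
  }
  lv <- codebook[[variable]]$levels
  ref <- match_levels(reference, lv, column = variable)
  codebook[[variable]]$reference <- ref
  codebook
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("Questionnaire codebook: %d variables\n", length(x)))
  kinds <- vapply(x, `[[`, "", "kind")
  for (k in unique(kinds)) {
    cat(sprintf("  %-20s %d\n", k, sum(kinds == k)))
  }
  invisible(x)
}
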