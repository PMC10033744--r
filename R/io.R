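#' Read a subject-level cohort file
#'
#' Reads a delimited text file with one row per subject and a header of
#' variable names, validates every categorical cell against the codebook
#' (case-insensitively, after whitespace normalization), converts numeric
#' columns, and attaches a per-variable missing-count summary. A single
#' missing token (default: the empty string) marks missing data in the file;
#' internally missing values are `NA`, never a sentinel number, because
#' per-variable missingness is reported alongside every analysis.
#'
#' Columns not present in the codebook are preserved as-is but ignored by the
#' analysis stages. A `subject_id` column is required to be unique; if
#' absent, sequential identifiers are generated.
#'
#' @param path Path to the delimited file (UTF-8, header row).
#' @param codebook A `"codebook"` object; defaults to [default_codebook()].
#' @param missing_token String marking missing cells (default `""`).
#' @param delim Field delimiter (default `","`).
#' @return A `data.frame` with class `"cohort"`, carrying attributes
#'   `codebook`, `provenance`, and `missing_counts` (named integer vector).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("subject_id,gender,food_pulses",
#'              "s1,female,once or twice per week",
#'              "s2,Male,", "s3,female,never or only occasionally"), f)
#' ch <- read_cohort(f)
#' attr(ch, "missing_counts")[["food_pulses"]]
#' @export
read_cohort <- function(path, codebook = default_codebook(),
                        missing_token = "", delim = ",") {
  if (!file.exists(path)) {
    stop(sprintf("cannot read cohort file: '%s' (no such file)", path), call. = FALSE)
  }
  raw <- utils::read.table(
    path, header = TRUE, sep = delim, colClasses = "character",
    check.names = FALSE, quote = "\"", comment.char = "",
    na.strings = NULL, fileEncoding = "UTF-8"
  )
  for (j in seq_along(raw)) {
    raw[[j]][raw[[j]] == missing_token] <- NA_character_
  }
  as_cohort(raw, codebook = codebook, provenance = path)
}

#' Validate and canonicalize a subject-level data frame as a cohort
#'
#' @param data A data.frame of coded answers (character or factor cells).
#' @param codebook A `"codebook"` object.
#' @param provenance Free-text origin (file path or simulation seed).
#' @return A `"cohort"` data.frame; see [read_cohort()].
#' @export
as_cohort <- function(data, codebook = default_codebook(), provenance = "in-memory") {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (is.null(data$subject_id)) {
    data$subject_id <- sprintf("S%06d", seq_len(nrow(data)))
  }
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id)) {
    stop("subject_id values must be unique", call. = FALSE)
  }

  shared <- intersect(names(data), names(codebook))
  for (v in shared) {
    def <- codebook[[v]]
    col <- data[[v]]
    if (def$kind == "numeric") {
      if (!is.numeric(col)) {
        chr <- as.character(col)
        num <- suppressWarnings(as.numeric(chr))
        bad <- which(!is.na(chr) & is.na(num))
        if (length(bad) > 0) {
          stop(sprintf(
            "invalid numeric value in column '%s', row %d: '%s'",
            v, bad[1], chr[bad[1]]
          ), call. = FALSE)
        }
        col <- num
      }
      data[[v]] <- col
    } else {
      data[[v]] <- match_levels(as.character(col), def$levels, column = v)
    }
  }

  miss <- vapply(data[shared], function(x) sum(is.na(x)), integer(1))
  structure(
    data,
    codebook = codebook,
    provenance = provenance,
    missing_counts = miss,
    class = c("cohort", "data.frame")
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Cohort: %d subjects, %d variables (%s)\n",
    nrow(x), ncol(x) - 1L, attr(x, "provenance")
  ))
  mc <- attr(x, "missing_counts")
  if (!is.null(mc) && any(mc > 0)) {
    top <- sort(mc[mc > 0], decreasing = TRUE)
    cat("Missing counts (top):",
        paste(sprintf("%s=%d", names(top)[seq_len(min(5, length(top)))],
                      top[seq_len(min(5, length(top)))]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a result table to a delimited file
#'
#' Writes a rectangular result table as comma-delimited UTF-8 with a header
#' row. Integers round-trip bit-identically; reals are written with enough
#' digits to round-trip to at least 12 significant digits.
#'
#' @param rows A non-empty data.frame (or coercible object).
#' @param path Output file path.
#' @param delim Field delimiter (default `","`).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, delim = ",") {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0 || ncol(rows) == 0) {
    stop("write_table: 'rows' must be non-empty", call. = FALSE)
  }
  ok <- tryCatch({
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    utils::write.table(rows, con, sep = delim, row.names = FALSE,
                       qmethod = "double")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop(sprintf("cannot write table to '%s': %s", path, conditionMessage(ok)),
         call. = FALSE)
  }
  invisible(path)
}
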