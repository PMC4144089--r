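#' Read a table of already-measured areas or volumes
#'
#' Supports the workflow where a clinician traced the regions in a DICOM
#' viewer and recorded the measurements by hand: a comma-separated file
#' ("." decimal point, UTF-8) with a header row naming, for the 2D mode,
#' `A1, A_prime1, B1, A2, A_prime2, B2, months` (areas in mm^2), or for
#' the 3D mode, `A1, A_prime1, C1, C_prime1, D1, A2, A_prime2, C2,
#' C_prime2, D2, months` (volumes in mm^3). An optional `subject_id`
#' column identifies rows (auto-numbered when absent); an optional
#' `group` column is carried through for cohort summaries.
#'
#' Validation per row: all measurements must be non-negative and finite
#' and `months` strictly positive. Duplicated `subject_id`s are always
#' an error. With `strict = TRUE` (default) any invalid row aborts with
#' a row-numbered message; with `strict = FALSE` invalid rows are
#' dropped with a warning listing them.
#'
#' @param path CSV file path.
#' @param mode `"2d"` or `"3d"` — selects the required column set.
#' @param strict Abort on invalid rows (`TRUE`) or drop them with a
#'   warning (`FALSE`).
#' @return A validated measurement tibble with a `subject_id` column.
#' @export
read_measurement_table <- function(path, mode = c("2d", "3d"),
                                   strict = TRUE) {
  mode <- arg_match(mode)
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "yrrta_io_error")
  }
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- required_measure_cols(mode)
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0L) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "yrrta_schema_error")
  }
  if (!"subject_id" %in% names(tbl)) {
    tbl$subject_id <- sprintf("S%03d", seq_len(nrow(tbl)))
  }
  tbl$subject_id <- as.character(tbl$subject_id)
  dup <- duplicated(tbl$subject_id)
  if (any(dup)) {
    abort(paste0("Duplicated subject_id(s): ",
                 paste(unique(tbl$subject_id[dup]), collapse = ", ")),
          class = "yrrta_validation_error")
  }
  meas_cols <- setdiff(need, "months")
  bad_reasons <- vapply(seq_len(nrow(tbl)), function(i) {
    m <- unlist(tbl[i, meas_cols])
    if (any(!is.finite(m))) return("non-finite measurement")
    if (any(m < 0)) return("negative measurement")
    mo <- tbl$months[i]
    if (!is.finite(mo) || mo <= 0) return("months must be > 0")
    ""
  }, character(1))
  bad <- which(bad_reasons != "")
  if (length(bad) > 0L) {
    msgs <- sprintf("row %d (subject_id %s): %s",
                    bad, tbl$subject_id[bad], bad_reasons[bad])
    if (strict) {
      abort(paste0("Invalid measurement row(s):\n  ",
                   paste(msgs, collapse = "\n  ")),
            class = "yrrta_validation_error")
    }
    warn(paste0("Dropping invalid row(s):\n  ",
                paste(msgs, collapse = "\n  ")),
         class = "yrrta_validation_warning")
    tbl <- tbl[-bad, , drop = FALSE]
  }
  keep <- intersect(c("subject_id", "group", need), names(tbl))
  as_tibble(tbl[, keep, drop = FALSE])
}

#' Write rate results (and classifications) to CSV or JSON
#'
#' Serializes every column of a results table, one record per row. An
#' undefined yrRTA (zero ventricular change) is written as the explicit
#' sentinel string `"NA"`, never as a number, in both formats.
#'
#' @param results Data frame, typically from [compute_rates()] or
#'   [classify_rates()]; may have zero rows.
#' @param path Output file path.
#' @param format `"csv"` or `"json"` (default inferred from the file
#'   extension, falling back to csv).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- arg_match(format, c("csv", "json"))
  results <- as_tibble(results)
  if (format == "csv") {
    tryCatch(readr::write_csv(results, path, na = "NA"),
             error = function(e) {
               abort(paste0("Cannot write: ", path), class = "yrrta_io_error")
             })
  } else {
    recs <- purrr::map(seq_len(nrow(results)), function(i) {
      rec <- as.list(results[i, ])
      purrr::map(rec, function(x) if (is.na(x)) "NA" else x)
    })
    tryCatch(jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA),
             error = function(e) {
               abort(paste0("Cannot write: ", path), class = "yrrta_io_error")
             })
  }
  invisible(path)
}

#' Read back a results file written by [write_results()]
#'
#' @param path CSV or JSON results file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   `NULL`.
#' @return Tibble of results; the `"NA"` sentinel in numeric columns
#'   becomes `NA`.
#' @export
read_results <- function(path, format = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "yrrta_io_error")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- arg_match(format, c("csv", "json"))
  if (format == "csv") {
    readr::read_csv(path, na = "NA", show_col_types = FALSE, progress = FALSE)
  } else {
    recs <- jsonlite::read_json(path)
    if (length(recs) == 0L) return(tibble())
    rows <- purrr::map(recs, function(rec) {
      as_tibble(purrr::map(rec, function(x) {
        if (identical(x, "NA")) NA else x
      }))
    })
    out <- bind_rows(rows)
    # columns that are numeric except for the NA sentinel come back numeric
    for (col in names(out)) {
      if (is.character(out[[col]])) {
        suppressWarnings(num <- as.numeric(out[[col]]))
        if (!any(is.na(num) & !is.na(out[[col]]))) out[[col]] <- num
      }
    }
    out
  }
}
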