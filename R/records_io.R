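#' Read longitudinal measurement records from CSV
#'
#' Reads a long-format CSV of repeated continuous measurements, one row per
#' observation. The expected columns are `subject_id`, `variable`, `time`
#' (decimal years; the scores depend only on time intervals, so any origin
#' works -- age in years is the conventional choice), `value` (in the
#' variable's native unit, e.g. inches for height, pounds for weight) and an
#' optional `record_id`. When `record_id` is absent it is generated as
#' `"<subject_id>:<row>"` using the 1-based data-row number, which makes
#' within-file identifiers reproducible.
#'
#' Rows whose time or value does not parse as a number are rejected with a
#' row-numbered warning; they are never silently dropped and never loaded.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping the canonical column
#'   names (`subject_id`, `variable`, `time`, `value`, `record_id`) to the
#'   column names used in the file, e.g. `c(subject_id = "PatientICN")`.
#' @return A `data.frame` with columns `subject_id`, `variable`, `time`,
#'   `value`, `record_id`. An empty file (header only) yields a zero-row
#'   data frame.
#' @seealso [write_records()], [group_series()]
#' @export
read_records <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         strip.white = TRUE)
  cols <- c(subject_id = "subject_id", variable = "variable",
            time = "time", value = "value", record_id = "record_id")
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), names(cols))
    if (length(bad) > 0) {
      stop("unknown schema keys: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    cols[names(schema)] <- schema
  }
  required <- cols[c("subject_id", "variable", "time", "value")]
  missing <- required[!required %in% names(raw)]
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(raw) == 0) {
    return(empty_records())
  }
  rec <- data.frame(
    subject_id = raw[[cols["subject_id"]]],
    variable   = raw[[cols["variable"]]],
    time       = suppressWarnings(as.numeric(raw[[cols["time"]]])),
    value      = suppressWarnings(as.numeric(raw[[cols["value"]]])),
    stringsAsFactors = FALSE
  )
  if (cols["record_id"] %in% names(raw)) {
    rec$record_id <- raw[[cols["record_id"]]]
  } else {
    rec$record_id <- paste0(rec$subject_id, ":", seq_len(nrow(rec)))
  }
  bad <- which(!is.finite(rec$time) | !is.finite(rec$value))
  if (length(bad) > 0) {
    warning(sprintf("rejected %d unparseable row(s) at data row(s): %s",
                    length(bad), paste(bad, collapse = ", ")),
            call. = FALSE)
    rec <- rec[-bad, , drop = FALSE]
    rownames(rec) <- NULL
  }
  if (anyDuplicated(rec$record_id)) {
    stop("duplicate record_id values in ", path, call. = FALSE)
  }
  rec
}

empty_records <- function() {
  data.frame(subject_id = character(), variable = character(),
             time = numeric(), value = numeric(),
             record_id = character(), stringsAsFactors = FALSE)
}

#' Write measurement (or scored) records to CSV
#'
#' Numeric columns are serialized with full double precision (up to 17
#' significant digits) so that a write/read round trip reproduces the values
#' bit-exactly.
#'
#' @param records A records data frame, optionally with appended score
#'   columns.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- vapply(out[[nm]], function(x) {
        if (is.na(x)) "" else format(x, digits = 17, scientific = FALSE)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Group records into per-subject, per-variable series
#'
#' Splits a records data frame into one series per (subject, variable) pair,
#' each sorted by time with ties broken by `record_id`. The ordering is
#' deterministic: any permutation of the input rows yields identical series.
#' Same-day (tied-time) measurements are retained.
#'
#' @param records A records data frame as returned by [read_records()].
#' @return A named list of data frames (names `"<subject_id>|<variable>"`),
#'   each carrying the class `subject_series` and sorted as described.
#' @export
group_series <- function(records) {
  if (nrow(records) == 0) return(structure(list(), names = character()))
  key <- paste(records$subject_id, records$variable, sep = "|")
  pieces <- split(records, key)
  lapply(pieces, function(df) {
    df <- df[order(df$time, df$record_id), , drop = FALSE]
    rownames(df) <- NULL
    class(df) <- c("subject_series", "data.frame")
    df
  })
}

#' Convert day counts to decimal years
#'
#' Helper for users whose timestamps are day offsets (e.g. days since birth or
#' since an index date); the scores depend only on time intervals.
#'
#' @param days Numeric vector of day counts.
#' @return `days / 365.25`, in decimal years.
#' @export
days_to_years <- function(days) {
  days / 365.25
}
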