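#' Plausible-range eligibility filter
#'
#' Keeps records whose value lies inside the variable's plausible range,
#' bounds inclusive (a boundary-valid measurement is kept). The default
#' ranges are 40--100 inches for height and 40--1000 pounds for weight.
#'
#' @param records Records data frame, all rows of the rule's variable.
#' @param rule A [variable_config()] (or any list with `low` and `high`).
#' @return A list with elements `kept` and `removed`; the two partition the
#'   input exhaustively and disjointly.
#' @export
apply_range_filter <- function(records, rule) {
  keep <- records$value >= rule$low & records$value <= rule$high
  list(kept = reset_rows(records[keep, , drop = FALSE]),
       removed = reset_rows(records[!keep, , drop = FALSE]))
}

#' Minimum-age eligibility filter
#'
#' Keeps records taken at or after `min_age`. The record `time` must encode
#' age in years for this filter to be meaningful.
#'
#' @param records Records data frame.
#' @param min_age Minimum age in years (default 17: kept iff age >= 17).
#' @return A list with elements `kept` and `removed`.
#' @export
apply_age_filter <- function(records, min_age = 17) {
  keep <- records$time >= min_age
  list(kept = reset_rows(records[keep, , drop = FALSE]),
       removed = reset_rows(records[!keep, , drop = FALSE]))
}

#' Same-day multiplicity filter
#'
#' Groups a series' records into same-day clusters (times equal within
#' `day_tolerance`, chained on consecutive sorted times) and removes every
#' record of any cluster larger than `max_same_day`: a variable measured more
#' than a few times on one day is most plausibly a computer entry error, and
#' there is no principled survivor to keep. Exactly `max_same_day` same-day
#' measurements are allowed.
#'
#' @param series A sorted `subject_series` data frame.
#' @param max_same_day Largest tolerated same-day count (default 3).
#' @param day_tolerance Half-day in years, so times recorded to day precision
#'   group together (default `0.5 / 365.25`).
#' @return A list with elements `kept` and `removed`.
#' @export
apply_same_day_rule <- function(series, max_same_day = 3,
                                day_tolerance = 0.5 / 365.25) {
  n <- nrow(series)
  if (n == 0) return(list(kept = series, removed = series))
  grp <- cumsum(c(TRUE, diff(series$time) > day_tolerance))
  sizes <- ave(grp, grp, FUN = length)
  keep <- sizes <= max_same_day
  list(kept = reset_rows(series[keep, , drop = FALSE]),
       removed = reset_rows(series[!keep, , drop = FALSE]))
}

#' Full preprocessing pipeline
#'
#' Applies, per variable, the plausible-range filter, the minimum-age filter
#' and the same-day multiplicity rule, in that order. The three criteria are
#' disjoint, so range and age ordering does not affect the kept set.
#'
#' @param records Records data frame (any mix of configured variables).
#' @param config Named list of [variable_config()] blocks; every variable
#'   present in `records` must have a block.
#' @param day_tolerance Passed to [apply_same_day_rule()].
#' @return A list with `kept` (ready for scoring) and `removed` (with a
#'   `reason` column: `"range"`, `"age"` or `"same_day"`).
#' @export
preprocess_records <- function(records, config = default_config(),
                               day_tolerance = 0.5 / 365.25) {
  vars <- unique(records$variable)
  kept_all <- list()
  removed_all <- list()
  for (v in vars) {
    rule <- config_for(config, v)
    sub <- records[records$variable == v, , drop = FALSE]
    r <- apply_range_filter(sub, rule)
    r$removed$reason <- rep("range", nrow(r$removed))
    a <- apply_age_filter(r$kept, rule$min_age)
    a$removed$reason <- rep("age", nrow(a$removed))
    series <- group_series(a$kept)
    sd_parts <- lapply(series, apply_same_day_rule,
                       max_same_day = rule$max_same_day,
                       day_tolerance = day_tolerance)
    kept <- do.call(rbind, c(lapply(sd_parts, `[[`, "kept"),
                             list(make.row.names = FALSE)))
    sd_removed <- do.call(rbind, c(lapply(sd_parts, `[[`, "removed"),
                                   list(make.row.names = FALSE)))
    if (is.null(sd_removed)) sd_removed <- empty_records()
    sd_removed$reason <- rep("same_day", nrow(sd_removed))
    class(sd_removed) <- "data.frame"
    kept_all[[v]] <- if (is.null(kept)) empty_records() else kept
    removed_all[[v]] <- rbind(r$removed, a$removed, sd_removed)
  }
  kept <- do.call(rbind, c(kept_all, list(make.row.names = FALSE)))
  removed <- do.call(rbind, c(removed_all, list(make.row.names = FALSE)))
  if (is.null(kept)) kept <- empty_records()
  if (is.null(removed) || nrow(removed) == 0) {
    removed <- cbind(empty_records(), reason = character())
  }
  class(kept) <- "data.frame"
  list(kept = reset_rows(kept), removed = reset_rows(removed))
}

reset_rows <- function(df) {
  rownames(df) <- NULL
  df
}

# rbind a list of data frames, ignoring NULL entries; NULL when none remain
rbind_rows <- function(lst) {
  lst <- Filter(Negate(is.null), lst)
  if (length(lst) == 0) return(NULL)
  do.call(rbind, c(lst, list(make.row.names = FALSE)))
}
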