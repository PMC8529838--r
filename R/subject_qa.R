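#' Subject-level QA summaries
#'
#' Aggregates record-level longitudinal flags into a per-subject decision:
#' the subject-level QA score is the proportion of scored measurements that
#' were flagged, and a subject is flagged when that proportion is STRICTLY
#' greater than `proportion_cutoff` ("more than 20%" leaves a subject at
#' exactly 20% unflagged). Records with undefined scores (single-measurement
#' subjects) are excluded from both numerator and denominator; a subject with
#' nothing scored gets an undefined proportion and is not flagged. The
#' flagged set is nonincreasing in the cutoff, so a 50% cutoff flags a subset
#' of the 20% one.
#'
#' @param scored A scored records data frame (columns `subject_id`,
#'   `variable`, `q_r`, `flag_r`).
#' @param proportion_cutoff Fraction in \[0, 1\]; default 0.20.
#' @return A data frame with one row per (subject, variable): `subject_id`,
#'   `variable`, `n_scored`, `n_flagged`, `proportion`, `subject_flagged`.
#' @export
summarize_subjects <- function(scored, proportion_cutoff = 0.20) {
  stopifnot(all(c("subject_id", "variable", "q_r", "flag_r") %in% names(scored)))
  if (proportion_cutoff < 0 || proportion_cutoff > 1) {
    stop("proportion_cutoff must be in [0, 1]", call. = FALSE)
  }
  key <- interaction(scored$subject_id, scored$variable, drop = TRUE, sep = "|")
  parts <- split(scored, key)
  rows <- lapply(parts, function(df) {
    ok <- !is.na(df$q_r)
    n_scored <- sum(ok)
    n_flagged <- sum(df$flag_r[ok])
    prop <- if (n_scored > 0) n_flagged / n_scored else NA_real_
    data.frame(subject_id = df$subject_id[1], variable = df$variable[1],
               n_scored = n_scored, n_flagged = n_flagged,
               proportion = prop,
               subject_flagged = isTRUE(prop > proportion_cutoff))
  })
  reset_rows(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
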