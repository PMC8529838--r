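#' Atemporal thresholding scores against a population reference
#'
#' The comparator score: each value is judged in isolation against population
#' reference statistics, ignoring the subject's history. The Z score is the
#' standardized distance from the reference mean and the score is its
#' two-sided normal p-value,
#' \deqn{Z_S = (y - \mu) / \sigma, \quad Q_S = 2(1 - \Phi(|Z_S|)),}
#' flagged when `Q_S <= cutoff`. The absolute value makes below-mean values
#' score symmetrically with above-mean ones.
#'
#' @param values Numeric vector of measurements, native units.
#' @param ref_mean Population reference mean.
#' @param ref_sd Population reference SD; must be positive.
#' @param cutoff Flagging cutoff in (0, 1); default 0.05.
#' @return A data frame with columns `z_s`, `q_s`, `flag_s`.
#' @export
qs_scores <- function(values, ref_mean, ref_sd, cutoff = 0.05) {
  if (!is.numeric(ref_sd) || length(ref_sd) != 1 || !is.finite(ref_sd) ||
      ref_sd <= 0) {
    stop("reference SD must be a positive number", call. = FALSE)
  }
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0,1)", call. = FALSE)
  z <- (values - ref_mean) / ref_sd
  q <- 2 * stats::pnorm(-abs(z))
  data.frame(z_s = z, q_s = q, flag_s = q <= cutoff)
}

#' Estimate population reference statistics from records
#'
#' Mean and sample SD of all values, unstratified by default; an optional
#' stratification column yields one set of statistics per stratum. A zero SD
#' is a degenerate reference (infinite Z for any off-mean value) and raises a
#' warning.
#'
#' @param records Records data frame (column `value`), or a numeric vector.
#' @param strata Optional name of a column in `records` to stratify by.
#' @return A list with `mean`, `sd`, `n` -- or, when `strata` is given, a
#'   named list of such lists, one per stratum.
#' @export
estimate_reference_stats <- function(records, strata = NULL) {
  values <- if (is.data.frame(records)) records$value else records
  if (!is.null(strata)) {
    stopifnot(is.data.frame(records), strata %in% names(records))
    parts <- split(records, records[[strata]])
    return(lapply(parts, estimate_reference_stats))
  }
  if (length(values) < 2) {
    stop("at least two records are required to estimate reference statistics",
         call. = FALSE)
  }
  s <- stats::sd(values)
  if (s == 0) {
    warning("degenerate reference: all values identical (SD = 0)",
            call. = FALSE)
  }
  list(mean = mean(values), sd = s, n = length(values))
}

#' Within-subject variance component (one-way random effects)
#'
#' Estimates the within-subject measurement variance `var_y` used to
#' standardize the EWMA deviation, from a one-way random-effects
#' decomposition with subject as the random intercept. The ANOVA
#' (method-of-moments) estimator is used -- deterministic and closed-form,
#' which is adequate for a tuning constant:
#' \deqn{MS_{within} = \frac{\sum_j \sum_i (y_{ij} - \bar y_j)^2}
#'                         {\sum_j (n_j - 1)}}
#' over subjects `j` with at least two measurements.
#'
#' @param records Records data frame with columns `subject_id` and `value`
#'   for a single variable.
#' @return The within-subject variance in squared native units. Zero (every
#'   subject constant) raises a degenerate-variance warning.
#' @export
estimate_within_variance <- function(records) {
  stopifnot(is.data.frame(records), all(c("subject_id", "value") %in% names(records)))
  parts <- split(records$value, records$subject_id)
  nj <- lengths(parts)
  usable <- nj >= 2
  if (!any(usable)) {
    stop("no subject has at least two measurements", call. = FALSE)
  }
  ss <- vapply(parts[usable], function(y) sum((y - mean(y))^2), numeric(1))
  ms_within <- sum(ss) / sum(nj[usable] - 1)
  if (ms_within == 0) {
    warning("degenerate within-subject variance: every subject is constant",
            call. = FALSE)
  }
  ms_within
}
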