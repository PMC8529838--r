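#' Heuristic for the EWMA decay scale tau
#'
#' Chooses the decay scale so that a neighboring observation `xi_months` away
#' still carries a dependency (weight) of `omega`:
#' \deqn{\tau = -\frac{\xi/12}{\log(\omega)}}
#' with the natural logarithm, `xi` in months and `tau` in years. For a
#' stable quantity like adult height, 90% dependency at a 12-month gap gives
#' `tau = 9.49`; for a labile one like weight, 90% at half a month gives
#' `tau = 0.4` (the shipped weight default uses the optimized 0.5 instead).
#'
#' @param omega Desired dependency on a neighbor `xi_months` away, in (0, 1).
#' @param xi_months Gap in months at which that dependency should hold; > 0.
#' @return The decay scale tau in years; strictly increasing in both
#'   arguments.
#' @examples
#' heuristic_tau(0.9, 12)   # 9.49
#' heuristic_tau(0.9, 0.5)  # 0.40
#' @export
heuristic_tau <- function(omega, xi_months) {
  if (!is.numeric(omega) || any(omega <= 0) || any(omega >= 1)) {
    stop("omega must be in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(xi_months) || any(xi_months <= 0)) {
    stop("xi_months must be positive", call. = FALSE)
  }
  -(xi_months / 12) / log(omega)
}

#' Exponential decay weight between two time points
#'
#' The weight a measurement at `t_j` contributes to the EWMA centered at
#' `t_i`: 1 for the index measurement itself, `exp(-|t_j - t_i| / tau)`
#' otherwise. Symmetric in its time arguments; a same-timestamp neighbor gets
#' `exp(0) = 1`, identical to the self weight.
#'
#' @param t_j,t_i Times in decimal years (vectorized).
#' @param tau Decay scale in years; > 0.
#' @param is_self Logical; `TRUE` for the index measurement itself.
#' @return Weight(s) in (0, 1].
#' @examples
#' decay_weight(2, 0, tau = 9.49)  # 0.81
#' decay_weight(5, 0, tau = 9.49)  # 0.59
#' @export
decay_weight <- function(t_j, t_i, tau, is_self = FALSE) {
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be positive", call. = FALSE)
  w <- exp(-abs(t_j - t_i) / tau)
  w[rep_len(is_self, length(w))] <- 1
  w
}

#' EWMA estimate for one measurement in a series
#'
#' The exponentially weighted moving average for the i-th measurement is the
#' weighted mean over the ENTIRE sequence (including the index measurement
#' itself, with weight 1):
#' \deqn{\bar y_{i} = \sum_j w_j y_j / \sum_j w_j}
#' As a convex combination, the result always lies within the range of the
#' observed values.
#'
#' @param series A `subject_series` data frame (columns `time`, `value`).
#' @param i Index of the target measurement, 1-based.
#' @param tau Decay scale in years.
#' @return The EWMA estimate in the variable's native unit.
#' @export
compute_ewma <- function(series, i, tau) {
  n <- nrow(series)
  if (n < 1) stop("series is empty", call. = FALSE)
  if (i < 1 || i > n) stop("index out of range", call. = FALSE)
  w <- decay_weight(series$time, series$time[i], tau)
  w[i] <- 1
  sum(w * series$value) / sum(w)
}

#' Variance factor of the EWMA deviation
#'
#' The deviation `d_i = |y_i - ewma_i|` has, for independent measurements
#' with common variance `var_y`, variance `factor * var_y`. Writing
#' `W = sum(w)` and `S2 = sum(w^2)`, the `"derived"` variant returns
#' \deqn{S2/W^2 - 2 w_i/W + 1,}
#' which is the exact variance multiplier of the linear combination
#' `ewma_i - y_i` (coefficients `w_j/W - 1[j = i]`, whose squares sum to this
#' expression). The `"paper"` variant flips the middle sign to
#' `S2/W^2 + 2 w_i/W + 1`; it is retained for literal reproduction of the
#' published formula but does not match the simulated variance of the
#' deviation (see the package tests). The standard error of `d_i` is
#' `sqrt(factor * var_y)`.
#'
#' @param weights Weight vector for one target index, with `weights[i] = 1`.
#' @param i Target index.
#' @param variant `"derived"` (default) or `"paper"`.
#' @return The positive variance factor.
#' @export
deviation_variance_factor <- function(weights, i,
                                      variant = c("derived", "paper")) {
  variant <- match.arg(variant)
  if (length(weights) < 2) {
    stop("at least two measurements are required", call. = FALSE)
  }
  W <- sum(weights)
  S2 <- sum(weights^2)
  s <- if (variant == "paper") 2 else -2
  S2 / W^2 + s * weights[i] / W + 1
}

#' Longitudinal plausibility scores for one series
#'
#' For each measurement in a subject's series, computes the EWMA estimate,
#' the absolute deviation `d`, its standard error, the Z score `d / SE(d)`
#' and the two-sided normal p-value
#' \deqn{Q_R = 2(1 - \Phi(Z)),}
#' flagging the record when `Q_R <= cutoff`. A measurement is questionable
#' when it is inconsistent with the subject's own history; the number of
#' repeats and the time gaps between them drive the assessment through the
#' decay weights.
#'
#' At least two measurements are required. A single-measurement series is
#' returned with all scores missing, `flag_r = FALSE` and status
#' `"insufficient_history"`; it is never flagged.
#'
#' @param series A sorted `subject_series` data frame.
#' @param tau Decay scale in years.
#' @param var_y Assumed within-subject measurement variance, squared native
#'   units; > 0.
#' @param cutoff Flagging cutoff in (0, 1); default 0.05.
#' @param variance_variant See [deviation_variance_factor()].
#' @return The series with appended columns `ewma`, `d`, `se_d`, `z_r`,
#'   `q_r`, `flag_r`, `status`.
#' @export
qr_scores <- function(series, tau, var_y, cutoff = 0.05,
                      variance_variant = c("derived", "paper")) {
  variance_variant <- match.arg(variance_variant)
  if (!is.numeric(var_y) || var_y <= 0) stop("var_y must be positive", call. = FALSE)
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be in (0,1)", call. = FALSE)
  n <- nrow(series)
  out <- as.data.frame(series)
  if (n < 2) {
    out$ewma <- NA_real_; out$d <- NA_real_; out$se_d <- NA_real_
    out$z_r <- NA_real_; out$q_r <- NA_real_
    out$flag_r <- FALSE
    out$status <- rep("insufficient_history", n)
    return(out)
  }
  t <- series$time
  y <- series$value
  W <- exp(-abs(outer(t, t, "-")) / tau)
  diag(W) <- 1                       # self weight; exp(0)=1 anyway
  Wsum <- rowSums(W)
  ewma <- as.vector(W %*% y) / Wsum
  S2 <- rowSums(W^2)
  s <- if (variance_variant == "paper") 2 else -2
  fac <- S2 / Wsum^2 + s / Wsum + 1  # w_i = 1 at the target index
  se <- sqrt(fac * var_y)
  d <- abs(y - ewma)
  z <- d / se
  q <- 2 * stats::pnorm(-z)
  out$ewma <- ewma
  out$d <- d
  out$se_d <- se
  out$z_r <- z
  out$q_r <- q
  out$flag_r <- q <= cutoff
  out$status <- rep("scored", n)
  out
}

#' Score a preprocessed cohort with both QA scores
#'
#' Runs the longitudinal (EWMA) score per subject series and the atemporal
#' thresholding score per variable, appending the scored-output columns
#' `ewma`, `d`, `se_d`, `z_r`, `q_r`, `z_s`, `q_s`, `flag_r`, `flag_s` (plus
#' `status`). When a variable's `var_y` is `NULL` it is estimated from the
#' data with [estimate_within_variance()]; when `ref_mean`/`ref_sd` are
#' `NULL` they are estimated with [estimate_reference_stats()].
#'
#' @param records Preprocessed records data frame.
#' @param config Named list of [variable_config()] blocks covering every
#'   variable present.
#' @return A scored records data frame, one row per input record.
#' @export
score_records <- function(records, config = default_config()) {
  vars <- unique(records$variable)
  scored <- lapply(vars, function(v) {
    cfg <- config_for(config, v)
    sub <- records[records$variable == v, , drop = FALSE]
    var_y <- cfg$var_y
    if (is.null(var_y)) var_y <- estimate_within_variance(sub)
    series <- group_series(sub)
    qr <- do.call(rbind, c(lapply(series, qr_scores, tau = cfg$tau,
                                  var_y = var_y, cutoff = cfg$cutoff,
                                  variance_variant = cfg$variance_variant),
                           list(make.row.names = FALSE)))
    if (is.null(cfg$ref_mean) || is.null(cfg$ref_sd)) {
      ref <- estimate_reference_stats(sub)
    } else {
      ref <- list(mean = cfg$ref_mean, sd = cfg$ref_sd)
    }
    qs <- qs_scores(qr$value, ref_mean = ref$mean, ref_sd = ref$sd,
                    cutoff = cfg$cutoff)
    qr$z_s <- qs$z_s
    qr$q_s <- qs$q_s
    qr$flag_s <- qs$flag_s
    qr
  })
  reset_rows(do.call(rbind, c(scored, list(make.row.names = FALSE))))
}
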