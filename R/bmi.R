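#' Pair same-day height and weight records
#'
#' BMI is computed only when height and weight were measured on the same day.
#' For every weight record, the same-day height records of the same subject
#' are located (times equal within `day_tolerance`); when several heights
#' survive preprocessing on one day, the first by `record_id` is used, giving
#' one deterministic BMI candidate per (weight record, day).
#'
#' @param records Records data frame containing `height` and `weight` rows
#'   (preprocessed).
#' @param day_tolerance Same-day tolerance in years (default `0.5 / 365.25`).
#' @return A data frame of pairs: `subject_id`, `time` (the weight record's
#'   time), `height`, `weight`, `height_record_id`, `weight_record_id`.
#' @export
pair_same_day <- function(records, day_tolerance = 0.5 / 365.25) {
  h <- records[records$variable == "height", , drop = FALSE]
  w <- records[records$variable == "weight", , drop = FALSE]
  empty <- data.frame(subject_id = character(), time = numeric(),
                      height = numeric(), weight = numeric(),
                      height_record_id = character(),
                      weight_record_id = character(),
                      stringsAsFactors = FALSE)
  if (nrow(h) == 0 || nrow(w) == 0) return(empty)
  h <- h[order(h$subject_id, h$record_id), , drop = FALSE]
  rows <- lapply(split(w, w$subject_id), function(wsub) {
    hsub <- h[h$subject_id == wsub$subject_id[1], , drop = FALSE]
    if (nrow(hsub) == 0) return(NULL)
    out <- lapply(seq_len(nrow(wsub)), function(k) {
      hit <- which(abs(hsub$time - wsub$time[k]) <= day_tolerance)
      if (length(hit) == 0) return(NULL)
      j <- hit[order(hsub$record_id[hit])][1]
      data.frame(subject_id = wsub$subject_id[k], time = wsub$time[k],
                 height = hsub$value[j], weight = wsub$value[k],
                 height_record_id = hsub$record_id[j],
                 weight_record_id = wsub$record_id[k],
                 stringsAsFactors = FALSE)
    })
    rbind_rows(out)
  })
  out <- rbind_rows(rows)
  if (is.null(out)) empty else reset_rows(out)
}

#' Body mass index from inches and pounds
#'
#' `bmi = 703 * weight / height^2`, the standard conversion from pounds and
#' inches to kg/m².
#'
#' @param height Height in inches; must be positive.
#' @param weight Weight in pounds.
#' @return BMI in kg/m². Vectorized.
#' @export
compute_bmi <- function(height, weight) {
  if (any(height <= 0)) stop("height must be positive", call. = FALSE)
  703 * weight / height^2
}

#' WHO-based BMI classes
#'
#' Four classes with the obese groups overlapping by construction (class
#' III is a subset of class I/II/III when used as "ever in class" indicators;
#' here the classifier assigns the finest bucket): underweight (< 18.5),
#' normal to overweight (18.5 to < 30), obese class I/II/III (30 to < 40),
#' obese class III (>= 40).
#'
#' @param bmi Numeric BMI values, kg/m².
#' @return Character vector with levels `underweight`,
#'   `normal_to_overweight`, `obese_I_II_III`, `obese_III`.
#' @export
classify_bmi <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 0)) {
    stop("bmi must be finite and positive", call. = FALSE)
  }
  cls <- character(length(bmi))
  cls[bmi < 18.5] <- "underweight"
  cls[bmi >= 18.5 & bmi < 30] <- "normal_to_overweight"
  cls[bmi >= 30 & bmi < 40] <- "obese_I_II_III"
  cls[bmi >= 40] <- "obese_III"
  cls
}

bmi_class_levels <- function() {
  c("underweight", "normal_to_overweight", "obese_I_II_III", "obese_III")
}

#' Drop BMI pairs flagged by a QA regime
#'
#' Under regime `"none"` all pairs are usable. Under `"threshold"` a pair is
#' dropped when either component record has `q_s <= cutoff`; under
#' `"longitudinal"` when either has `q_r <= cutoff`. A stricter (larger)
#' cutoff never increases the number of usable pairs.
#'
#' @param pairs Output of [pair_same_day()].
#' @param scored Scored records data frame covering the paired records.
#' @param regime One of `"none"`, `"threshold"`, `"longitudinal"`.
#' @param cutoff Score cutoff; default 0.05.
#' @return The usable subset of `pairs`.
#' @export
qa_regime_filter <- function(pairs, scored,
                             regime = c("none", "threshold", "longitudinal"),
                             cutoff = 0.05) {
  regime <- match.arg(regime)
  if (regime == "none") return(pairs)
  col <- if (regime == "threshold") "q_s" else "q_r"
  if (!col %in% names(scored)) {
    stop("scores for regime '", regime, "' are not available", call. = FALSE)
  }
  q <- scored[[col]]
  names(q) <- scored$record_id
  qh <- q[pairs$height_record_id]
  qw <- q[pairs$weight_record_id]
  if (anyNA(match(pairs$height_record_id, scored$record_id)) ||
      anyNA(match(pairs$weight_record_id, scored$record_id))) {
    stop("paired records missing from the scored table", call. = FALSE)
  }
  # undefined scores (single-measurement series) are never flagged
  drop <- (!is.na(qh) & qh <= cutoff) | (!is.na(qw) & qw <= cutoff)
  reset_rows(pairs[!drop, , drop = FALSE])
}

#' Per-subject "ever in class" indicators and cohort proportions
#'
#' A subject counts once for every class any of their BMI values ever falls
#' into, so the class indicators are non-exclusive and the cohort proportions
#' need not sum to 1.
#'
#' @param bmi_records Data frame with columns `subject_id` and `bmi` (e.g.
#'   pairs from [pair_same_day()] with a `bmi` column added).
#' @return A list with `by_subject` (logical matrix, subjects x classes) and
#'   `proportion` (named numeric vector: fraction of subjects ever in each
#'   class).
#' @export
ever_in_class <- function(bmi_records) {
  stopifnot(all(c("subject_id", "bmi") %in% names(bmi_records)))
  lev <- bmi_class_levels()
  cls <- classify_bmi(bmi_records$bmi)
  subjects <- unique(bmi_records$subject_id)
  by_subject <- matrix(FALSE, nrow = length(subjects), ncol = length(lev),
                       dimnames = list(subjects, lev))
  for (k in seq_along(lev)) {
    hit <- unique(bmi_records$subject_id[cls == lev[k]])
    by_subject[hit, k] <- TRUE
  }
  list(by_subject = by_subject,
       proportion = colMeans(by_subject))
}

#' BMI class proportions under the three QA regimes
#'
#' Convenience wrapper reproducing the use-case comparison: same-day pairing,
#' BMI computation, then per-subject ever-in-class proportions with no QA,
#' with thresholding QA and with longitudinal QA (each regime dropping pairs
#' whose height or weight score falls at or below `cutoff`).
#'
#' @param records Preprocessed records containing height and weight.
#' @param scored Scored records (from [score_records()]).
#' @param cutoff Score cutoff; default 0.05.
#' @param day_tolerance Same-day tolerance in years.
#' @return A data frame: one row per BMI class, columns `none`, `threshold`,
#'   `longitudinal` holding the ever-in-class proportions, plus an
#'   `n_usable` attribute with the usable pair counts per regime.
#' @export
bmi_table <- function(records, scored, cutoff = 0.05,
                      day_tolerance = 0.5 / 365.25) {
  pairs <- pair_same_day(records, day_tolerance)
  regimes <- c("none", "threshold", "longitudinal")
  props <- list()
  n_usable <- integer(length(regimes))
  names(n_usable) <- regimes
  for (r in regimes) {
    usable <- qa_regime_filter(pairs, scored, regime = r, cutoff = cutoff)
    n_usable[r] <- nrow(usable)
    if (nrow(usable) == 0) {
      props[[r]] <- stats::setNames(rep(NA_real_, 4), bmi_class_levels())
      next
    }
    usable$bmi <- compute_bmi(usable$height, usable$weight)
    props[[r]] <- ever_in_class(usable)$proportion
  }
  out <- data.frame(class = bmi_class_levels(),
                    none = props$none, threshold = props$threshold,
                    longitudinal = props$longitudinal,
                    row.names = NULL)
  attr(out, "n_usable") <- n_usable
  out
}
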