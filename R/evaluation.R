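#' Confusion metrics of error flagging against ground truth
#'
#' "Positive" means flagged-as-error. False positive rate `fp/(fp+tn)`,
#' power (sensitivity) `tp/(tp+fn)`, positive predictive value `tp/(tp+fp)`
#' and negative predictive value `tn/(tn+fn)`; any rate with a zero
#' denominator is reported as `NA`, never coerced to 0.
#'
#' @param flags Logical vector: record flagged as an error.
#' @param truth Ground truth: either a logical vector aligned with `flags`,
#'   or a labels data frame (`record_id`, `is_error`), in which case
#'   `record_ids` must give the record ids of `flags`.
#' @param record_ids Optional record ids aligned with `flags`, required when
#'   `truth` is a labels data frame; mismatched ids are an error.
#' @return A list of class `confusion_metrics`: `tp`, `fp`, `tn`, `fn`,
#'   `fpr`, `power`, `ppv`, `npv`, `fdr` (= 1 - ppv).
#' @export
confusion_metrics <- function(flags, truth, record_ids = NULL) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("record_id", "is_error") %in% names(truth)))
    if (is.null(record_ids)) {
      stop("record_ids are required to align flags with labels", call. = FALSE)
    }
    pos <- match(record_ids, truth$record_id)
    if (anyNA(pos)) stop("flags contain record ids absent from the labels",
                         call. = FALSE)
    truth <- truth$is_error[pos]
  }
  stopifnot(is.logical(flags), is.logical(truth),
            length(flags) == length(truth))
  ok <- !is.na(flags) & !is.na(truth)
  flags <- flags[ok]; truth <- truth[ok]
  tp <- sum(flags & truth); fp <- sum(flags & !truth)
  tn <- sum(!flags & !truth); fn <- sum(!flags & truth)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 fpr = rate(fp, fp + tn), power = rate(tp, tp + fn),
                 ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
                 fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  FPR=%.4f power=%.4f PPV=%.4f NPV=%.4f\n",
              x$fpr, x$power, x$ppv, x$npv))
  invisible(x)
}

#' ROC sweep over score cutoffs
#'
#' Flags records at each cutoff (`q <= cutoff`), computes the (FPR, TPR)
#' point per cutoff, and the trapezoidal AUC over the curve anchored at
#' (0, 0) and (1, 1). The default grid spans the p-value scale densely and
#' always includes the conventional reporting cutoffs 0.01 and 0.05.
#'
#' @param q Numeric vector of score p-values.
#' @param truth Logical ground truth aligned with `q` (or labels data frame
#'   plus `record_ids`, as in [confusion_metrics()]).
#' @param cutoffs Cutoff grid; 0.01 and 0.05 are appended if absent.
#' @param record_ids Optional, see [confusion_metrics()].
#' @return A list of class `roc_sweep`: `points` (data frame `cutoff`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_sweep <- function(q, truth, cutoffs = NULL, record_ids = NULL) {
  if (is.data.frame(truth)) {
    stopifnot(all(c("record_id", "is_error") %in% names(truth)))
    pos <- match(record_ids, truth$record_id)
    if (anyNA(pos)) stop("record ids absent from the labels", call. = FALSE)
    truth <- truth$is_error[pos]
  }
  ok <- !is.na(q) & !is.na(truth)
  q <- q[ok]; truth <- truth[ok]
  if (!any(truth) || all(truth)) {
    stop("degenerate truth: need at least one error and one clean record",
         call. = FALSE)
  }
  if (is.null(cutoffs)) {
    cutoffs <- sort(unique(c(10^seq(-12, 0, length.out = 200), 0.01, 0.05)))
  } else {
    cutoffs <- sort(unique(c(cutoffs, 0.01, 0.05)))
  }
  pts <- t(vapply(cutoffs, function(ct) {
    flag <- q <= ct
    c(fpr = sum(flag & !truth) / sum(!truth),
      tpr = sum(flag & truth) / sum(truth))
  }, c(fpr = 0, tpr = 0)))
  points <- data.frame(cutoff = cutoffs, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
  x <- c(0, points$fpr, 1)
  y <- c(0, points$tpr, 1)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_sweep")
}

#' @export
print.roc_sweep <- function(x, ...) {
  cat(sprintf("ROC sweep over %d cutoffs; AUC = %.4f\n",
              nrow(x$points), x$auc))
  invisible(x)
}

#' Grid search over tau and var_y for the longitudinal score
#'
#' Scores the labeled records of one variable at every (tau, var_y) grid
#' point and tabulates the confusion metrics at the given cutoff. The
#' selected optimum maximizes power subject to a false-discovery-rate bound
#' (FDR = 1 - PPV <= `fdr_max`); grid points whose FDR is undefined (no
#' positive calls) are not eligible.
#'
#' @param records Preprocessed records of a single variable.
#' @param labels Labels data frame (`record_id`, `is_error`).
#' @param tau_grid,var_grid Positive numeric grids; must be non-empty.
#' @param cutoff Flagging cutoff; default 0.05.
#' @param fdr_max FDR bound for the selection criterion; default 0.2.
#' @param variance_variant See [deviation_variance_factor()].
#' @return A data frame with one row per grid point (`tau`, `var_y`, `tp`,
#'   `fp`, `tn`, `fn`, `fpr`, `power`, `ppv`, `npv`, `fdr`, `selected`).
#' @export
parameter_sweep <- function(records, labels, tau_grid, var_grid,
                            cutoff = 0.05, fdr_max = 0.2,
                            variance_variant = c("derived", "paper")) {
  variance_variant <- match.arg(variance_variant)
  if (length(tau_grid) == 0 || length(var_grid) == 0) {
    stop("tau_grid and var_grid must be non-empty", call. = FALSE)
  }
  if (length(unique(records$variable)) != 1) {
    stop("parameter_sweep expects records of a single variable", call. = FALSE)
  }
  truth_all <- labels$is_error[match(records$record_id, labels$record_id)]
  if (anyNA(truth_all)) stop("records contain ids absent from the labels",
                             call. = FALSE)
  if (!any(truth_all)) {
    stop("labels contain no errors: nothing to detect", call. = FALSE)
  }
  grid <- expand.grid(tau = tau_grid, var_y = var_grid,
                      KEEP.OUT.ATTRS = FALSE)
  series <- group_series(records)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    scored <- do.call(rbind, c(
      lapply(series, qr_scores, tau = grid$tau[g], var_y = grid$var_y[g],
             cutoff = cutoff, variance_variant = variance_variant),
      list(make.row.names = FALSE)))
    cm <- confusion_metrics(scored$flag_r[!is.na(scored$q_r)],
                            labels, scored$record_id[!is.na(scored$q_r)])
    data.frame(tau = grid$tau[g], var_y = grid$var_y[g],
               tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
               fpr = cm$fpr, power = cm$power, ppv = cm$ppv, npv = cm$npv,
               fdr = cm$fdr)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  eligible <- !is.na(out$fdr) & out$fdr <= fdr_max & !is.na(out$power)
  out$selected <- FALSE
  if (any(eligible)) {
    best <- which(eligible)[which.max(out$power[eligible])]
    out$selected[best] <- TRUE
  }
  out
}
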