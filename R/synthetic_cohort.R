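#' Error-injection model for synthetic cohorts
#'
#' Four mechanisms chosen to emulate the phenomenology of real entry errors,
#' in particular errors whose values look unremarkable at the population
#' level and are only implausible against the subject's own history:
#' \describe{
#'   \item{unit}{a value recorded in the wrong unit system: height
#'     multiplied by 2.54 (cm-for-inch confusion); weight multiplied or
#'     divided by 2.2046 (kg/lb confusion), each direction equally likely.}
#'   \item{digit}{a typing slip on the integer part: two adjacent digits
#'     transposed, or a digit dropped or inserted.}
#'   \item{gross}{replacement with a uniform draw over the variable's
#'     plausible range (so the range filter alone cannot remove it).}
#'   \item{wrong_patient}{replacement with another random subject's value
#'     nearest in time -- a record filed to the wrong chart.}
#' }
#'
#' @param rate Fraction of records corrupted, in \[0, 1).
#' @param probs Named relative probabilities for mechanisms `unit`, `digit`,
#'   `gross`, `wrong_patient`; normalized to sum to 1.
#' @return A list of class `error_model`.
#' @export
error_model <- function(rate = 0.05,
                        probs = c(unit = 0.25, digit = 0.25,
                                  gross = 0.25, wrong_patient = 0.25)) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  need <- c("unit", "digit", "gross", "wrong_patient")
  if (!all(need %in% names(probs))) {
    stop("probs must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  probs <- probs[need] / sum(probs[need])
  structure(list(rate = rate, probs = probs), class = "error_model")
}

#' Specification of a synthetic longitudinal height/weight cohort
#'
#' Defaults describe an adult cohort followed for about 12 years (SD 5) with
#' a median of 2 height and 3 weight measurements per year; heights are
#' stable per subject over adult follow-up, weights drift slowly as a
#' Gaussian random walk. True heights are Normal(69, 3) inches. Baseline
#' weights follow a two-component mixture -- a typical subpopulation
#' Normal(185, 30) pounds and, with probability `obese_fraction`, an obese
#' subpopulation Normal(285, 45) -- because adult weight is right-skewed and
#' stable heavy subjects are exactly the patients an atemporal population
#' threshold misjudges; a single Gaussian would erase that feature of real
#' cohorts. Within-subject measurement SDs default to 0.6 inches and 6
#' pounds -- the scale of real stadiometer/scale noise plus clothing and
#' time-of-day variation. The scoring default `var_y = 210` squared pounds
#' is a deliberately conservative tuning constant, several times this noise
#' variance; setting `within_sd` to `sqrt(var_y)` instead yields an exactly
#' calibrated score (clean-data flag rate equal to the cutoff), which is how
#' the calibration tests use this generator.
#'
#' @param n_subjects Number of subjects; >= 1.
#' @param years_followup_mean,years_followup_sd Follow-up length (years).
#' @param visits_per_year Named vector: mean visits/year for `height` and
#'   `weight`.
#' @param height_mean,height_sd Population distribution of true adult height
#'   (inches).
#' @param weight_mean,weight_sd Baseline weight distribution of the typical
#'   subpopulation (pounds).
#' @param obese_fraction Probability that a subject belongs to the obese
#'   subpopulation; 0 gives a single-Gaussian weight population.
#' @param obese_mean,obese_sd Baseline weight distribution of the obese
#'   subpopulation (pounds).
#' @param within_sd Named vector: within-subject measurement SD per variable,
#'   native units.
#' @param weight_drift_sd Random-walk scale, pounds per sqrt(year).
#' @param error_model An [error_model()].
#' @param seed Integer seed; the cohort is fully reproducible from it, and
#'   per-subject substreams are derived deterministically so existing
#'   subjects are unchanged when `n_subjects` grows.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200,
                        years_followup_mean = 12, years_followup_sd = 5,
                        visits_per_year = c(height = 2, weight = 3),
                        height_mean = 69, height_sd = 3,
                        weight_mean = 185, weight_sd = 30,
                        obese_fraction = 0.15,
                        obese_mean = 285, obese_sd = 45,
                        within_sd = c(height = 0.6, weight = 6),
                        weight_drift_sd = 4,
                        error_model = ehrqa::error_model(),
                        seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  stopifnot(all(c("height", "weight") %in% names(visits_per_year)),
            all(c("height", "weight") %in% names(within_sd)),
            years_followup_sd >= 0, height_sd >= 0, weight_sd >= 0,
            obese_fraction >= 0, obese_fraction < 1, obese_sd >= 0,
            all(within_sd >= 0), weight_drift_sd >= 0)
  structure(list(n_subjects = n_subjects,
                 years_followup_mean = years_followup_mean,
                 years_followup_sd = years_followup_sd,
                 visits_per_year = visits_per_year,
                 height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 obese_fraction = obese_fraction,
                 obese_mean = obese_mean, obese_sd = obese_sd,
                 within_sd = within_sd, weight_drift_sd = weight_drift_sd,
                 error_model = error_model, seed = as.integer(seed)),
            class = "cohort_spec")
}

subject_seed <- function(seed, k, stream = 0L) {
  (as.numeric(seed) + 10007 * k + 1000003 * stream) %% 2147483587
}

truncated_normal <- function(n, mean, sd, low, high) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < low | out > high)
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < low | out > high)
  }
  out
}

plausible_range_for <- function(variable) {
  switch(variable, height = c(40, 100), weight = c(40, 1000),
         stop("no plausible range for variable: ", variable, call. = FALSE))
}

#' Generate a labeled synthetic cohort
#'
#' Per subject: a stable true height (constant over adult follow-up) and a
#' baseline weight following a Gaussian random walk; irregular visit times
#' from a Poisson (exponential-gap) renewal process at the configured rate
#' over the follow-up window, with `time` encoding age in years; observed
#' value = truth + Normal(0, within-subject SD). A fraction `rate` of records
#' is then corrupted according to the [error_model()] mechanism mix, and
#' every record receives a ground-truth label.
#'
#' @param spec A [cohort_spec()].
#' @return A list with `records` (a records data frame) and `labels`
#'   (`record_id`, `is_error`, `mechanism`, `original_value`), aligned
#'   row-by-row.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  per_subject <- vector("list", spec$n_subjects)
  for (k in seq_len(spec$n_subjects)) {
    set.seed(subject_seed(spec$seed, k))
    sid <- sprintf("S%05d", k)
    age0 <- stats::runif(1, 25, 75)
    fup <- truncated_normal(1, spec$years_followup_mean,
                            spec$years_followup_sd, 1, 25)
    height_true <- truncated_normal(1, spec$height_mean, spec$height_sd, 50, 90)
    weight_base <- if (stats::runif(1) < spec$obese_fraction) {
      truncated_normal(1, spec$obese_mean, spec$obese_sd, 180, 600)
    } else {
      truncated_normal(1, spec$weight_mean, spec$weight_sd, 80, 400)
    }
    rows <- list()
    for (v in c("height", "weight")) {
      rate <- spec$visits_per_year[[v]]
      gaps <- stats::rexp(ceiling(rate * 30 + 20), rate = rate)
      t_rel <- cumsum(gaps)
      t_rel <- t_rel[t_rel <= fup]
      if (length(t_rel) == 0) t_rel <- stats::runif(1, 0, fup)
      n <- length(t_rel)
      if (v == "height") {
        truth <- rep(height_true, n)
      } else {
        increments <- stats::rnorm(n, 0, spec$weight_drift_sd *
                                     sqrt(c(t_rel[1], diff(t_rel))))
        truth <- weight_base + cumsum(increments)
      }
      obs <- truth + stats::rnorm(n, 0, spec$within_sd[[v]])
      rows[[v]] <- data.frame(subject_id = sid, variable = v,
                              time = age0 + t_rel, value = obs,
                              stringsAsFactors = FALSE)
    }
    df <- rbind(rows$height, rows$weight)
    df$record_id <- paste0(sid, ":", seq_len(nrow(df)))
    per_subject[[k]] <- df
  }
  records <- reset_rows(do.call(rbind, c(per_subject,
                                         list(make.row.names = FALSE))))
  inject_errors(records, spec)
}

inject_errors <- function(records, spec) {
  em <- spec$error_model
  n <- nrow(records)
  labels <- data.frame(record_id = records$record_id,
                       is_error = FALSE,
                       mechanism = NA_character_,
                       original_value = records$value,
                       stringsAsFactors = FALSE)
  if (em$rate > 0 && n > 0) {
    set.seed(subject_seed(spec$seed, 0L, stream = 7L))
    hit <- which(stats::runif(n) < em$rate)
    mech <- sample(names(em$probs), length(hit), replace = TRUE,
                   prob = em$probs)
    for (idx in seq_along(hit)) {
      i <- hit[idx]
      v <- records$variable[i]
      x <- records$value[i]
      records$value[i] <- switch(
        mech[idx],
        unit = corrupt_unit(x, v),
        digit = corrupt_digit(x),
        gross = stats::runif(1, plausible_range_for(v)[1],
                             plausible_range_for(v)[2]),
        wrong_patient = wrong_patient_value(records, i)
      )
    }
    labels$is_error[hit] <- TRUE
    labels$mechanism[hit] <- mech
  }
  list(records = records, labels = labels)
}

corrupt_unit <- function(x, variable) {
  if (variable == "height") {
    x * 2.54
  } else {
    if (stats::runif(1) < 0.5) x * 2.2046 else x / 2.2046
  }
}

corrupt_digit <- function(x) {
  s <- strsplit(as.character(round(abs(x))), "")[[1]]
  nc <- length(s)
  op <- sample(c("transpose", "drop", "add"), 1)
  out <- if (op == "transpose" && nc >= 2) {
    i <- sample.int(nc - 1, 1)
    s[c(i, i + 1)] <- s[c(i + 1, i)]
    as.numeric(paste(s, collapse = ""))
  } else if (op == "drop" && nc >= 2) {
    as.numeric(paste(s[-sample.int(nc, 1)], collapse = ""))
  } else {
    i <- sample.int(nc + 1, 1)
    as.numeric(paste(append(s, as.character(sample(0:9, 1)), after = i - 1),
                     collapse = ""))
  }
  if (!is.finite(out) || out <= 0 || out == round(abs(x))) {
    out <- as.numeric(paste(c(s, as.character(sample(1:9, 1))), collapse = ""))
  }
  out
}

wrong_patient_value <- function(records, i) {
  cand <- which(records$variable == records$variable[i] &
                  records$subject_id != records$subject_id[i])
  if (length(cand) == 0) return(records$value[i])
  donor_subject <- sample(unique(records$subject_id[cand]), 1)
  cand <- cand[records$subject_id[cand] == donor_subject]
  j <- cand[which.min(abs(records$time[cand] - records$time[i]))]
  records$value[j]
}
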