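test_that("tau heuristic reproduces the published tuning values", {
  expect_equal(round(heuristic_tau(0.9, 12), 2), 9.49)
  expect_equal(round(heuristic_tau(0.9, 0.5), 1), 0.4)
  expect_equal(heuristic_tau(exp(-1), 12), 1)          # ln(e^-1) = -1
  # strictly increasing in both arguments
  expect_gt(heuristic_tau(0.95, 12), heuristic_tau(0.9, 12))
  expect_gt(heuristic_tau(0.9, 24), heuristic_tau(0.9, 12))
  expect_error(heuristic_tau(1.2, 12), "omega")
  expect_error(heuristic_tau(0.9, -1), "xi_months")
})

test_that("decay weights match the published 2-year and 5-year dependencies", {
  tau <- heuristic_tau(0.9, 12)
  expect_equal(round(decay_weight(2, 0, tau), 2), 0.81)
  expect_equal(round(decay_weight(5, 0, tau), 2), 0.59)
  expect_equal(decay_weight(99, 0, tau, is_self = TRUE), 1)
  # symmetric in the two times
  expect_equal(decay_weight(3, 7, 1.5), decay_weight(7, 3, 1.5))
})

test_that("EWMA is a convex combination over the entire sequence", {
  const <- make_series(c(50, 51, 52), c(200, 200, 200))
  for (i in 1:3) expect_equal(compute_ewma(const, i, tau = 0.5), 200)

  mixed <- make_series(c(50, 53, 57), c(150, 210, 180))
  huge_tau <- compute_ewma(mixed, 1, tau = 1e9)
  expect_equal(huge_tau, mean(mixed$value), tolerance = 1e-8)
  for (i in 1:3) {
    e <- compute_ewma(mixed, i, tau = 2)
    expect_gte(e, min(mixed$value)); expect_lte(e, max(mixed$value))
  }
  # two-term hand oracle: values [200, 180] at [0, 1], tau = 1, i = 2
  s2 <- make_series(c(0, 1), c(200, 180))
  expect_equal(compute_ewma(s2, 2, tau = 1),
               (exp(-1) * 200 + 180) / (exp(-1) + 1))
  expect_error(compute_ewma(s2, 3, tau = 1), "index")
})

test_that("deviation variance factor matches closed forms for both variants", {
  expect_equal(deviation_variance_factor(c(1, 1), 1, "derived"), 0.5)
  expect_equal(deviation_variance_factor(c(1, 1), 1, "paper"), 2.5)
  # n equal weights of 1: derived factor simplifies to 1 - 1/n
  for (n in c(2, 3, 7, 20)) {
    expect_equal(deviation_variance_factor(rep(1, n), 3 %% n + 1, "derived"),
                 1 - 1 / n)
  }
  expect_error(deviation_variance_factor(1, 1), "two measurements")
})

test_that("derived factor equals the sum of squared linear-combination coefficients", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(2:12, 1)
    t <- sort(runif(n, 0, 10))
    i <- sample.int(n, 1)
    w <- decay_weight(t, t[i], tau = runif(1, 0.2, 5))
    w[i] <- 1
    a <- w / sum(w); a[i] <- a[i] - 1
    expect_equal(deviation_variance_factor(w, i, "derived"), sum(a^2))
  }
})

test_that("qr_scores agrees with an independent step-by-step hand calculation", {
  s <- make_series(c(50.0, 50.1, 50.2), c(200, 200, 180))
  out <- qr_scores(s, tau = 0.5, var_y = 210)
  # hand calculation for the third record, scalar by scalar
  w <- c(exp(-0.2 / 0.5), exp(-0.1 / 0.5), 1)
  ewma <- (w[1] * 200 + w[2] * 200 + w[3] * 180) / sum(w)
  d <- abs(180 - ewma)
  fac <- (w[1]^2 + w[2]^2 + w[3]^2) / sum(w)^2 - 2 * 1 / sum(w) + 1
  z <- d / sqrt(fac * 210)
  expect_equal(out$ewma[3], ewma)
  expect_equal(out$d[3], d)
  expect_equal(out$z_r[3], z)
  expect_equal(out$q_r[3], 2 * (1 - pnorm(z)))
})

test_that("qr_scores handles constant series and known normal quantiles", {
  const <- make_series(c(50, 50.5, 51), c(200, 200, 200))
  out <- qr_scores(const, tau = 0.5, var_y = 210)
  expect_equal(out$d, rep(0, 3))
  expect_equal(out$z_r, rep(0, 3))
  expect_equal(out$q_r, rep(1, 3))
  expect_false(any(out$flag_r))
  # a record whose Z lands on the two-sided 5% quantile scores 0.05
  q <- 2 * (1 - pnorm(1.959964))
  expect_equal(round(q, 6), 0.05)
})

test_that("single-measurement series get missing scores and are never flagged", {
  s1 <- make_series(50, 180)
  out <- qr_scores(s1, tau = 0.5, var_y = 210)
  expect_true(is.na(out$q_r))
  expect_false(out$flag_r)
  expect_equal(out$status, "insufficient_history")
})

test_that("scores are invariant to unit rescaling and time shifts", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    s <- make_series(sort(runif(n, 40, 50)), rnorm(n, 180, 10))
    base <- qr_scores(s, tau = 0.5, var_y = 210)
    cc <- runif(1, 0.1, 5)
    scaled <- s; scaled$value <- s$value * cc
    out_s <- qr_scores(scaled, tau = 0.5, var_y = 210 * cc^2)
    expect_equal(out_s$z_r, base$z_r, tolerance = 1e-8)
    expect_equal(out_s$q_r, base$q_r, tolerance = 1e-8)

    shifted <- s; shifted$time <- s$time + runif(1, -30, 30)
    out_t <- qr_scores(shifted, tau = 0.5, var_y = 210)
    expect_equal(out_t$q_r, base$q_r, tolerance = 1e-12)
    expect_equal(out_t$ewma, base$ewma, tolerance = 1e-12)
  }
})

test_that("q_r is monotone nonincreasing in the deviation, all else fixed", {
  qs <- vapply(seq(180, 260, by = 10), function(v) {
    s <- make_series(c(50, 50.2, 50.4), c(180, 180, v))
    qr_scores(s, tau = 1e6, var_y = 210)$q_r[3]
  }, numeric(1))
  expect_true(all(diff(qs) <= 1e-15))
})

test_that("score_records appends both scores and respects per-variable config", {
  set.seed(9)
  rec <- rbind(iid_cohort(5, 6, 69, 3, 0.6, variable = "height"),
               iid_cohort(5, 6, 185, 30, 6, variable = "weight"))
  rec$record_id <- paste0(rec$variable, ":", seq_len(nrow(rec)))
  scored <- score_records(rec, default_config())
  expect_setequal(scored$record_id, rec$record_id)
  expect_true(all(c("ewma", "d", "se_d", "z_r", "q_r", "z_s", "q_s",
                    "flag_r", "flag_s") %in% names(scored)))
  expect_true(all(scored$q_r > 0 & scored$q_r <= 1))
  expect_error(score_records(make_records("A", "pulse", c(1, 2), c(60, 61))),
               "pulse")
})
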