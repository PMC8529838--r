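day <- function(d) 40 + d / 365.25  # age 40 plus an offset in days

test_that("same-day pairing matches within the day tolerance only", {
  rec <- rbind(make_records("A", "height", day(10), 70, "h1"),
               make_records("A", "weight", day(10), 200, "w1"),
               make_records("A", "weight", day(11), 201, "w2"))
  pairs <- pair_same_day(rec)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$height_record_id, "h1")
  expect_equal(pairs$weight_record_id, "w1")
  # different subjects never pair
  rec2 <- rbind(make_records("A", "height", day(1), 70, "h1"),
                make_records("B", "weight", day(1), 200, "w1"))
  expect_equal(nrow(pair_same_day(rec2)), 0)
})

test_that("multiple same-day heights break ties by record_id, independent of input order", {
  rec <- rbind(make_records("A", "height", day(c(10, 10)), c(70, 72),
                            c("h2", "h1")),
               make_records("A", "weight", day(10), 200, "w1"))
  for (perm in list(1:3, 3:1, c(2, 1, 3))) {
    pairs <- pair_same_day(rec[perm, , drop = FALSE])
    expect_equal(nrow(pairs), 1)
    expect_equal(pairs$height_record_id, "h1")
    expect_equal(pairs$height, 72)
  }
})

test_that("BMI conversion and scaling behave as 703 w / h^2", {
  expect_equal(round(compute_bmi(70, 200), 2), 28.69)
  expect_equal(compute_bmi(1, 3), 703 * 3)
  expect_equal(compute_bmi(65, 2 * 150), 2 * compute_bmi(65, 150))
  expect_error(compute_bmi(0, 100), "positive")
})

test_that("BMI classes follow the WHO-based boundaries", {
  expect_equal(classify_bmi(18.4999), "underweight")
  expect_equal(classify_bmi(18.5), "normal_to_overweight")
  expect_equal(classify_bmi(29.999), "normal_to_overweight")
  expect_equal(classify_bmi(30), "obese_I_II_III")
  expect_equal(classify_bmi(39.999), "obese_I_II_III")
  expect_equal(classify_bmi(40.0), "obese_III")
  expect_error(classify_bmi(-1), "positive")
})

test_that("ever-in-class counts a subject once per class, non-exclusively", {
  df <- data.frame(subject_id = c("A", "A", "B", "C", "D"),
                   bmi = c(25, 31, 25, 41, 45))
  out <- ever_in_class(df)
  expect_true(out$by_subject["A", "normal_to_overweight"])
  expect_true(out$by_subject["A", "obese_I_II_III"])
  expect_false(out$by_subject["A", "obese_III"])
  expect_equal(unname(out$proportion["obese_III"]), 0.5)   # 2 of 4 subjects
  expect_equal(unname(out$proportion["normal_to_overweight"]), 0.5)
})

test_that("the QA regime filter drops pairs by the right score column", {
  pairs <- data.frame(subject_id = "A", time = day(1), height = 70,
                      weight = 200, height_record_id = "h1",
                      weight_record_id = "w1", stringsAsFactors = FALSE)
  scored <- data.frame(record_id = c("h1", "w1"),
                       q_r = c(0.03, 0.8), q_s = c(0.9, 0.9),
                       stringsAsFactors = FALSE)
  expect_equal(nrow(qa_regime_filter(pairs, scored, "longitudinal", 0.05)), 0)
  expect_equal(nrow(qa_regime_filter(pairs, scored, "threshold", 0.05)), 1)
  expect_identical(qa_regime_filter(pairs, scored, "none"), pairs)
  # cutoff 0 drops nothing since scores are strictly positive
  expect_equal(nrow(qa_regime_filter(pairs, scored, "longitudinal", 1e-300)), 1)
  no_qs <- scored[, c("record_id", "q_r")]
  expect_error(qa_regime_filter(pairs, no_qs, "threshold"), "not available")
})

test_that("a stricter cutoff never increases the number of usable pairs", {
  set.seed(8)
  ch <- generate_cohort(cohort_spec(n_subjects = 40, seed = 8))
  pre <- preprocess_records(ch$records)
  sc <- score_records(pre$kept)
  pairs <- pair_same_day(pre$kept, day_tolerance = 0.25)  # coarse window: more pairs
  counts <- vapply(c(0.01, 0.05, 0.2, 0.5), function(ct) {
    nrow(qa_regime_filter(pairs, sc, "longitudinal", ct))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("longitudinal QA recovers the extreme-obesity proportion better than thresholding under unit errors", {
  spec <- cohort_spec(n_subjects = 150, seed = 5,
                      error_model = error_model(rate = 0.10,
                                                probs = c(unit = 1, digit = 0,
                                                          gross = 0,
                                                          wrong_patient = 0)))
  ch <- generate_cohort(spec)
  pre <- preprocess_records(ch$records)
  sc <- score_records(pre$kept)
  tol <- 0.25  # coarse pairing window so height/weight visits actually meet
  tbl <- bmi_table(pre$kept, sc, day_tolerance = tol)

  clean <- ch$records
  clean$value <- ch$labels$original_value
  pre0 <- preprocess_records(clean)
  pairs0 <- pair_same_day(pre0$kept, day_tolerance = tol)
  pairs0$bmi <- compute_bmi(pairs0$height, pairs0$weight)
  truth <- ever_in_class(pairs0)$proportion["obese_III"]

  p <- tbl[tbl$class == "obese_III", ]
  expect_lt(abs(p$longitudinal - truth), abs(p$threshold - truth))
})
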