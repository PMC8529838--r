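# Small builders used across the suite; fixtures are always constructed in
# code, never stored.

make_records <- function(subject_id, variable, times, values,
                         record_id = NULL) {
  n <- length(times)
  if (is.null(record_id)) {
    record_id <- if (n == 0) character(0) else
      paste0(subject_id[1], ":", seq_len(n))
  }
  data.frame(subject_id = rep_len(subject_id, n),
             variable = rep_len(variable, n),
             time = times, value = values, record_id = record_id,
             stringsAsFactors = FALSE)
}

make_series <- function(times, values, subject_id = "S1",
                        variable = "weight", record_id = NULL) {
  df <- make_records(subject_id, variable, times, values, record_id)
  group_series(df)[[1]]
}

# iid-normal cohort in long format: n_subjects, each with its own mean drawn
# from N(mu, sigma_b) and visits at sorted uniform times
iid_cohort <- function(n_subjects, visits, mu, sigma_b, sigma_w,
                       variable = "weight", t_span = 3) {
  rows <- lapply(seq_len(n_subjects), function(k) {
    times <- sort(runif(visits, 0, t_span)) + 40
    base <- rnorm(1, mu, sigma_b)
    make_records(sprintf("P%04d", k), variable, times,
                 rnorm(visits, base, sigma_w))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
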