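test_that("identical config and seed give byte-identical traffic", {
  cohort <- list(patient_profile("X1", "inpatient", inpatient_days = 3L))
  a <- simulate_cohort(simulation_config(cohort, seed = 5))
  b <- simulate_cohort(simulation_config(cohort, seed = 5))
  expect_identical(a$log, b$log)
  expect_identical(a$truth, b$truth)
  c <- simulate_cohort(simulation_config(cohort, seed = 6))
  expect_false(identical(a$log, c$log))
})

test_that("degenerate parameters give the degenerate statistics", {
  # always responds, never errs, near-zero latency: every rate is 1
  perfect <- list(patient_profile(
    "X1", "inpatient", respond_probability = 1,
    format_error_probability = 0, latency_meanlog = log(1),
    latency_sdlog = 1e-6, inpatient_days = 4L))
  sim <- simulate_cohort(simulation_config(perfect, seed = 3))
  expect_identical(compliance_rate(sim$log, sim$events, "pain"), 1)
  expect_identical(validity_rate(sim$log, sim$events, "pain"), 1)
  expect_identical(on_time_rate(sim$log, sim$events, "pain"), 1)

  # never responds: zero compliance, empty report store
  silent <- list(patient_profile("X2", "inpatient", respond_probability = 0,
                                 inpatient_days = 4L))
  sim <- simulate_cohort(simulation_config(silent, seed = 3))
  expect_identical(compliance_rate(sim$log, sim$events, "pain"), 0)
  expect_identical(nrow(sim$reports), 0L)
})

test_that("mutate_to_invalid always produces a failing message", {
  set.seed(77)
  for (i in 1:100) {
    spec <- registry[[sample(names(registry), 1)]]
    msg <- random_valid_message(spec)
    bad <- mutate_to_invalid(msg, spec)
    expect_false(parse_report(bad, spec)$valid,
                 info = sprintf("%s -> %s", msg, bad))
  }
  expect_error(mutate_to_invalid("NOT A REPORT", pain_spec))
})

test_that("simulated traffic is consistent with its independent ground truth", {
  sim <- sim_small()
  truth <- sim$truth
  # every intended no-response event has no inbound attempt
  inbound <- sim$log[sim$log$direction == "inbound", ]
  expect_identical(sort(unique(inbound$event_id)),
                   sort(truth$event_id[truth$responded]))
  # corrected messages in the log equal the injected invalid->valid sequences
  n_corrected_log <- sum(sim$log$corrected %in% TRUE)
  expect_identical(n_corrected_log, sum(truth$had_error & truth$retried))
  # invalid entries equal the injected errors
  expect_identical(sum(inbound$classification == "invalid"),
                   sum(truth$had_error))
  # every generated valid message parses; every invalid one fails
  for (i in seq_len(nrow(inbound))) {
    spec <- registry[[inbound$template_id[i]]]
    res <- parse_report(inbound$raw_text[i], spec)
    expect_identical(res$valid, inbound$classification[i] == "valid")
  }
  # no stored report violates its template (validation gates storage)
  for (i in seq_len(nrow(sim$reports))) {
    spec <- registry[[sim$reports$template_id[i]]]
    expect_true(parse_report(sim$reports$canonical_text[i], spec)$valid)
  }
})

test_that("alarms fire exactly when a stored pain report crosses the threshold", {
  sim <- sim_small()   # cohort threshold 5
  scores <- vapply(seq_len(nrow(sim$reports)), function(i) {
    if (sim$reports$template_id[i] != "pain") return(NA_integer_)
    alarm_score(parse_report(sim$reports$canonical_text[i], pain_spec)$report)
  }, 0L)
  should_alarm <- sim$reports$event_id[!is.na(scores) & scores > 5L]
  expect_setequal(sim$alarms$event_id, should_alarm)
  expect_true(all(sim$alarms$observed_score > sim$alarms$threshold))
})

test_that("the correction fraction recovers the error-times-retry product", {
  cohort <- lapply(sprintf("R%02d", 1:30), function(id)
    patient_profile(id, "outpatient", respond_probability = 1,
                    format_error_probability = 0.15,
                    retry_probability = 0.8, outpatient_days = 100L))
  cfg <- simulation_config(cohort, seed = 21,
                           protocol = list(recurrence("pain", "daily",
                                                      "09:00", 180)))
  sim <- simulate_cohort(cfg)
  expect_gte(nrow(sim$events), 3000L)
  corr <- correction_rate(sim$log, sim$events, "pain")
  target <- 0.15 * 0.8
  n_valid <- sum(sim$log$classification == "valid")
  tol <- 3 * sqrt(target * (1 - target) / n_valid)
  expect_lt(abs(corr - target), tol + 0.005)
})
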