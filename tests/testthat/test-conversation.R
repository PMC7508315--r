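pending_pain_state <- function() {
  ev <- make_event()
  set_pending(conversation_state("P1"), ev)
}

test_that("a pain score strictly above the threshold raises an alarm, at the threshold it does not", {
  pol <- threshold_policy("P1", "pain", 5, provider_ids = "dr1")
  at <- as.POSIXct("2024-01-08 13:30:00", tz = "UTC")

  out <- handle_inbound(pending_pain_state(), "P6BACK", at, registry, pol)
  kinds <- vapply(out$actions, `[[`, "", "kind")
  expect_identical(kinds, c("store", "alarm"))
  expect_identical(out$alarm$observed_score, 6L)
  expect_identical(out$alarm$threshold, 5L)
  expect_identical(out$alarm$provider_ids, "dr1")

  out <- handle_inbound(pending_pain_state(), "P5BACK", at, registry, pol)
  expect_null(out$alarm)
  expect_identical(vapply(out$actions, `[[`, "", "kind"), "store")

  # multi-site reports alarm on their maximum intensity
  out <- handle_inbound(pending_pain_state(), "P3HEAD&7LL&2UR", at, registry,
                        pol)
  expect_identical(out$alarm$observed_score, 7L)
})

test_that("alarm_score is the maximum intensity and zero for no pain", {
  r <- parse_report("P2CHEST&3BELLY", pain_spec)$report
  expect_identical(alarm_score(r), 3L)
  expect_identical(alarm_score(pain_report(no_pain = TRUE)), 0L)
  expect_identical(alarm_score(parse_report("P10HEAD", pain_spec)$report),
                   10L)
})

test_that("an invalid attempt triggers error-proofing and the corrected retry is flagged", {
  at <- as.POSIXct("2024-01-08 13:10:00", tz = "UTC")
  st <- pending_pain_state()

  out1 <- handle_inbound(st, "2CHEST", at, registry)
  expect_identical(out1$actions[[1]]$kind, "instruction")
  expect_match(out1$actions[[1]]$text, "P2CHEST&3BELLY", fixed = TRUE)
  expect_null(out1$report)
  expect_true(out1$state$had_invalid_attempt)
  expect_identical(out1$state$attempt_count, 1L)
  # event stays pending for the retry
  expect_false(is.null(out1$state$pending_event))

  out2 <- handle_inbound(out1$state, "P2CHEST", at + 300, registry)
  expect_identical(out2$actions[[1]]$kind, "store")
  expect_true(out2$actions[[1]]$corrected)
  log <- as_message_log(c(out1$log, out2$log))
  expect_identical(log$classification,
                   c("invalid", "instruction", "valid"))
  expect_true(log$corrected[3])
  # pending cleared, counters reset
  expect_null(out2$state$pending_event)
  expect_identical(out2$state$attempt_count, 0L)
})

test_that("a message with no pending event gets help and is not stored", {
  st <- conversation_state("P1")
  at <- as.POSIXct("2024-01-08 13:00:00", tz = "UTC")
  out <- handle_inbound(st, "P2CHEST", at, registry)
  expect_identical(out$actions[[1]]$kind, "help")
  expect_null(out$report)
  log <- as_message_log(out$log)
  expect_identical(log$classification[log$direction == "inbound"], "other")
})

test_that("scale resubmission within the window wins; after the window it does not apply", {
  ev <- make_event(template_id = "promis8", window_minutes = 51 * 60)
  st <- conversation_state("P1")
  prior <- parse_report("01324101", promis_spec)$report

  within <- ev$window_start + 3600
  out <- handle_resubmission(st, prior, ev, "01324102", within, registry)
  expect_true(out$applied)
  expect_identical(out$report$items[8], 2L)

  late <- ev$window_end + 3600
  out <- handle_resubmission(st, prior, ev, "01324102", late, registry)
  expect_false(out$applied)
  expect_identical(out$report$items, prior$items)
  expect_identical(length(out$log), 1L)  # still logged

  out <- handle_resubmission(st, prior, ev, "0132410", within, registry)
  expect_false(out$applied)
  expect_identical(out$report$items, prior$items)
  expect_identical(out$actions[[1]]$kind, "instruction")
})

test_that("health tips are one-way and never disturb a pending query", {
  pool <- read_pool(system.file("extdata", "pools", "health_tips.txt",
                                package = "txtpro"))
  st <- pending_pain_state()
  at <- as.POSIXct("2024-01-08 16:00:00", tz = "UTC")
  set.seed(1)
  tip1 <- send_health_tip(pool, st, at)
  expect_identical(tip1$action$kind, "one_way")
  expect_true(tip1$action$text %in% pool$messages)
  expect_identical(tip1$state$pending_event$event_id, st$pending_event$event_id)
  log <- as_message_log(tip1$log)
  expect_identical(log$classification, "one_way")
  expect_identical(log$direction, "outbound")
  # consecutive tips differ when the pool has more than one message
  tip2 <- send_health_tip(tip1$pool, tip1$state, at + 60)
  expect_false(identical(tip1$action$text, tip2$action$text))
})
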