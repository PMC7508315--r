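local_hm <- function(t, tz) format(lubridate::with_tz(t, tz), "%H:%M")

test_that("the inpatient protocol expands to three daily pain chances between 7AM and 7PM", {
  tz <- "America/New_York"
  sched <- schedule("p1", tz, inpatient_protocol(), setting = "inpatient")
  ev <- expand_schedule(sched, "2024-01-08", "2024-01-08")
  pain <- ev[ev$template_id == "pain", ]
  expect_identical(nrow(pain), 3L)
  expect_identical(local_hm(pain$window_start, tz),
                   c("08:00", "12:00", "17:00"))
  seven_am <- local_instant(as.Date("2024-01-08"), "07:00", tz)
  seven_pm <- local_instant(as.Date("2024-01-08"), "19:00", tz)
  expect_true(all(pain$window_start >= seven_am & pain$window_end <= seven_pm))
  expect_true(all(ev$setting == "inpatient"))
})

test_that("the weekly scale expands to one weekend window per week", {
  tz <- "America/New_York"
  sched <- schedule("p1", tz, list(
    recurrence("promis8", "weekly", "18:00",
               window_minutes = 51 * 60, weekday = 5L)))
  ev <- expand_schedule(sched, "2024-01-08", "2024-01-14")
  expect_identical(nrow(ev), 1L)
  expect_identical(format(lubridate::with_tz(ev$window_start, tz),
                          "%a %H:%M"), "Fri 18:00")
  expect_identical(format(lubridate::with_tz(ev$window_end, tz),
                          "%a %H:%M"), "Sun 21:00")
})

test_that("expansion is deterministic, ordered, and honors exceptions and empty horizons", {
  sched <- schedule("p1", "America/New_York", outpatient_protocol(),
                    exceptions = as.Date("2024-01-09"),
                    setting = "outpatient")
  a <- expand_schedule(sched, "2024-01-08", "2024-01-10")
  b <- expand_schedule(sched, "2024-01-08", "2024-01-10")
  expect_identical(a, b)
  expect_false(as.Date("2024-01-09") %in% a$local_date)
  expect_true(!is.unsorted(a$window_start))
  expect_identical(nrow(expand_schedule(sched, "2024-01-10", "2024-01-08")),
                   0L)
  expect_error(schedule("p1", "Not/AZone", outpatient_protocol()),
               "unknown timezone")
})

test_that("windows stay at the configured local clock time across DST transitions", {
  tz <- "America/New_York"
  sched <- schedule("p1", tz, list(recurrence("pain", "daily", "08:00", 120)))
  # 2024-03-10: US spring-forward
  ev <- expand_schedule(sched, "2024-03-09", "2024-03-11")
  expect_identical(local_hm(ev$window_start, tz), rep("08:00", 3))
  expect_identical(local_hm(ev$window_end, tz), rep("10:00", 3))
  # UTC offsets differ around the transition even though local time is fixed
  expect_identical(diff(as.numeric(ev$window_start)) / 3600, c(23, 24))
})

test_that("prompts and reminders are due only inside the window and reminders are suppressed by a valid response", {
  ev <- make_event(offsets = c(30, 90))
  ws <- ev$window_start
  # before the window opens: nothing
  expect_identical(nrow(due_actions(ev, now = ws - 1)), 0L)
  # past both offsets with no response: one prompt + two reminders
  acts <- due_actions(ev, now = ws + 100 * 60)
  expect_identical(acts$kind, c("initial_prompt", "reminder", "reminder"))
  expect_true(all(acts$due_at >= ws & acts$due_at < ev$window_end))
  # a valid response before the first offset suppresses both reminders
  log <- as_message_log(list(log_entry(
    "P1", "inbound", ws + 10 * 60, "P2CHEST", "E1", "pain", "valid",
    corrected = FALSE)))
  acts <- due_actions(ev, log, now = ws + 100 * 60)
  expect_identical(acts$kind, "initial_prompt")
  # monotone suppression: a response between the offsets kills only later ones
  log2 <- as_message_log(list(log_entry(
    "P1", "inbound", ws + 45 * 60, "P2CHEST", "E1", "pain", "valid",
    corrected = FALSE)))
  acts <- due_actions(ev, log2, now = ws + 100 * 60)
  expect_identical(acts$kind, c("initial_prompt", "reminder"))
  expect_identical(acts$due_at[2], ws + 30 * 60)
})

test_that("reminder suppression is monotone over random response times", {
  set.seed(505)
  ev <- make_event(offsets = c(20, 50, 80), window_minutes = 120)
  ws <- ev$window_start
  now <- ws + 119 * 60
  base <- due_actions(ev, now = now)
  for (i in 1:25) {
    t_resp <- ws + runif(1, 0, 120) * 60
    log <- as_message_log(list(log_entry(
      "P1", "inbound", t_resp, "P2CHEST", "E1", "pain", "valid",
      corrected = FALSE)))
    got <- due_actions(ev, log, now = now)
    kept <- base[base$kind == "initial_prompt" | base$due_at < t_resp, ]
    expect_identical(got$due_at, kept$due_at)
  }
})

test_that("on-time classification is a closed interval and latency counts from the prompt", {
  ev <- make_event()
  expect_true(is_on_time(ev, ev$window_start))
  expect_true(is_on_time(ev, ev$window_end))
  expect_false(is_on_time(ev, ev$window_end + 60))
  expect_false(is_on_time(ev, ev$window_start - 1))
  expect_identical(response_latency(ev, ev$window_start + 36 * 60), 36)
  expect_identical(response_latency(ev, ev$window_start), 0)
})
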