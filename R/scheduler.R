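#' Recurring report query rule
#'
#' One recurrence expands to one report event per matching patient-local day:
#' a completion window opening at `start_time` local clock time and lasting
#' `window_minutes`, with reminders at `reminder_offsets` minutes after the
#' window opens (each strictly inside the window). Daily-pain protocols use
#' several daily recurrences to give patients multiple chances per day;
#' weekly scales use a single long weekend window.
#'
#' @param template_id Which report template the query asks for.
#' @param freq `"daily"` or `"weekly"`.
#' @param start_time Local clock time `"HH:MM"` at which the window opens.
#' @param window_minutes Window length in minutes.
#' @param weekday ISO weekday (1 = Monday .. 7 = Sunday) on which a weekly
#'   recurrence fires.
#' @param reminder_offsets Minutes after window start at which reminders are
#'   due when no valid response has arrived; default one reminder at the
#'   window midpoint.
#' @param one_way `TRUE` for one-way messages (health tips) that expect no
#'   response.
#' @return An object of class `txt_recurrence`.
#' @export
recurrence <- function(template_id, freq = c("daily", "weekly"),
                       start_time = "08:00", window_minutes = 120,
                       weekday = NULL,
                       reminder_offsets = window_minutes / 2,
                       one_way = FALSE) {
  freq <- match.arg(freq)
  stopifnot(grepl("^[0-2]?[0-9]:[0-5][0-9]$", start_time),
            window_minutes > 0)
  if (freq == "weekly") {
    stopifnot(!is.null(weekday), weekday %in% 1:7)
  }
  if (one_way) reminder_offsets <- numeric()
  if (any(reminder_offsets <= 0 | reminder_offsets >= window_minutes)) {
    abort("reminder offsets must lie strictly inside the window")
  }
  structure(list(template_id = template_id, freq = freq,
                 start_time = start_time,
                 window_minutes = as.numeric(window_minutes),
                 weekday = if (!is.null(weekday)) as.integer(weekday),
                 reminder_offsets = sort(as.numeric(reminder_offsets)),
                 one_way = isTRUE(one_way)),
            class = "txt_recurrence")
}

#' Per-patient reporting schedule
#'
#' A schedule bundles the recurrences a patient is enrolled in, the IANA
#' timezone their clock times refer to, and exception dates (e.g. school
#' breaks) on which no events fire. Timestamps are stored in UTC throughout
#' the package; schedules are the only place local clock time appears.
#'
#' @param patient_id Opaque patient identifier.
#' @param timezone IANA timezone name, e.g. `"America/New_York"`.
#' @param recurrences List of [recurrence()] rules.
#' @param exceptions `Date` vector of skipped local dates.
#' @param setting Optional care setting label (`"inpatient"` /
#'   `"outpatient"`) carried onto expanded events for per-setting statistics.
#' @return An object of class `txt_schedule`.
#' @export
schedule <- function(patient_id, timezone = "America/New_York",
                     recurrences = list(), exceptions = as.Date(character()),
                     setting = NA_character_) {
  if (!timezone %in% OlsonNames()) {
    abort(sprintf("unknown timezone '%s'", timezone))
  }
  stopifnot(all(vapply(recurrences, inherits, TRUE, "txt_recurrence")))
  structure(list(patient_id = patient_id, timezone = timezone,
                 recurrences = recurrences,
                 exceptions = as.Date(exceptions),
                 setting = setting),
            class = "txt_schedule")
}

#' @export
print.txt_schedule <- function(x, ...) {
  cat(sprintf("<txt_schedule> patient %s, tz %s, %d recurrence(s), %d exception date(s)\n",
              x$patient_id, x$timezone, length(x$recurrences),
              length(x$exceptions)))
  for (r in x$recurrences) {
    cat(sprintf("  %s %s at %s for %gmin%s%s\n", r$freq, r$template_id,
                r$start_time, r$window_minutes,
                if (r$freq == "weekly") sprintf(" (weekday %d)", r$weekday) else "",
                if (r$one_way) " [one-way]" else ""))
  }
  invisible(x)
}

empty_events <- function() {
  tibble::tibble(event_id = character(), patient_id = character(),
                 template_id = character(), setting = character(),
                 local_date = as.Date(character()),
                 window_start = as.POSIXct(character(), tz = "UTC"),
                 window_end = as.POSIXct(character(), tz = "UTC"),
                 reminder_offsets = list(), one_way = logical())
}

local_instant <- function(date, hhmm, tz) {
  lubridate::with_tz(
    lubridate::ymd_hm(paste(format(date), hhmm), tz = tz), "UTC")
}

#' Expand a schedule into concrete report events
#'
#' Deterministically expands every recurrence over a date horizon into one
#' event per matching day, skipping exception dates. Windows are anchored at
#' the configured local clock time in the patient's timezone (so they stay at
#' the same wall-clock time across daylight-saving transitions) and stored as
#' UTC instants.
#'
#' @param sched A [schedule()].
#' @param from,to First and last local date (inclusive) of the horizon.
#' @return A tibble of events in chronological order with columns `event_id`,
#'   `patient_id`, `template_id`, `setting`, `local_date`, `window_start`,
#'   `window_end` (UTC `POSIXct`), `reminder_offsets` (list of minutes) and
#'   `one_way`.
#' @export
expand_schedule <- function(sched, from, to) {
  stopifnot(inherits(sched, "txt_schedule"))
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) return(empty_events())
  days <- seq(from, to, by = "day")
  days <- days[!days %in% sched$exceptions]
  out <- list()
  for (r in sched$recurrences) {
    on <- if (r$freq == "daily") days else
      days[as.integer(format(days, "%u")) == r$weekday]
    if (length(on) == 0L) next
    ws <- local_instant(on, r$start_time, sched$timezone)
    out[[length(out) + 1L]] <- tibble::tibble(
      event_id = sprintf("%s-%s-%s-%s", sched$patient_id, r$template_id,
                         format(on), gsub(":", "", r$start_time)),
      patient_id = sched$patient_id,
      template_id = r$template_id,
      setting = sched$setting,
      local_date = on,
      window_start = ws,
      window_end = ws + r$window_minutes * 60,
      reminder_offsets = rep(list(r$reminder_offsets), length(on)),
      one_way = r$one_way)
  }
  if (length(out) == 0L) return(empty_events())
  dplyr::arrange(dplyr::bind_rows(out), .data$window_start, .data$event_id)
}

#' Default reporting protocols
#'
#' `inpatient_protocol()` gives three daily pain-report chances between 7AM
#' and 7PM local (two-hour windows opening 08:00, 12:00 and 17:00), the
#' weekly scale window from Friday 18:00 to Sunday 21:00, and a daily one-way
#' health tip. `outpatient_protocol()` adds a daily school-attendance query
#' around dinnertime (18:00); its pain chances default to before school,
#' after school and before bedtime but are fully personalizable.
#'
#' @param pain_times,pain_window Local opening times and window length
#'   (minutes) of the daily pain chances.
#' @param tip_time Local time of the daily health tip.
#' @return List of [recurrence()] rules.
#' @export
inpatient_protocol <- function(pain_times = c("08:00", "12:00", "17:00"),
                               pain_window = 120, tip_time = "16:00") {
  c(lapply(pain_times, function(t)
      recurrence("pain", "daily", start_time = t,
                 window_minutes = pain_window)),
    list(recurrence("promis8", "weekly", start_time = "18:00",
                    window_minutes = promis_window_minutes(), weekday = 5L),
         recurrence("tips", "daily", start_time = tip_time,
                    window_minutes = 60, one_way = TRUE)))
}

#' @rdname inpatient_protocol
#' @param attendance_time Local time of the school-attendance query.
#' @export
outpatient_protocol <- function(pain_times = c("07:00", "15:30", "20:00"),
                                pain_window = 120,
                                attendance_time = "18:00",
                                tip_time = "16:00") {
  c(lapply(pain_times, function(t)
      recurrence("pain", "daily", start_time = t,
                 window_minutes = pain_window)),
    list(recurrence("attendance", "daily", start_time = attendance_time,
                    window_minutes = 120),
         recurrence("promis8", "weekly", start_time = "18:00",
                    window_minutes = promis_window_minutes(), weekday = 5L),
         recurrence("tips", "daily", start_time = tip_time,
                    window_minutes = 60, one_way = TRUE)))
}

# Friday 18:00 local to Sunday 21:00 local = 51 hours
promis_window_minutes <- function() 51 * 60

#' Prompts and reminders due by a point in time
#'
#' For every event whose window has opened, an initial prompt is due at
#' window start; each configured reminder is due at its offset unless a valid
#' response to that event arrived before the reminder time. No action is ever
#' due outside its event window, and inserting a valid response at time `t`
#' suppresses exactly the reminders later than `t` (monotone suppression).
#'
#' @param events Event tibble from [expand_schedule()].
#' @param log Message log (see [empty_message_log()]); valid inbound rows
#'   referencing an event suppress its later reminders.
#' @param now UTC timestamp up to which actions are collected.
#' @return Tibble with columns `kind` (`"initial_prompt"` / `"reminder"`),
#'   `event_id`, `due_at`, chronologically ordered.
#' @export
due_actions <- function(events, log = empty_message_log(), now) {
  stopifnot(inherits(now, "POSIXct"))
  valid <- log[log$direction == "inbound" & log$classification == "valid", ]
  rows <- list()
  live <- events[!events$one_way & events$window_start <= now, ]
  for (i in seq_len(nrow(live))) {
    ev <- live[i, ]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      kind = "initial_prompt", event_id = ev$event_id,
      due_at = ev$window_start)
    responded_at <- valid$at[valid$event_id == ev$event_id]
    for (off in ev$reminder_offsets[[1]]) {
      due <- ev$window_start + off * 60
      if (due > now || due >= ev$window_end) next
      if (any(responded_at < due)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "reminder", event_id = ev$event_id, due_at = due)
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(kind = character(), event_id = character(),
                          due_at = as.POSIXct(character(), tz = "UTC")))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$due_at, .data$event_id)
}

#' On-time classification and response latency
#'
#' A response is on time iff it falls inside the event's completion window,
#' boundaries included. Late valid reports are still recorded (they count
#' toward compliance, not toward the on-time rate). Latency is measured in
#' minutes from the initial prompt — the window opening — to the response.
#'
#' @param event One event (single-row tibble or list with `window_start`,
#'   `window_end`).
#' @param at UTC response timestamp.
#' @return `is_on_time()`: logical. `response_latency()`: minutes (numeric).
#' @export
is_on_time <- function(event, at) {
  as.numeric(at) >= as.numeric(event$window_start) &
    as.numeric(at) <= as.numeric(event$window_end)
}

#' @rdname is_on_time
#' @export
response_latency <- function(event, at) {
  as.numeric(difftime(at, event$window_start, units = "mins"))
}
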