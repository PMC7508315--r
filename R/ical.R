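## Minimal RFC 5545 (iCalendar) subset covering exactly what txtpro schedules
## need: one VEVENT per recurrence with DTSTART;TZID, DURATION, RRULE
## (FREQ=DAILY | FREQ=WEEKLY;BYDAY), EXDATE per exception date, and private
## X- properties for the template id, reminder offsets and one-way flag.

ical_byday <- c("MO", "TU", "WE", "TH", "FR", "SA", "SU")

#' Export / import a schedule as iCalendar
#'
#' `write_ical()` serializes a [schedule()] as an RFC 5545 calendar, one
#' VEVENT per recurrence: `DTSTART;TZID=<tz>` anchors the first window at the
#' recurrence's local clock time, `DURATION` carries the window length,
#' `RRULE` the daily/weekly repetition, and `EXDATE` the exception dates.
#' The report template id, reminder offsets (minutes) and one-way flag travel
#' in the private properties `X-TXTPRO-TEMPLATE`, `X-TXTPRO-REMINDERS` and
#' `X-TXTPRO-ONEWAY`. `read_ical()` parses such a file back; the round trip
#' preserves the schedule exactly.
#'
#' @param sched A [schedule()].
#' @param path Output (input) file path.
#' @param dtstart Local anchor date written into `DTSTART` (recurrences are
#'   open-ended; any date works, the expansion horizon is chosen at
#'   [expand_schedule()] time).
#' @return `write_ical()`: `path`, invisibly. `read_ical()`: a `txt_schedule`.
#' @export
write_ical <- function(sched, path, dtstart = as.Date("2024-01-01")) {
  stopifnot(inherits(sched, "txt_schedule"))
  dtstart <- as.Date(dtstart)
  fmt_dt <- function(date, hhmm) {
    paste0(format(date, "%Y%m%d"), "T",
           gsub(":", "", sprintf("%s", hhmm)), "00")
  }
  lines <- c("BEGIN:VCALENDAR", "VERSION:2.0", "PRODID:-//txtpro//R//EN")
  for (i in seq_along(sched$recurrences)) {
    r <- sched$recurrences[[i]]
    anchor <- dtstart
    if (r$freq == "weekly") {
      # move anchor forward to the configured weekday
      shift <- (r$weekday - as.integer(format(dtstart, "%u"))) %% 7L
      anchor <- dtstart + shift
    }
    rrule <- if (r$freq == "daily") "FREQ=DAILY" else
      sprintf("FREQ=WEEKLY;BYDAY=%s", ical_byday[r$weekday])
    ev <- c("BEGIN:VEVENT",
            sprintf("UID:%s-%s-%d@txtpro", sched$patient_id, r$template_id, i),
            sprintf("SUMMARY:%s query", r$template_id),
            sprintf("DTSTART;TZID=%s:%s", sched$timezone,
                    fmt_dt(anchor, r$start_time)),
            sprintf("DURATION:PT%dM", as.integer(r$window_minutes)),
            sprintf("RRULE:%s", rrule),
            sprintf("X-TXTPRO-TEMPLATE:%s", r$template_id),
            sprintf("X-TXTPRO-REMINDERS:%s",
                    paste(r$reminder_offsets, collapse = ",")),
            sprintf("X-TXTPRO-ONEWAY:%s", if (r$one_way) "TRUE" else "FALSE"))
    if (length(sched$exceptions)) {
      ev <- c(ev, sprintf("EXDATE;TZID=%s:%s", sched$timezone,
                          paste0(fmt_dt(sched$exceptions, r$start_time),
                                 collapse = ",")))
    }
    ev <- c(ev, "END:VEVENT")
    lines <- c(lines, ev)
  }
  lines <- c(lines,
             sprintf("X-TXTPRO-PATIENT:%s", sched$patient_id),
             sprintf("X-TXTPRO-SETTING:%s", sched$setting),
             "END:VCALENDAR")
  writeLines(lines, path, sep = "\r\n")
  invisible(path)
}

#' @rdname write_ical
#' @export
read_ical <- function(path) {
  lines <- gsub("\r$", "", readLines(path, warn = FALSE))
  prop <- function(block, name) {
    hit <- grep(paste0("^", name, "[;:]"), block, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0("^", name, "(;[^:]*)?:"), "", hit[1])
  }
  prop_param <- function(block, name, param) {
    hit <- grep(paste0("^", name, ";"), block, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    sub(paste0(".*", param, "=([^:;]+)[:;].*"), "\\1", hit[1])
  }
  starts <- which(lines == "BEGIN:VEVENT")
  ends <- which(lines == "END:VEVENT")
  if (length(starts) != length(ends)) abort("malformed iCalendar file")
  tz <- NULL
  recurs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    dt <- prop(block, "DTSTART")
    tz <- prop_param(block, "DTSTART", "TZID") %||% tz
    start_time <- sprintf("%s:%s", substr(dt, 10, 11), substr(dt, 12, 13))
    dur <- prop(block, "DURATION")
    window_minutes <- as.numeric(sub("^PT([0-9]+)M$", "\\1", dur))
    rrule <- prop(block, "RRULE")
    if (grepl("FREQ=DAILY", rrule)) {
      freq <- "daily"; weekday <- NULL
    } else {
      freq <- "weekly"
      weekday <- match(sub(".*BYDAY=([A-Z]{2}).*", "\\1", rrule), ical_byday)
    }
    offsets <- prop(block, "X-TXTPRO-REMINDERS")
    offsets <- if (is.null(offsets) || !nzchar(offsets)) numeric() else
      as.numeric(strsplit(offsets, ",")[[1]])
    recurs[[k]] <- recurrence(
      template_id = prop(block, "X-TXTPRO-TEMPLATE"),
      freq = freq, start_time = start_time,
      window_minutes = window_minutes, weekday = weekday,
      reminder_offsets = offsets,
      one_way = identical(prop(block, "X-TXTPRO-ONEWAY"), "TRUE"))
  }
  exdates <- as.Date(character())
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    ex <- prop(block, "EXDATE")
    if (!is.null(ex)) {
      exdates <- unique(c(exdates,
                          as.Date(substr(strsplit(ex, ",")[[1]], 1, 8),
                                  "%Y%m%d")))
    }
  }
  patient <- NULL
  hit <- grep("^X-TXTPRO-PATIENT:", lines, value = TRUE)
  if (length(hit)) patient <- sub("^X-TXTPRO-PATIENT:", "", hit[1])
  setting <- NA_character_
  hit <- grep("^X-TXTPRO-SETTING:", lines, value = TRUE)
  if (length(hit)) setting <- sub("^X-TXTPRO-SETTING:", "", hit[1])
  if (identical(setting, "NA")) setting <- NA_character_
  schedule(patient_id = patient %||% "unknown",
           timezone = tz %||% "UTC",
           recurrences = recurs,
           exceptions = sort(exdates),
           setting = setting)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
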