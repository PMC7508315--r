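## Outcome statistics over the message log.
##
## "Messages received" counts final message outcomes: an invalid attempt that
## the patient later corrected (a valid message for the same event arrived
## afterwards) collapses into that valid, corrected message; only invalid
## attempts that were never followed by a valid report for their event count
## as received-invalid. Raw attempts always remain in the log.

filter_events <- function(events, template_id = NULL, setting = NULL,
                          two_way = TRUE) {
  if (two_way) events <- events[!events$one_way, ]
  if (!is.null(template_id)) {
    events <- events[events$template_id %in% template_id, ]
  }
  if (!is.null(setting)) {
    events <- events[!is.na(events$setting) & events$setting %in% setting, ]
  }
  events
}

log_for_events <- function(log, events) {
  log[log$direction == "inbound" & !is.na(log$event_id) &
        log$event_id %in% events$event_id, ]
}

# valid / received(final-outcome) counts for inbound attempts at `events`
message_counts <- function(log, events) {
  inb <- log_for_events(log, events)
  valid <- inb[inb$classification == "valid", ]
  invalid <- inb[inb$classification == "invalid", ]
  absorbed <- vapply(seq_len(nrow(invalid)), function(i) {
    any(valid$event_id == invalid$event_id[i] &
          valid$at > invalid$at[i])
  }, TRUE)
  list(valid = valid,
       invalid = invalid,
       n_valid = nrow(valid),
       n_received = nrow(valid) + sum(!absorbed),
       n_corrected = sum(valid$corrected %in% TRUE))
}

rate_or_na <- function(num, den) if (den == 0L) NA_real_ else num / den

#' Daily compliance rate
#'
#' Fraction of query days — patient-local calendar days with at least one
#' scheduled query of the template — on which at least one valid report of
#' that template was received. Late valid reports still count toward
#' compliance (only the on-time rate penalizes them). `NA` when there are no
#' query days.
#'
#' @param log Message log tibble (see [as_message_log()]).
#' @param events Event tibble from [expand_schedule()] covering the analysis
#'   horizon.
#' @param template_id Template to score, e.g. `"pain"`.
#' @param setting Optional setting filter (`"inpatient"` / `"outpatient"`).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
compliance_rate <- function(log, events, template_id, setting = NULL) {
  ev <- filter_events(events, template_id, setting)
  days <- dplyr::distinct(ev, .data$patient_id, .data$local_date)
  if (nrow(days) == 0L) return(NA_real_)
  valid <- log[log$direction == "inbound" & log$classification == "valid", ]
  ev_valid <- ev[ev$event_id %in% valid$event_id, ]
  good <- dplyr::distinct(ev_valid, .data$patient_id, .data$local_date)
  nrow(good) / nrow(days)
}

#' Validity (reporting-accuracy) rate
#'
#' Fraction of received report messages that were valid under the template,
#' where a corrected sequence (invalid attempt followed by a valid retry for
#' the same event) counts as one received, valid message.
#'
#' @inheritParams compliance_rate
#' @return Fraction in `[0, 1]`, or `NA` with no received messages.
#' @export
validity_rate <- function(log, events, template_id, setting = NULL) {
  ev <- filter_events(events, template_id, setting)
  mc <- message_counts(log, ev)
  rate_or_na(mc$n_valid, mc$n_received)
}

#' Real-time correction rate
#'
#' Fraction of valid messages that were initially invalid and fixed through
#' the error-proofing instruction within the same event.
#'
#' @inheritParams compliance_rate
#' @return Fraction in `[0, 1]`, or `NA` with no valid messages.
#' @export
correction_rate <- function(log, events, template_id, setting = NULL) {
  ev <- filter_events(events, template_id, setting)
  mc <- message_counts(log, ev)
  rate_or_na(mc$n_corrected, mc$n_valid)
}

valid_with_windows <- function(log, ev) {
  mc <- message_counts(log, ev)
  v <- mc$valid
  v <- dplyr::left_join(
    v, ev[c("event_id", "window_start", "window_end")], by = "event_id")
  v$on_time <- as.numeric(v$at) >= as.numeric(v$window_start) &
    as.numeric(v$at) <= as.numeric(v$window_end)
  list(valid = v, n_valid = mc$n_valid, n_received = mc$n_received)
}

#' On-time reporting rate
#'
#' Fraction of report messages received within their completion window
#' (boundaries included). The denominator is configurable: `"valid"` divides
#' on-time messages by valid messages, `"received"` by all received
#' (final-outcome) messages; both conventions appear in practice and both are
#' exposed, defaulting to over-valid.
#'
#' @inheritParams compliance_rate
#' @param denominator `"valid"` (default) or `"received"`.
#' @return Fraction in `[0, 1]`, or `NA` with an empty denominator.
#' @export
on_time_rate <- function(log, events, template_id, setting = NULL,
                         denominator = c("valid", "received")) {
  denominator <- match.arg(denominator)
  ev <- filter_events(events, template_id, setting)
  vw <- valid_with_windows(log, ev)
  den <- if (denominator == "valid") vw$n_valid else vw$n_received
  rate_or_na(sum(vw$valid$on_time), den)
}

#' Mean response latency of on-time messages
#'
#' Average minutes from the initial prompt (the window opening) to each
#' on-time valid message. Late messages are excluded from the average.
#'
#' @inheritParams compliance_rate
#' @return Minutes (numeric), or `NA` with no on-time valid messages.
#' @export
mean_latency <- function(log, events, template_id, setting = NULL) {
  ev <- filter_events(events, template_id, setting)
  vw <- valid_with_windows(log, ev)
  ot <- vw$valid[vw$valid$on_time, ]
  if (nrow(ot) == 0L) return(NA_real_)
  mean(as.numeric(difftime(ot$at, ot$window_start, units = "mins")))
}

#' Overall reporting accuracy across settings
#'
#' Pooled validity over all events of the named template(s) regardless of
#' setting: total valid messages over total received messages.
#'
#' @inheritParams compliance_rate
#' @param template_id Character vector of template ids to pool.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
overall_accuracy <- function(log, events, template_id) {
  ev <- filter_events(events, template_id, setting = NULL)
  mc <- message_counts(log, ev)
  rate_or_na(mc$n_valid, mc$n_received)
}

#' Weekly scale compliance
#'
#' Fraction of query weeks — weekly scale events — with at least one valid
#' scale report.
#'
#' @inheritParams compliance_rate
#' @param template_id The weekly scale template, default `"promis8"`.
#' @return Fraction in `[0, 1]`, or `NA` with no query weeks.
#' @export
weekly_scale_compliance <- function(log, events, template_id = "promis8",
                                    setting = NULL) {
  ev <- filter_events(events, template_id, setting)
  if (nrow(ev) == 0L) return(NA_real_)
  valid <- log[log$direction == "inbound" & log$classification == "valid", ]
  mean(ev$event_id %in% valid$event_id)
}

#' Trial summary statistics
#'
#' Per-setting, per-template summary of the whole deployment: query
#' days (weeks for weekly templates), compliant days, received / valid /
#' corrected / on-time message counts, both on-time rate variants, and mean
#' latency of on-time messages. Rates with empty denominators are `NA`,
#' never 0.
#'
#' @inheritParams compliance_rate
#' @return A tibble, one row per (setting, template).
#' @export
trial_stats <- function(log, events) {
  ev_all <- events[!events$one_way, ]
  combos <- dplyr::distinct(ev_all, .data$setting, .data$template_id)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    st <- combos$setting[i]; tid <- combos$template_id[i]
    st_f <- if (is.na(st)) NULL else st
    ev <- filter_events(events, tid, st_f)
    days <- dplyr::distinct(ev, .data$patient_id, .data$local_date)
    valid_all <- log[log$direction == "inbound" &
                       log$classification == "valid", ]
    good <- dplyr::distinct(ev[ev$event_id %in% valid_all$event_id, ],
                            .data$patient_id, .data$local_date)
    vw <- valid_with_windows(log, ev)
    mc <- message_counts(log, ev)
    tibble::tibble(
      setting = st, template_id = tid,
      query_days = nrow(days), compliant_days = nrow(good),
      compliance = rate_or_na(nrow(good), nrow(days)),
      messages_received = vw$n_received,
      messages_valid = vw$n_valid,
      messages_corrected = mc$n_corrected,
      messages_on_time = sum(vw$valid$on_time),
      validity = rate_or_na(vw$n_valid, vw$n_received),
      correction = rate_or_na(mc$n_corrected, vw$n_valid),
      on_time_over_valid = rate_or_na(sum(vw$valid$on_time), vw$n_valid),
      on_time_over_received = rate_or_na(sum(vw$valid$on_time),
                                         vw$n_received),
      mean_latency_min = mean_latency(log, events, tid, st_f))
  })
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, .data$setting, .data$template_id)
}
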