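#' Conversation state for one patient
#'
#' Tracks the pending report event a patient is expected to answer, how many
#' attempts they have made at it, and whether any attempt so far was invalid
#' (so that the eventual valid report can be flagged as corrected in real
#' time via the error-proofing loop).
#'
#' @param patient_id Opaque patient identifier.
#' @param pending_event A single-row event tibble (see [expand_schedule()])
#'   the patient is expected to answer, or `NULL`.
#' @param last_outbound UTC timestamp of the last message sent to the
#'   patient, or `NULL`.
#' @return An object of class `txt_conversation`.
#' @export
conversation_state <- function(patient_id, pending_event = NULL,
                               last_outbound = NULL) {
  structure(list(patient_id = patient_id,
                 pending_event = pending_event,
                 attempt_count = 0L,
                 had_invalid_attempt = FALSE,
                 last_outbound = last_outbound),
            class = "txt_conversation")
}

#' Set or clear the pending event
#'
#' Called when a prompt goes out (the event becomes pending) or after a valid
#' report is stored (attempt counters reset).
#'
#' @param state A [conversation_state()].
#' @param event Single-row event tibble, or `NULL` to clear.
#' @return Updated state.
#' @export
set_pending <- function(state, event) {
  state$pending_event <- event
  state$attempt_count <- 0L
  state$had_invalid_attempt <- FALSE
  state
}

#' Threshold alarm policy
#'
#' Providers set a personal numeric threshold per patient; a stored report
#' whose score is strictly above it raises a critical alarm to the listed
#' providers (e.g. threshold 5: a pain score of 6 alarms, a score of 5 does
#' not). For multi-site pain reports the score is the maximum intensity over
#' all reported sites — the clinically conservative aggregation.
#'
#' @param patient_id Patient the policy applies to.
#' @param metric Template id the threshold is defined on (pain only).
#' @param threshold Integer threshold on the metric's scale.
#' @param provider_ids Providers to notify.
#' @return An object of class `txt_policy`.
#' @export
threshold_policy <- function(patient_id, metric = "pain", threshold,
                             provider_ids = character()) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(patient_id = patient_id, metric = metric,
                 threshold = as.integer(threshold),
                 provider_ids = provider_ids),
            class = "txt_policy")
}

#' Alarm score of a pain report
#'
#' The single number compared against the patient's threshold: the maximum
#' intensity over all reported sites, or 0 for an explicit no-pain report.
#'
#' @param report A `pain_report`.
#' @return Integer score.
#' @export
alarm_score <- function(report) {
  stopifnot(inherits(report, "pain_report"))
  if (report$no_pain || nrow(report$pairs) == 0L) return(0L)
  max(report$pairs$intensity)
}

conv_action <- function(kind, text = NA_character_, ...) {
  c(list(kind = kind, text = text), list(...))
}

#' Handle one inbound patient message
#'
#' The core of the two-way loop. The message is validated against the
#' template of the pending event. An invalid message triggers an
#' error-proofing instruction (with a valid example) and keeps the event
#' pending so the patient can retry — attempts are unlimited within the
#' window. A valid message is stored in canonical form, flagged `corrected`
#' when an earlier attempt at the same event was invalid, and — for pain
#' reports under a threshold policy — raises an alarm when its score is
#' strictly above the patient's threshold. A message arriving with no
#' pending event gets a generic help reply and is logged but not stored.
#'
#' @param state A [conversation_state()].
#' @param text Raw inbound message.
#' @param at UTC timestamp of receipt.
#' @param registry [template_registry()] used to look up the pending
#'   template.
#' @param policy Optional [threshold_policy()] for this patient.
#' @return List with elements `state` (updated), `actions` (list of outbound
#'   actions, each with `kind` and `text`), `log` (list of [log_entry()]
#'   rows, inbound first), `report` (stored `txt_report` or `NULL`) and
#'   `alarm` (alarm record or `NULL`).
#' @export
handle_inbound <- function(state, text, at, registry = template_registry(),
                           policy = NULL) {
  stopifnot(inherits(state, "txt_conversation"), inherits(at, "POSIXct"))
  ev <- state$pending_event
  if (is.null(ev)) {
    help <- "We were not expecting a report right now. We will text you at your next scheduled report time."
    return(list(
      state = state,
      actions = list(conv_action("help", help)),
      log = list(
        log_entry(state$patient_id, "inbound", at, text,
                  classification = "other"),
        log_entry(state$patient_id, "outbound", at, help,
                  classification = "other")),
      report = NULL, alarm = NULL))
  }
  spec <- registry[[ev$template_id]]
  if (is.null(spec)) {
    abort(sprintf("no template '%s' in registry", ev$template_id))
  }
  res <- parse_report(text, spec)
  if (!res$valid) {
    state$attempt_count <- state$attempt_count + 1L
    state$had_invalid_attempt <- TRUE
    state$last_outbound <- at
    return(list(
      state = state,
      actions = list(conv_action("instruction", res$instruction,
                                 error_code = res$error_code)),
      log = list(
        log_entry(state$patient_id, "inbound", at, text,
                  event_id = ev$event_id, template_id = ev$template_id,
                  classification = "invalid"),
        log_entry(state$patient_id, "outbound", at, res$instruction,
                  event_id = ev$event_id, template_id = ev$template_id,
                  classification = "instruction")),
      report = NULL, alarm = NULL))
  }
  corrected <- state$had_invalid_attempt
  canonical <- render_report(res$report, spec)
  actions <- list(conv_action("store", canonical, report = res$report,
                              corrected = corrected))
  alarm <- NULL
  if (!is.null(policy) && inherits(res$report, "pain_report") &&
      identical(policy$metric, ev$template_id)) {
    score <- alarm_score(res$report)
    if (score > policy$threshold) {
      alarm <- list(patient_id = state$patient_id,
                    provider_ids = policy$provider_ids,
                    event_id = ev$event_id,
                    observed_score = score,
                    threshold = policy$threshold,
                    at = at)
      actions <- c(actions, list(conv_action(
        "alarm",
        sprintf("ALERT: patient %s reported pain %d (threshold %d).",
                state$patient_id, score, policy$threshold),
        alarm = alarm)))
    }
  }
  log <- list(
    log_entry(state$patient_id, "inbound", at, text,
              event_id = ev$event_id, template_id = ev$template_id,
              classification = "valid", corrected = corrected))
  state <- set_pending(state, NULL)
  list(state = state, actions = actions, log = log,
       report = res$report, alarm = alarm)
}

#' Handle a scale-report resubmission
#'
#' Multi-item scale reports may be resent within the event window to change
#' answers: a new valid parse supersedes the stored one (last write wins);
#' both raw messages stay in the log. Resubmissions after the window closes
#' are logged but not applied, and invalid resubmissions trigger the usual
#' error-proofing instruction without touching the stored report.
#'
#' @param state A [conversation_state()].
#' @param prior_report The currently stored `scale_report` for the event.
#' @param event The event the report belongs to (single-row tibble).
#' @param text Raw resubmission message.
#' @param at UTC timestamp of receipt.
#' @param registry [template_registry()].
#' @return List with `state`, `actions`, `log`, `report` (the now-current
#'   stored report) and `applied` (whether the resubmission replaced the
#'   prior report).
#' @export
handle_resubmission <- function(state, prior_report, event, text, at,
                                registry = template_registry()) {
  stopifnot(inherits(prior_report, "scale_report"))
  spec <- registry[[event$template_id]]
  res <- parse_report(text, spec)
  if (!res$valid) {
    return(list(
      state = state,
      actions = list(conv_action("instruction", res$instruction,
                                 error_code = res$error_code)),
      log = list(
        log_entry(state$patient_id, "inbound", at, text,
                  event_id = event$event_id, template_id = event$template_id,
                  classification = "invalid"),
        log_entry(state$patient_id, "outbound", at, res$instruction,
                  event_id = event$event_id, template_id = event$template_id,
                  classification = "instruction")),
      report = prior_report, applied = FALSE))
  }
  in_window <- is_on_time(event, at)
  list(
    state = state,
    actions = list(),
    log = list(
      log_entry(state$patient_id, "inbound", at, text,
                event_id = event$event_id, template_id = event$template_id,
                classification = "valid", corrected = FALSE)),
    report = if (in_window) res$report else prior_report,
    applied = in_window)
}

#' Send a one-way health tip
#'
#' Picks the next tip from the pool for this patient and emits it as a
#' one-way outbound message. Tips never create a pending event: a pain query
#' awaiting an answer stays pending across any number of tips.
#'
#' @param pool A [message_pool()].
#' @param state A [conversation_state()] (returned unchanged except for
#'   `last_outbound`).
#' @param at UTC send timestamp.
#' @return List with `pool` (updated history), `state`, `action` and `log`
#'   (one outbound `one_way` row).
#' @export
send_health_tip <- function(pool, state, at) {
  if (pool_size(pool) == 0L) abort("health tip pool is empty")
  sel <- pool_select(pool, state$patient_id)
  state$last_outbound <- at
  list(pool = sel$pool, state = state,
       action = conv_action("one_way", sel$text),
       log = list(log_entry(state$patient_id, "outbound", at, sel$text,
                            classification = "one_way")))
}
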