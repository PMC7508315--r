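#' Synthetic patient profile
#'
#' Behavioural parameters of one simulated adolescent: how often they answer
#' a query, how often a first answer has a format error, whether they retry
#' after the error-proofing instruction, and how long they take to respond.
#' Defaults emulate the reference pilot cohort: 95% response probability, 5%
#' format-error probability with 90% retry, log-normal latency with a 30
#' minute median, 5-day inpatient and 20-day outpatient enrollments.
#'
#' The pain process is a plain fixture, not a clinical model: each queried
#' day has pain with probability `pain_daily_probability`; painful days draw
#' a geometric site count (capped at the 8 template locations) with uniform
#' 1--10 intensities.
#'
#' @param patient_id Opaque identifier.
#' @param setting `"inpatient"`, `"outpatient"` or `"both"` (inpatient phase
#'   followed by outpatient phase).
#' @param respond_probability Probability of responding to a two-way query.
#' @param format_error_probability Probability the first response is
#'   malformed.
#' @param retry_probability Probability an error-proofed patient resends a
#'   corrected report.
#' @param latency_meanlog,latency_sdlog Log-normal response latency
#'   parameters (minutes).
#' @param pain_daily_probability Probability a queried day has any pain.
#' @param site_count_p Geometric parameter of the pain-site count.
#' @param attendance_probs Named probabilities over the attendance codes
#'   (must sum to 1).
#' @param scale_item_probs Probabilities over the scale item values 0..4.
#' @param inpatient_days,outpatient_days Enrollment lengths per phase.
#' @param pain_threshold Optional alarm threshold on the pain score.
#' @return An object of class `txt_profile`.
#' @export
patient_profile <- function(patient_id,
                            setting = c("inpatient", "outpatient", "both"),
                            respond_probability = 0.95,
                            format_error_probability = 0.05,
                            retry_probability = 0.9,
                            latency_meanlog = log(30),
                            latency_sdlog = 0.6,
                            pain_daily_probability = 0.6,
                            site_count_p = 0.55,
                            attendance_probs = c(WD = 0.85, AM = 0.05,
                                                 AF = 0.05, AW = 0.05),
                            scale_item_probs = rep(0.2, 5),
                            inpatient_days = 5L,
                            outpatient_days = 20L,
                            pain_threshold = NULL) {
  setting <- match.arg(setting)
  probs <- c(respond_probability, format_error_probability,
             retry_probability, pain_daily_probability)
  if (any(probs < 0 | probs > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  if (abs(sum(attendance_probs) - 1) > 1e-8) {
    abort("attendance_probs must sum to 1")
  }
  structure(list(patient_id = patient_id, setting = setting,
                 respond_probability = respond_probability,
                 format_error_probability = format_error_probability,
                 retry_probability = retry_probability,
                 latency_meanlog = latency_meanlog,
                 latency_sdlog = latency_sdlog,
                 pain_daily_probability = pain_daily_probability,
                 site_count_p = site_count_p,
                 attendance_probs = attendance_probs,
                 scale_item_probs = scale_item_probs,
                 inpatient_days = as.integer(inpatient_days),
                 outpatient_days = as.integer(outpatient_days),
                 pain_threshold = pain_threshold),
            class = "txt_profile")
}

#' Simulation configuration
#'
#' @param cohort List of [patient_profile()]s.
#' @param seed Integer RNG seed; a fixed seed makes the whole run
#'   byte-reproducible.
#' @param start_date First local enrollment date.
#' @param timezone IANA timezone of the cohort.
#' @param registry [template_registry()] the engine validates against.
#' @param tip_pool Optional [message_pool()] of one-way health tips; default
#'   is the shipped synthetic pool.
#' @param protocol Optional list of [recurrence()] rules overriding the
#'   default per-setting protocols for every patient (e.g. a single daily
#'   query for calibration experiments).
#' @return An object of class `txt_simconfig`.
#' @export
simulation_config <- function(cohort, seed = 1L,
                              start_date = as.Date("2024-01-08"),
                              timezone = "America/New_York",
                              registry = template_registry(),
                              tip_pool = NULL, protocol = NULL) {
  stopifnot(all(vapply(cohort, inherits, TRUE, "txt_profile")))
  if (is.null(tip_pool)) {
    tip_pool <- read_pool(system.file("extdata", "pools", "health_tips.txt",
                                      package = "txtpro"))
  }
  structure(list(cohort = cohort, seed = as.integer(seed),
                 start_date = as.Date(start_date), timezone = timezone,
                 registry = registry, tip_pool = tip_pool,
                 protocol = protocol),
            class = "txt_simconfig")
}

#' Mutate a valid message into an invalid one
#'
#' Draws one mutation from {drop header, out-of-range digit, unknown code,
#' wrong length} and applies it, re-parsing to guarantee the result fails
#' validation. Used to inject realistic format errors into simulated
#' traffic.
#'
#' @param text A message that parses under `spec`.
#' @param spec The [template_spec()] the text parses under.
#' @return A string that does not parse under `spec`.
#' @export
mutate_to_invalid <- function(text, spec) {
  stopifnot(parse_report(text, spec)$valid)
  candidates <- list(
    drop_header = function(x) substring(x, 2L),
    out_of_range = function(x) sub("[1-9]", "0", x),
    unknown_code = function(x) sub("[A-Z]+$", "XX", paste0(x, "Z")),
    wrong_length = function(x) substring(x, 1L, max(nchar(x) - 1L, 1L)))
  if (spec$kind == "digit_vector") {
    hi <- spec$item_range[2]
    candidates$out_of_range <- function(x) {
      if (hi < 9L) sub("[0-9]", as.character(hi + 1L), x) else paste0("X", x)
    }
  }
  for (f in candidates[sample.int(length(candidates))]) {
    mutated <- f(text)
    if (!identical(mutated, text) && !parse_report(mutated, spec)$valid) {
      return(mutated)
    }
  }
  paste0("??", text)  # always fails every grammar
}

random_report_text <- function(profile, spec) {
  if (spec$kind == "pair_list") {
    if (runif(1) > profile$pain_daily_probability) {
      return(spec$no_event_response)
    }
    n_sites <- min(1L + stats::rgeom(1L, profile$site_count_p),
                   length(spec$location_vocabulary))
    locs <- sample(spec$location_vocabulary, n_sites)
    ints <- sample(seq(spec$intensity_range[1], spec$intensity_range[2]),
                   n_sites, replace = TRUE)
    paste0(spec$header, paste0(ints, locs, collapse = "&"))
  } else if (spec$kind == "code_choice") {
    sample(names(profile$attendance_probs), 1L,
           prob = profile$attendance_probs)
  } else {
    vals <- seq(spec$item_range[1], spec$item_range[2])
    paste(sample(vals, spec$item_count, replace = TRUE,
                 prob = profile$scale_item_probs), collapse = "")
  }
}

profile_schedules <- function(profile, config) {
  scheds <- list()
  start <- config$start_date
  if (profile$setting %in% c("inpatient", "both")) {
    scheds[[length(scheds) + 1L]] <- list(
      sched = schedule(profile$patient_id, config$timezone,
                       config$protocol %||% inpatient_protocol(),
                       setting = "inpatient"),
      from = start, to = start + profile$inpatient_days - 1L)
    start <- start + profile$inpatient_days
  }
  if (profile$setting %in% c("outpatient", "both")) {
    scheds[[length(scheds) + 1L]] <- list(
      sched = schedule(profile$patient_id, config$timezone,
                       config$protocol %||% outpatient_protocol(),
                       setting = "outpatient"),
      from = start, to = start + profile$outpatient_days - 1L)
  }
  scheds
}

# plain list rows are much cheaper than tibble row indexing in the hot loop
df_rows <- function(df) {
  cols <- as.list(df)
  lapply(seq_len(nrow(df)), function(i) lapply(cols, `[[`, i))
}

#' Simulate a patient cohort end to end
#'
#' Expands each patient's protocol, then drives the real conversation engine
#' with generated traffic: for every two-way event the patient responds with
#' probability `respond_probability` at a log-normal latency after the
#' prompt; with probability `format_error_probability` the first message is
#' mutated to an invalid one (and, with probability `retry_probability`,
#' followed five minutes later by the corrected valid report). One-way tip
#' events draw from the health-tip pool. Ground truth about every intended
#' outcome is recorded independently of the engine, so classification tests
#' never rely on the system under test.
#'
#' @param config A [simulation_config()].
#' @return List with `log` (message log tibble), `events`, `reports` (stored
#'   report tibble), `truth` (per-event intended outcome), `alarms`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "txt_simconfig"))
  set.seed(config$seed)
  pool <- config$tip_pool
  all_events <- list(); all_log <- list(); all_truth <- list()
  all_reports <- list(); all_alarms <- list()
  for (profile in config$cohort) {
    policy <- if (!is.null(profile$pain_threshold)) {
      threshold_policy(profile$patient_id, "pain", profile$pain_threshold)
    }
    state <- conversation_state(profile$patient_id)
    for (phase in profile_schedules(profile, config)) {
      events <- expand_schedule(phase$sched, phase$from, phase$to)
      all_events[[length(all_events) + 1L]] <- events
      for (ev in df_rows(events)) {
        if (ev$one_way) {
          tip <- send_health_tip(pool, state, ev$window_start)
          pool <- tip$pool; state <- tip$state
          all_log[[length(all_log) + 1L]] <- tip$log
          next
        }
        spec <- config$registry[[ev$template_id]]
        all_log[[length(all_log) + 1L]] <- list(log_entry(
          profile$patient_id, "outbound", ev$window_start,
          sprintf("[%s query]", ev$template_id),
          event_id = ev$event_id, template_id = ev$template_id,
          classification = "prompt"))
        responded <- runif(1) < profile$respond_probability
        if (!responded) {
          all_truth[[length(all_truth) + 1L]] <- list(
            event_id = ev$event_id, responded = FALSE, had_error = FALSE,
            retried = FALSE, latency_min = NA_real_)
          next
        }
        latency <- rlnorm(1, profile$latency_meanlog, profile$latency_sdlog)
        # gateway timestamps have whole-second resolution
        at <- .POSIXct(round(as.numeric(ev$window_start) + latency * 60),
                       tz = "UTC")
        valid_text <- random_report_text(profile, spec)
        had_error <- runif(1) < profile$format_error_probability
        retried <- FALSE
        state <- set_pending(state, ev)
        if (had_error) {
          bad <- mutate_to_invalid(valid_text, spec)
          out <- handle_inbound(state, bad, at, config$registry, policy)
          state <- out$state
          all_log[[length(all_log) + 1L]] <- out$log
          retried <- runif(1) < profile$retry_probability
          if (retried) {
            at <- at + 5 * 60
            out <- handle_inbound(state, valid_text, at, config$registry,
                                  policy)
            state <- out$state
            all_log[[length(all_log) + 1L]] <- out$log
            if (!is.null(out$report)) {
              all_reports[[length(all_reports) + 1L]] <- list(
                patient_id = profile$patient_id, event_id = ev$event_id,
                template_id = ev$template_id, at = at,
                canonical_text = render_report(out$report, spec),
                corrected = TRUE)
            }
            if (!is.null(out$alarm)) {
              all_alarms[[length(all_alarms) + 1L]] <-
                out$alarm[c("patient_id", "event_id", "observed_score",
                            "threshold", "at")]
            }
          } else {
            state <- set_pending(state, NULL)
          }
        } else {
          out <- handle_inbound(state, valid_text, at, config$registry,
                                policy)
          state <- out$state
          all_log[[length(all_log) + 1L]] <- out$log
          all_reports[[length(all_reports) + 1L]] <- list(
            patient_id = profile$patient_id, event_id = ev$event_id,
            template_id = ev$template_id, at = at,
            canonical_text = render_report(out$report, spec),
            corrected = FALSE)
          if (!is.null(out$alarm)) {
            all_alarms[[length(all_alarms) + 1L]] <-
              out$alarm[c("patient_id", "event_id", "observed_score",
                          "threshold", "at")]
          }
        }
        all_truth[[length(all_truth) + 1L]] <- list(
          event_id = ev$event_id, responded = TRUE, had_error = had_error,
          retried = retried, latency_min = latency)
      }
    }
  }
  events <- dplyr::bind_rows(all_events)
  log <- as_message_log(unlist(all_log, recursive = FALSE))
  log <- dplyr::arrange(log, .data$at)
  truth <- dplyr::bind_rows(lapply(all_truth, tibble::as_tibble))
  reports <- if (length(all_reports)) {
    dplyr::bind_rows(lapply(all_reports, tibble::as_tibble))
  } else {
    tibble::tibble(patient_id = character(), event_id = character(),
                   template_id = character(),
                   at = as.POSIXct(character(), tz = "UTC"),
                   canonical_text = character(), corrected = logical())
  }
  alarms <- if (length(all_alarms)) {
    dplyr::bind_rows(lapply(all_alarms, tibble::as_tibble))
  } else {
    tibble::tibble(patient_id = character(), event_id = character(),
                   observed_score = integer(), threshold = integer(),
                   at = as.POSIXct(character(), tz = "UTC"))
  }
  list(log = log, events = events, reports = reports, truth = truth,
       alarms = alarms)
}
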