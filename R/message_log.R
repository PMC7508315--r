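## Message log: one row per inbound/outbound message. Classifications:
##   inbound : valid | invalid | other
##   outbound: prompt | reminder | instruction | one_way | other
## `corrected` is set only on valid inbound rows (TRUE when the patient fixed
## an initially invalid attempt within the same event).

log_columns <- c("patient_id", "direction", "at", "raw_text", "event_id",
                 "template_id", "classification", "corrected")

#' Message log container
#'
#' The append-only record of every message the engine sends or receives.
#' `empty_message_log()` returns a zero-row log with the canonical schema;
#' `log_entry()` builds one row (as a plain list, cheap to accumulate);
#' `as_message_log()` binds a list of such rows into a tibble, validating the
#' schema invariants (`corrected` only on valid inbound rows; every valid
#' inbound row references an event).
#'
#' @return A tibble with columns `patient_id`, `direction`
#'   (`"inbound"`/`"outbound"`), `at` (UTC `POSIXct`), `raw_text`,
#'   `event_id`, `template_id`, `classification`, `corrected`.
#' @export
empty_message_log <- function() {
  tibble::tibble(patient_id = character(), direction = character(),
                 at = as.POSIXct(character(), tz = "UTC"),
                 raw_text = character(), event_id = character(),
                 template_id = character(), classification = character(),
                 corrected = logical())
}

#' @rdname empty_message_log
#' @param patient_id,direction,at,raw_text,event_id,template_id,classification,corrected
#'   Field values for one log row.
#' @export
log_entry <- function(patient_id, direction, at, raw_text,
                      event_id = NA_character_,
                      template_id = NA_character_,
                      classification, corrected = NA) {
  list(patient_id = patient_id, direction = direction, at = at,
       raw_text = raw_text, event_id = event_id, template_id = template_id,
       classification = classification, corrected = corrected)
}

#' @rdname empty_message_log
#' @param rows List of [log_entry()] rows (or an existing log tibble).
#' @export
as_message_log <- function(rows) {
  if (is.data.frame(rows)) {
    log <- tibble::as_tibble(rows)
  } else if (length(rows) == 0L) {
    return(empty_message_log())
  } else {
    chr <- function(field) vapply(rows, function(r) as.character(r[[field]]),
                                  NA_character_)
    log <- tibble::tibble(
      patient_id = chr("patient_id"),
      direction = chr("direction"),
      at = .POSIXct(vapply(rows, function(r) as.numeric(r$at), 0),
                    tz = "UTC"),
      raw_text = chr("raw_text"),
      event_id = chr("event_id"),
      template_id = chr("template_id"),
      classification = chr("classification"),
      corrected = vapply(rows, function(r) as.logical(r$corrected), NA))
  }
  missing <- setdiff(log_columns, names(log))
  if (length(missing)) {
    abort(sprintf("message log is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  log <- log[log_columns]
  attr(log$at, "tzone") <- "UTC"
  bad <- !is.na(log$corrected) &
    !(log$direction == "inbound" & log$classification == "valid")
  if (any(bad)) {
    abort("corrected may be set only on valid inbound entries")
  }
  if (any(log$direction == "inbound" & log$classification == "valid" &
          is.na(log$event_id))) {
    abort("every valid inbound entry must reference an event")
  }
  log
}
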