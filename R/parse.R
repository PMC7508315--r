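#' Parsed report constructors
#'
#' Typed containers for validated report content. `pain_report()` holds
#' ordered (intensity, location) pairs or the no-pain flag;
#' `attendance_report()` a single attendance code; `scale_report()` the item
#' vector of a multi-item scale. Constructors enforce the type invariants
#' (no-pain iff no pairs, no duplicate location, item count and range) and are
#' what [parse_report()] returns on success.
#'
#' @param pairs A data frame / tibble with integer `intensity` and character
#'   `location` columns, in message order.
#' @param no_pain `TRUE` for an explicit no-pain report (then `pairs` must be
#'   empty).
#' @return An object of class `txt_report` (subclass `pain_report`,
#'   `attendance_report` or `scale_report`).
#' @export
pain_report <- function(pairs = tibble::tibble(intensity = integer(),
                                               location = character()),
                        no_pain = FALSE) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(all(c("intensity", "location") %in% names(pairs)))
  pairs$intensity <- as.integer(pairs$intensity)
  if (no_pain && nrow(pairs) > 0L) {
    abort("a no-pain report cannot carry pain pairs")
  }
  if (!no_pain && nrow(pairs) == 0L) {
    abort("a pain report needs at least one pair unless no_pain = TRUE")
  }
  if (anyDuplicated(pairs$location)) {
    abort("a location may appear at most once per report")
  }
  structure(list(pairs = pairs, no_pain = no_pain),
            class = c("pain_report", "txt_report"))
}

#' @rdname pain_report
#' @param code Attendance code (one of the template's `code_options`).
#' @export
attendance_report <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  structure(list(code = toupper(code)),
            class = c("attendance_report", "txt_report"))
}

#' @rdname pain_report
#' @param items Integer vector, one value per scale item, in message order.
#' @param item_count,item_range Expected length and inclusive per-item range.
#' @export
scale_report <- function(items, item_count = length(items),
                         item_range = c(0L, 4L)) {
  items <- as.integer(items)
  if (length(items) != item_count) {
    abort(sprintf("expected %d items, got %d", item_count, length(items)))
  }
  if (any(items < item_range[1] | items > item_range[2])) {
    abort(sprintf("items must lie in %d..%d", item_range[1], item_range[2]))
  }
  structure(list(items = items), class = c("scale_report", "txt_report"))
}

#' @export
print.txt_report <- function(x, ...) {
  if (inherits(x, "pain_report")) {
    if (x$no_pain) {
      cat("<pain_report> no pain\n")
    } else {
      cat("<pain_report>",
          paste(sprintf("%d@%s", x$pairs$intensity, x$pairs$location),
                collapse = ", "), "\n")
    }
  } else if (inherits(x, "attendance_report")) {
    cat("<attendance_report>", x$code, "\n")
  } else {
    cat("<scale_report>", paste(x$items, collapse = " "), "\n")
  }
  invisible(x)
}

## Error codes the validator can emit, in the order rules are checked.
report_error_codes <- c("bad_header", "unknown_location",
                        "intensity_out_of_range", "duplicate_location",
                        "bad_code", "wrong_length", "digit_out_of_range",
                        "empty", "trailing_garbage")

validation_result <- function(spec, valid, report = NULL, error_code = NULL) {
  if (!valid) {
    stopifnot(error_code %in% report_error_codes)
    instruction <- error_instruction(spec, error_code)
  } else {
    instruction <- NULL
  }
  structure(list(valid = valid, report = report, error_code = error_code,
                 instruction = instruction),
            class = "txt_validation")
}

#' @export
print.txt_validation <- function(x, ...) {
  if (x$valid) {
    cat("<valid>\n")
    print(x$report)
  } else {
    cat(sprintf("<invalid: %s>\n%s\n", x$error_code, x$instruction))
  }
  invisible(x)
}

#' Parse and validate an inbound report message
#'
#' Applies the template grammar to a raw inbound message. Matching is
#' case-insensitive and tolerates leading/trailing whitespace; accepted
#' reports are stored in canonical uppercase. Every grammar violation maps to
#' exactly one error code, the first one encountered left to right; an invalid
#' result always carries an error-proofing `instruction` embedding the
#' template's valid example, ready to send back to the patient.
#'
#' For `pair_list` templates, intensity digits are consumed greedily before
#' the alphabetic location code (so a two-digit `10` is unambiguous), the
#' no-event code (e.g. `PN`) must be the entire message, and a repeated
#' location is rejected so the patient restates the report. For
#' `digit_vector` templates non-digit characters are reported before a length
#' mismatch, which is reported before an out-of-range digit.
#'
#' @param text Raw message text.
#' @param spec A [template_spec()].
#' @return A `txt_validation` with fields `valid`, `report` (on success),
#'   `error_code` and `instruction` (on failure).
#' @examples
#' parse_report("P2CHEST&3BELLY", pain_template())
#' parse_report("p0head", pain_template())$error_code
#' @export
parse_report <- function(text, spec) {
  stopifnot(inherits(spec, "txt_template"),
            is.character(text), length(text) == 1L, !is.na(text))
  norm <- toupper(trimws(text))
  if (!nzchar(norm)) {
    return(validation_result(spec, FALSE, error_code = "empty"))
  }
  switch(spec$kind,
         pair_list = parse_pair_list(norm, spec),
         code_choice = parse_code_choice(norm, spec),
         digit_vector = parse_digit_vector(norm, spec))
}

parse_pair_list <- function(norm, spec) {
  fail <- function(code) validation_result(spec, FALSE, error_code = code)
  if (!is.null(spec$no_event_response)) {
    ne <- toupper(spec$no_event_response)
    if (norm == ne) {
      return(validation_result(spec, TRUE, report = pain_report(no_pain = TRUE)))
    }
    # the no-event code must be the whole message
    if (startsWith(norm, ne) &&
        !grepl("^[A-Z]", substring(norm, nchar(ne) + 1L))) {
      return(fail("trailing_garbage"))
    }
  }
  if (nzchar(spec$header)) {
    if (!startsWith(norm, spec$header)) return(fail("bad_header"))
    body <- substring(norm, nchar(spec$header) + 1L)
  } else {
    body <- norm
  }
  if (!nzchar(trimws(body))) return(fail("trailing_garbage"))
  if (grepl("^\\s*&|&\\s*&|&\\s*$", body)) return(fail("trailing_garbage"))
  tokens <- trimws(strsplit(body, "&", fixed = TRUE)[[1]])
  lo <- spec$intensity_range[1]; hi <- spec$intensity_range[2]
  seen <- character()
  ints <- integer(length(tokens)); locs <- character(length(tokens))
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    m <- regmatches(tok, regexec("^([0-9]+)(.*)$", tok))[[1]]
    if (length(m) == 0L || !nzchar(m[2])) return(fail("trailing_garbage"))
    intensity <- suppressWarnings(as.integer(m[2]))
    if (is.na(intensity) || intensity < lo || intensity > hi) {
      return(fail("intensity_out_of_range"))
    }
    loc <- m[3]
    if (!loc %in% spec$location_vocabulary) return(fail("unknown_location"))
    if (loc %in% seen) return(fail("duplicate_location"))
    seen <- c(seen, loc)
    ints[i] <- intensity; locs[i] <- loc
  }
  validation_result(spec, TRUE,
    report = pain_report(tibble::tibble(intensity = ints, location = locs)))
}

parse_code_choice <- function(norm, spec) {
  if (!norm %in% spec$code_options) {
    return(validation_result(spec, FALSE, error_code = "bad_code"))
  }
  validation_result(spec, TRUE, report = attendance_report(norm))
}

parse_digit_vector <- function(norm, spec) {
  fail <- function(code) validation_result(spec, FALSE, error_code = code)
  if (grepl("[^0-9]", norm)) return(fail("bad_code"))
  if (nchar(norm) != spec$item_count) return(fail("wrong_length"))
  items <- as.integer(strsplit(norm, "")[[1]])
  if (any(items < spec$item_range[1] | items > spec$item_range[2])) {
    return(fail("digit_out_of_range"))
  }
  validation_result(spec, TRUE,
    report = scale_report(items, spec$item_count, spec$item_range))
}

#' Render a report in canonical message form
#'
#' Inverse of [parse_report()] for valid reports:
#' `parse_report(render_report(r, spec), spec)$report` equals `r`. Used for
#' canonical storage and round-trip testing.
#'
#' @param report A `txt_report`.
#' @param spec The matching [template_spec()].
#' @return Canonical uppercase message text.
#' @export
render_report <- function(report, spec) {
  stopifnot(inherits(report, "txt_report"), inherits(spec, "txt_template"))
  if (inherits(report, "pain_report")) {
    if (report$no_pain) return(spec$no_event_response)
    paste0(spec$header,
           paste0(report$pairs$intensity, report$pairs$location,
                  collapse = "&"))
  } else if (inherits(report, "attendance_report")) {
    report$code
  } else {
    paste(report$items, collapse = "")
  }
}

#' Error-proofing instruction for an invalid message
#'
#' Builds the automatic reply to a message that failed validation: it names
#' the violated rule, restates the template's format, embeds a valid example,
#' and asks the patient to resend. This is the real-time correction mechanism
#' that lets initially invalid reports be fixed within the reporting window.
#'
#' @param spec A [template_spec()].
#' @param error_code One of the validator's error codes.
#' @return Instruction text containing `spec$valid_example`.
#' @export
error_instruction <- function(spec, error_code) {
  stopifnot(error_code %in% report_error_codes)
  rule <- switch(error_code,
    empty = "Your message was empty.",
    bad_header = sprintf("Your report must start with '%s'.", spec$header),
    unknown_location = sprintf(
      "Each pain entry needs one of the locations %s.",
      paste(spec$location_vocabulary, collapse = "/")),
    intensity_out_of_range = sprintf(
      "Pain intensity must be a number from %d to %d.",
      spec$intensity_range[1], spec$intensity_range[2]),
    duplicate_location = "Please report each location at most once.",
    bad_code = if (spec$kind == "code_choice") {
      sprintf("Please reply with one of %s.",
              paste(spec$code_options, collapse = "/"))
    } else {
      "Please reply with digits only."
    },
    wrong_length = sprintf("Please reply with exactly %d digits, one per question.",
                           spec$item_count),
    digit_out_of_range = sprintf("Each answer must be a digit from %d to %d.",
                                 spec$item_range[1], spec$item_range[2]),
    trailing_garbage = "Your message had extra characters we could not read.")
  format_hint <- switch(spec$kind,
    pair_list = sprintf(
      "Report pain as '%s' then intensity (%d-%d) and location pairs joined by '&'%s.",
      spec$header, spec$intensity_range[1], spec$intensity_range[2],
      if (!is.null(spec$no_event_response))
        sprintf(", or '%s' if you have no pain", spec$no_event_response)
      else ""),
    code_choice = sprintf("Reply with one of %s.",
                          paste(spec$code_options, collapse = "/")),
    digit_vector = sprintf("Reply with %d digits (%d-%d), one per question.",
                           spec$item_count, spec$item_range[1],
                           spec$item_range[2]))
  sprintf("Sorry, we could not read your report. %s %s For example, reply '%s'. Please resend your report.",
          rule, format_hint, spec$valid_example)
}
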