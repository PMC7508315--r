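#' Declare a report template
#'
#' A template is the grammar for one kind of structured self-report message.
#' Three kinds are supported: `pair_list` (a header letter followed by
#' intensity/location pairs separated by `&`, e.g. a multi-site pain report),
#' `code_choice` (a single fixed code from a small vocabulary, e.g. school
#' attendance), and `digit_vector` (a fixed-length run of digits, one per
#' questionnaire item, e.g. an 8-item pain-interference scale).
#'
#' Location and choice vocabularies must be non-empty, alphabetic and
#' uppercase, and no location code may be a prefix of another; prefix-freedom
#' guarantees every valid message has exactly one tokenization.
#' `valid_example` must itself parse under the template; it is embedded in
#' every error-proofing instruction.
#'
#' @param template_id Short identifier, e.g. `"pain"`.
#' @param kind One of `"pair_list"`, `"code_choice"`, `"digit_vector"`.
#' @param header Leading header character(s) for `pair_list` templates
#'   (possibly `""`).
#' @param intensity_range Inclusive integer interval `c(lo, hi)` for
#'   `pair_list` intensities.
#' @param location_vocabulary Ordered character vector of location codes
#'   (`pair_list` only).
#' @param code_options Character vector of allowed codes (`code_choice` only).
#' @param item_count,item_range Number of items and inclusive per-item digit
#'   interval (`digit_vector` only).
#' @param no_event_response Full-message code meaning "nothing to report"
#'   (e.g. the no-pain reply), or `NULL`.
#' @param valid_example A message that parses under this template, shown in
#'   error-proofing instructions.
#' @param description Free-text description of what the template measures.
#'
#' @return An object of class `txt_template`.
#' @seealso [pain_template()], [attendance_template()], [promis_template()],
#'   [parse_report()], [read_template()]
#' @export
template_spec <- function(template_id,
                          kind = c("pair_list", "code_choice", "digit_vector"),
                          header = "",
                          intensity_range = NULL,
                          location_vocabulary = NULL,
                          code_options = NULL,
                          item_count = NULL,
                          item_range = NULL,
                          no_event_response = NULL,
                          valid_example,
                          description = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(template_id), length(template_id) == 1L,
            nzchar(template_id))

  check_codes <- function(codes, what) {
    if (length(codes) == 0L) {
      abort(sprintf("%s must be non-empty", what))
    }
    ok <- nzchar(codes) & grepl("^[A-Z]+$", codes)
    if (!all(ok)) {
      abort(sprintf("%s must be non-empty uppercase alphabetic codes: %s",
                    what, paste(codes[!ok], collapse = ", ")))
    }
    if (anyDuplicated(codes)) {
      abort(sprintf("%s contains duplicates", what))
    }
  }

  if (kind == "pair_list") {
    if (is.null(intensity_range) || length(intensity_range) != 2L ||
        intensity_range[1] > intensity_range[2]) {
      abort("pair_list templates need intensity_range = c(lo, hi)")
    }
    check_codes(location_vocabulary, "location_vocabulary")
    for (i in seq_along(location_vocabulary)) {
      for (j in seq_along(location_vocabulary)) {
        if (i != j && startsWith(location_vocabulary[j],
                                 location_vocabulary[i])) {
          abort(sprintf(
            "location code '%s' is a prefix of '%s'; vocabulary must be prefix-free",
            location_vocabulary[i], location_vocabulary[j]))
        }
      }
    }
  } else if (kind == "code_choice") {
    check_codes(code_options, "code_options")
  } else {
    if (is.null(item_count) || item_count < 1L) {
      abort("digit_vector templates need a positive item_count")
    }
    if (is.null(item_range) || length(item_range) != 2L ||
        item_range[1] > item_range[2] ||
        item_range[1] < 0 || item_range[2] > 9) {
      abort("item_range must be an interval of single digits, lo <= hi")
    }
  }

  spec <- structure(
    list(template_id = template_id,
         kind = kind,
         header = toupper(header),
         intensity_range = if (!is.null(intensity_range)) as.integer(intensity_range),
         location_vocabulary = location_vocabulary,
         code_options = code_options,
         item_count = if (!is.null(item_count)) as.integer(item_count),
         item_range = if (!is.null(item_range)) as.integer(item_range),
         no_event_response = no_event_response,
         valid_example = valid_example,
         description = description),
    class = "txt_template")

  check <- parse_report(valid_example, spec)
  if (!check$valid) {
    abort(sprintf("valid_example '%s' does not parse under template '%s' (%s)",
                  valid_example, template_id, check$error_code))
  }
  spec
}

#' @export
print.txt_template <- function(x, ...) {
  cat(sprintf("<txt_template '%s'> kind=%s\n", x$template_id, x$kind))
  detail <- switch(x$kind,
    pair_list = sprintf("header '%s', intensities %d..%d, locations: %s%s",
                        x$header, x$intensity_range[1], x$intensity_range[2],
                        paste(x$location_vocabulary, collapse = ", "),
                        if (!is.null(x$no_event_response))
                          sprintf(" (none: '%s')", x$no_event_response) else ""),
    code_choice = sprintf("options: %s", paste(x$code_options, collapse = ", ")),
    digit_vector = sprintf("%d items, each %d..%d",
                           x$item_count, x$item_range[1], x$item_range[2]))
  cat(" ", detail, "\n", sep = "")
  cat(sprintf("  example: %s\n", x$valid_example))
  invisible(x)
}

#' Built-in report templates
#'
#' `pain_template()` is the daily multi-site pain report: header `P`, then
#' intensity (1--10, 10 = worst imaginable pain) and location pairs joined by
#' `&` over the eight most common sickle-cell pain sites, with `PN` meaning no
#' pain. `attendance_template()` is the two-character school attendance report
#' (`WD` whole day attended, `AM` absent morning, `AF` absent afternoon,
#' `AW` absent whole day). `promis_template()` is the weekly pediatric 8-item
#' pain-interference short form, answered as eight digits 0--4 in one message.
#'
#' @return A `txt_template`.
#' @export
pain_template <- function() {
  template_spec(
    template_id = "pain",
    kind = "pair_list",
    header = "P",
    intensity_range = c(1L, 10L),
    location_vocabulary = c("HEAD", "CHEST", "BELLY", "BACK",
                            "UL", "UR", "LL", "LR"),
    no_event_response = "PN",
    valid_example = "P2CHEST&3BELLY",
    description = "Daily pain intensity (1-10) and location report")
}

#' @rdname pain_template
#' @export
attendance_template <- function() {
  template_spec(
    template_id = "attendance",
    kind = "code_choice",
    code_options = c("WD", "AM", "AF", "AW"),
    valid_example = "WD",
    description = "Daily school attendance report")
}

#' @rdname pain_template
#' @export
promis_template <- function() {
  template_spec(
    template_id = "promis8",
    kind = "digit_vector",
    item_count = 8L,
    item_range = c(0L, 4L),
    valid_example = "01324101",
    description = "Weekly 8-item pain interference scale (0-4 per item)")
}

#' Template registry
#'
#' A named list of templates keyed by `template_id`, used by the conversation
#' engine and simulator to look up the grammar for a pending report event.
#'
#' @param ... `txt_template` objects; defaults to the three built-ins.
#' @return Named list of `txt_template`s.
#' @export
template_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 0L) {
    specs <- list(pain_template(), attendance_template(), promis_template())
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "template_id"))
}

#' Read / write a template definition file
#'
#' Templates are stored one per YAML document with keys matching the
#' [template_spec()] arguments. The three built-in templates ship under
#' `system.file("extdata", "templates", package = "txtpro")`.
#'
#' @param path Path to a YAML template file.
#' @return `read_template()` returns a `txt_template`; `write_template()`
#'   returns `path` invisibly.
#' @export
read_template <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("template_id", "kind", "header", "intensity_range",
               "location_vocabulary", "code_options", "item_count",
               "item_range", "no_event_response", "valid_example",
               "description")
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown)) {
    abort(sprintf("unknown template keys in %s: %s",
                  path, paste(unknown, collapse = ", ")))
  }
  do.call(template_spec, doc)
}

#' @rdname read_template
#' @param spec A `txt_template`.
#' @export
write_template <- function(spec, path) {
  stopifnot(inherits(spec, "txt_template"))
  doc <- spec[!vapply(spec, is.null, TRUE)]
  doc$description <- NULL
  doc <- c(doc, list(description = spec$description))
  yaml::write_yaml(doc, path)
  invisible(path)
}
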