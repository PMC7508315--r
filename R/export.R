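## De-identified CSV / JSON-lines export of logs, reports and events.
## Exports are whitelist-based: only the canonical schema columns ever reach
## a file, so stray fields (e.g. a real name accidentally joined onto a log)
## can never leak.

report_columns <- c("patient_id", "event_id", "template_id", "at",
                    "canonical_text", "corrected")

#' Export and re-import the message log and report store
#'
#' `export_log()` / `export_reports()` write RFC 4180 CSV with the canonical
#' column set only (timestamps as ISO 8601 UTC); any extra columns are
#' dropped, which keeps exports de-identified by construction.
#' `import_log()` reads a log CSV back; export -> import -> export is
#' byte-identical. `write_jsonl_log()` / `read_jsonl_log()` do the same over
#' JSON-lines for machine consumption.
#'
#' @param log Message log tibble.
#' @param path Destination file.
#' @return The path, invisibly (exports); a tibble (imports).
#' @export
export_log <- function(log, path) {
  log <- as_message_log(log[intersect(names(log), log_columns)])
  readr::write_csv(log, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_log
#' @export
import_log <- function(path) {
  log <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      direction = readr::col_character(),
      at = readr::col_datetime(),
      raw_text = readr::col_character(),
      event_id = readr::col_character(),
      template_id = readr::col_character(),
      classification = readr::col_character(),
      corrected = readr::col_logical()))
  as_message_log(log)
}

#' @rdname export_log
#' @param reports Report-store tibble (columns `patient_id`, `event_id`,
#'   `template_id`, `at`, `canonical_text`, `corrected`).
#' @export
export_reports <- function(reports, path) {
  missing <- setdiff(report_columns, names(reports))
  if (length(missing)) {
    abort(sprintf("report store is missing columns: %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(reports[report_columns], path, progress = FALSE)
  invisible(path)
}

#' @rdname export_log
#' @export
write_jsonl_log <- function(log, path) {
  log <- as_message_log(log[intersect(names(log), log_columns)])
  log$at <- format(log$at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  jsonlite::stream_out(log, con, verbose = FALSE, na = "null")
  invisible(path)
}

#' @rdname export_log
#' @export
read_jsonl_log <- function(path) {
  log <- jsonlite::stream_in(file(path), verbose = FALSE)
  log$at <- as.POSIXct(log$at, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (is.null(log$corrected)) log$corrected <- NA
  as_message_log(tibble::as_tibble(log))
}

#' Export / import expanded events
#'
#' Events round-trip through CSV with reminder offsets flattened to a
#' semicolon-separated string.
#'
#' @param events Event tibble from [expand_schedule()].
#' @param path Destination file.
#' @return The path, invisibly (export); an event tibble (import).
#' @export
export_events <- function(events, path) {
  flat <- events
  flat$reminder_offsets <- vapply(events$reminder_offsets, paste,
                                  "", collapse = ";")
  readr::write_csv(flat, path, progress = FALSE)
  invisible(path)
}

#' @rdname export_events
#' @export
import_events <- function(path) {
  flat <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      event_id = readr::col_character(),
      patient_id = readr::col_character(),
      template_id = readr::col_character(),
      setting = readr::col_character(),
      local_date = readr::col_date(),
      window_start = readr::col_datetime(),
      window_end = readr::col_datetime(),
      reminder_offsets = readr::col_character(),
      one_way = readr::col_logical()))
  flat$reminder_offsets <- lapply(flat$reminder_offsets, function(s) {
    if (is.na(s) || !nzchar(s)) numeric() else
      as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  attr(flat$window_start, "tzone") <- "UTC"
  attr(flat$window_end, "tzone") <- "UTC"
  flat
}

#' @rdname export_log
#' @param stats Summary tibble from [trial_stats()].
#' @export
export_stats <- function(stats, path) {
  readr::write_csv(stats, path, progress = FALSE)
  invisible(path)
}
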