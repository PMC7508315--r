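# Shared fixtures: random valid report generators, an independent brute-force
# pain tokenizer (the oracle for parse uniqueness), and a cached small
# simulation reused across test files.

pain_spec <- pain_template()
attendance_spec <- attendance_template()
promis_spec <- promis_template()
registry <- template_registry()

random_pain_message <- function() {
  if (runif(1) < 0.15) return("PN")
  n <- sample(1:4, 1)
  locs <- sample(pain_spec$location_vocabulary, n)
  ints <- sample(1:10, n, replace = TRUE)
  paste0("P", paste0(ints, locs, collapse = "&"))
}

random_valid_message <- function(spec) {
  switch(spec$kind,
         pair_list = random_pain_message(),
         code_choice = sample(spec$code_options, 1),
         digit_vector = paste(
           sample(spec$item_range[1]:spec$item_range[2], spec$item_count,
                  replace = TRUE),
           collapse = ""))
}

# Independent oracle: enumerate every digit/location split of every token and
# count the tokenizations that satisfy the grammar. A valid message must
# admit exactly one.
brute_pain_parse_count <- function(text) {
  norm <- toupper(trimws(text))
  if (identical(norm, "PN")) return(1L)
  if (!startsWith(norm, "P")) return(0L)
  tokens <- strsplit(substring(norm, 2), "&", fixed = TRUE)[[1]]
  if (length(tokens) == 0L) return(0L)
  per_token <- vapply(tokens, function(tok) {
    n <- nchar(tok)
    if (n < 2L) return(0L)
    hits <- 0L
    for (k in seq_len(n - 1L)) {
      digits <- substr(tok, 1L, k)
      loc <- substr(tok, k + 1L, n)
      if (grepl("^[0-9]+$", digits) &&
          as.integer(digits) >= 1L && as.integer(digits) <= 10L &&
          loc %in% pain_spec$location_vocabulary) {
        hits <- hits + 1L
      }
    }
    hits
  }, 0L)
  # duplicate locations invalidate the whole message under any tokenization
  locs <- sub("^[0-9]+", "", tokens)
  if (anyDuplicated(locs[locs %in% pain_spec$location_vocabulary])) return(0L)
  as.integer(prod(per_token))
}

make_event <- function(event_id = "E1", patient_id = "P1",
                       template_id = "pain", setting = "inpatient",
                       start = as.POSIXct("2024-01-08 13:00:00", tz = "UTC"),
                       window_minutes = 120, offsets = 60) {
  tibble::tibble(event_id = event_id, patient_id = patient_id,
                 template_id = template_id, setting = setting,
                 local_date = as.Date(start),
                 window_start = start,
                 window_end = start + window_minutes * 60,
                 reminder_offsets = list(offsets), one_way = FALSE)
}

# one small end-to-end simulation, computed once per test run
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- lapply(sprintf("S%02d", 1:4), function(id)
        patient_profile(id, "both", format_error_probability = 0.15,
                        pain_threshold = 5,
                        inpatient_days = 4L, outpatient_days = 10L))
      cache <<- simulate_cohort(simulation_config(cohort, seed = 11L))
    }
    cache
  }
})
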