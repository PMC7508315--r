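test_that("pain messages parse into ordered intensity/location pairs", {
  res <- parse_report("P2CHEST&3BELLY", pain_spec)
  expect_true(res$valid)
  expect_identical(res$report$pairs$intensity, c(2L, 3L))
  expect_identical(res$report$pairs$location, c("CHEST", "BELLY"))
  expect_false(res$report$no_pain)

  res <- parse_report("PN", pain_spec)
  expect_true(res$valid)
  expect_true(res$report$no_pain)
  expect_identical(nrow(res$report$pairs), 0L)

  # two-digit intensity disambiguated by greedy digit consumption
  res <- parse_report("P10BACK&1UL", pain_spec)
  expect_identical(res$report$pairs$intensity, c(10L, 1L))
  expect_identical(res$report$pairs$location, c("BACK", "UL"))
})

test_that("each pain grammar violation maps to one error code", {
  msgs <- c("P0HEAD", "P11HEAD", "P2CHEST&4CHEST", "P2NOSE", "2CHEST",
            "PN&2HEAD", "P", "P2CHEST&", "PCHEST", "", "   ")
  codes <- c("intensity_out_of_range", "intensity_out_of_range",
             "duplicate_location", "unknown_location", "bad_header",
             "trailing_garbage", "trailing_garbage", "trailing_garbage",
             "trailing_garbage", "empty", "empty")
  for (i in seq_along(msgs)) {
    res <- parse_report(msgs[i], pain_spec)
    expect_false(res$valid, info = msgs[i])
    expect_identical(res$error_code, codes[i], info = msgs[i])
    expect_match(res$instruction, pain_spec$valid_example, fixed = TRUE,
                 info = msgs[i])
  }
  # the first violation left-to-right wins
  expect_identical(parse_report("P0HEAD&4NOSE", pain_spec)$error_code,
                   "intensity_out_of_range")
  expect_identical(parse_report("P2NOSE&0HEAD", pain_spec)$error_code,
                   "unknown_location")
})

test_that("attendance and scale grammars validate and normalize", {
  expect_identical(parse_report("WD", attendance_spec)$report$code, "WD")
  expect_identical(parse_report(" aw ", attendance_spec)$report$code, "AW")
  expect_identical(parse_report("WX", attendance_spec)$error_code, "bad_code")

  res <- parse_report("01324101", promis_spec)
  expect_identical(res$report$items, c(0L, 1L, 3L, 2L, 4L, 1L, 0L, 1L))
  expect_identical(parse_report("0132410", promis_spec)$error_code,
                   "wrong_length")
  expect_identical(parse_report("01324105", promis_spec)$error_code,
                   "digit_out_of_range")
  expect_identical(parse_report("0132A101", promis_spec)$error_code,
                   "bad_code")
})

test_that("case and surrounding whitespace never change the parse", {
  set.seed(101)
  for (i in 1:50) {
    spec <- registry[[sample(names(registry), 1)]]
    msg <- random_valid_message(spec)
    scrambled <- paste0("  ", chartr("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                                     "abcdefghijklmnopqrstuvwxyz", msg), " ")
    a <- parse_report(msg, spec)
    b <- parse_report(scrambled, spec)
    expect_true(b$valid)
    expect_identical(a$report, b$report)
  }
})

test_that("render/parse round-trips every randomly generated valid report", {
  set.seed(202)
  for (i in 1:200) {
    spec <- registry[[sample(names(registry), 1)]]
    msg <- random_valid_message(spec)
    res <- parse_report(msg, spec)
    expect_true(res$valid, info = msg)
    canonical <- render_report(res$report, spec)
    back <- parse_report(canonical, spec)
    expect_identical(back$report, res$report, info = msg)
    expect_identical(render_report(back$report, spec), canonical)
  }
})

test_that("single-character mutations are either valid or get exactly one error code", {
  set.seed(303)
  alphabet <- c(LETTERS, as.character(0:9), "&", " ", "?")
  mutate1 <- function(msg) {
    n <- nchar(msg)
    op <- sample(c("insert", "delete", "substitute"), 1)
    pos <- sample(n, 1)
    ch <- sample(alphabet, 1)
    switch(op,
           insert = paste0(substr(msg, 1, pos), ch, substr(msg, pos + 1, n)),
           delete = paste0(substr(msg, 1, pos - 1), substr(msg, pos + 1, n)),
           substitute = paste0(substr(msg, 1, pos - 1), ch,
                               substr(msg, pos + 1, n)))
  }
  for (i in 1:300) {
    spec <- registry[[sample(names(registry), 1)]]
    mutated <- mutate1(random_valid_message(spec))
    res <- NULL
    expect_no_error(res <- parse_report(mutated, spec))
    if (res$valid) {
      # silent acceptance of out-of-range values is impossible: re-render and
      # check the canonical form parses to the same report
      expect_identical(
        parse_report(render_report(res$report, spec), spec)$report,
        res$report)
    } else {
      expect_length(res$error_code, 1L)
      expect_true(res$error_code %in% c(
        "bad_header", "unknown_location", "intensity_out_of_range",
        "duplicate_location", "bad_code", "wrong_length",
        "digit_out_of_range", "empty", "trailing_garbage"))
      expect_match(res$instruction, spec$valid_example, fixed = TRUE)
    }
  }
})

test_that("prefix-free vocabulary gives every valid pain message a unique tokenization", {
  set.seed(404)
  for (i in 1:100) {
    msg <- random_pain_message()
    expect_identical(brute_pain_parse_count(msg), 1L, info = msg)
    expect_true(parse_report(msg, pain_spec)$valid)
  }
  # and the brute-force count agrees with the parser on rejects
  for (msg in c("P2NOSE", "2CHEST", "P0HEAD", "P2CHEST&4CHEST")) {
    expect_identical(brute_pain_parse_count(msg), 0L, info = msg)
  }
})

test_that("error instructions name the violated rule and embed a valid example", {
  ins <- error_instruction(pain_spec, "intensity_out_of_range")
  expect_match(ins, "P2CHEST&3BELLY", fixed = TRUE)
  expect_match(ins, "1 to 10")
  ins <- error_instruction(attendance_spec, "bad_code")
  expect_match(ins, "WD/AM/AF/AW", fixed = TRUE)
  ins <- error_instruction(promis_spec, "wrong_length")
  expect_match(ins, "8 digits")
  expect_match(ins, "01324101", fixed = TRUE)
})

test_that("canonical rendering matches the message dialect", {
  r <- parse_report("p2chest&3belly", pain_spec)$report
  expect_identical(render_report(r, pain_spec), "P2CHEST&3BELLY")
  expect_identical(render_report(pain_report(no_pain = TRUE), pain_spec),
                   "PN")
  expect_identical(
    render_report(scale_report(rep(0L, 8)), promis_spec), "00000000")
})
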