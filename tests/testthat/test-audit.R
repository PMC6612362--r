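req1 <- conversion_request("morphine", "oral", 60, "oxycodone", "oral")
res1 <- convert(f1, req1)

test_that("append assigns gapless monotone record ids and is append-only", {
  log <- audit_log()
  expect_length(log, 0)
  for (i in 1:3) {
    log <- append_record(log, as_audit_record(req1, res1,
                                              timestamp = "2017-05-01T08:00:00Z"))
  }
  expect_length(log, 3)
  expect_identical(vapply(log$records, `[[`, integer(1), "record_id"), 1:3)
  expect_false(any(c("update_record", "delete_record") %in%
                     getNamespaceExports("omeconvert")))
})

test_that("records with fields outside the closed schema are rejected by name", {
  rec <- as_audit_record(req1, res1)
  rec$patient_name <- "John Doe"
  expect_error(append_record(audit_log(), rec), "patient_name")

  rec2 <- as_audit_record(req1, res1)
  rec2$indication <- "pain after the fall at home on Tuesday"
  expect_error(append_record(audit_log(), rec2), "closed category list")

  rec3 <- as_audit_record(req1, res1)
  rec3$timestamp <- "yesterday"
  expect_error(append_record(audit_log(), rec3), "ISO-8601")
})

test_that("usage summary tallies index/target drugs and breakthroughs separately", {
  log <- small_log(n_conv = 10, n_bt = 3)
  s <- summarize_usage(log)
  expect_identical(s$total_conversions, 10L)
  expect_identical(s$total_breakthrough, 3L)
  expect_identical(sum(s$index_counts), 10L)
  expect_identical(sum(s$target_counts), 10L)
  expect_length(s$quarantined_records, 0)

  empty <- summarize_usage(audit_log())
  expect_identical(empty$total_conversions, 0L)
  expect_identical(empty$total_breakthrough, 0L)
  expect_length(empty$index_counts, 0)
})

test_that("index and target tallies are conserved on any generated log", {
  for (seed in c(1, 2, 3)) {
    log <- build_study_log(seed = seed, n_conversions = 40,
                           n_no_equivalence = 4, n_defect_border = 3,
                           n_breakthrough = 15)
    s <- summarize_usage(log)
    expect_identical(sum(s$index_counts), s$total_conversions)
    expect_identical(sum(s$target_counts), s$total_conversions)
    expect_identical(s$total_conversions, 40L)
    expect_identical(s$total_breakthrough, 15L)
  }
})

test_that("logs round-trip through JSON-lines with identical summaries", {
  log <- build_study_log(seed = 8, n_conversions = 30, n_no_equivalence = 3,
                         n_defect_border = 2, n_breakthrough = 10)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(log, path)
  back <- read_audit_log(path)
  expect_length(back, length(log))
  expect_equal(summarize_usage(back), summarize_usage(log))
  # and the match analysis is identical too
  gold <- make_gold_standard(f1)
  expect_equal(match_rate(back, gold), match_rate(log, gold))
})

test_that("corrupt records are quarantined by position, not fatal", {
  log <- small_log(n_conv = 5, n_bt = 0)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_audit_log(log, path)
  lines <- readLines(path)
  lines[3] <- "{not json at all"
  writeLines(lines, path)
  s <- summarize_usage(read_audit_log(path))
  expect_identical(s$quarantined_records, 3L)
  expect_identical(s$total_conversions, 4L)
})

test_that("match rate excludes no-equivalence records and compares practical doses", {
  log <- build_study_log(seed = 4, n_conversions = 50, n_no_equivalence = 6,
                         n_defect_border = 5, n_breakthrough = 20,
                         patch_tie = "up")
  ms <- match_rate(log, make_gold_standard(f1))
  expect_identical(ms$total_records, 70L)
  expect_identical(ms$excluded_no_equivalence, 6L)
  expect_identical(ms$analyzed, 64L)
  expect_identical(ms$matched, 59L)  # the 5 border-exact defect records mismatch
  expect_equal(ms$match_rate, round_half_up(100 * 59 / 64, 1))
  expect_identical(ms$excluded_no_equivalence + ms$analyzed, ms$total_records)

  # corrected tool: everything matches
  fixed <- build_study_log(seed = 4, n_conversions = 50, n_no_equivalence = 6,
                           n_defect_border = 5, n_breakthrough = 20,
                           patch_tie = "down")
  expect_equal(match_rate(fixed, make_gold_standard(f1))$match_rate, 100)
})

test_that("match rate is invariant under record order permutation", {
  log <- build_study_log(seed = 12, n_conversions = 30, n_no_equivalence = 3,
                         n_defect_border = 2, n_breakthrough = 10)
  perm <- audit_log()
  idx <- local_seed(99, sample(length(log)))
  for (i in idx) {
    r <- log$records[[i]]
    r$record_id <- NULL
    perm <- append_record(perm, r)
  }
  gold <- make_gold_standard(f1)
  a <- match_rate(log, gold)
  b <- match_rate(perm, gold)
  expect_identical(a$match_rate, b$match_rate)
  expect_identical(a$analyzed, b$analyzed)
  expect_identical(a$matched, b$matched)
})

test_that("formulary version mismatch between log and gold standard is fatal", {
  log <- small_log(n_conv = 3, n_bt = 0)
  other <- f1
  other$version <- "F2"
  expect_error(match_rate(log, make_gold_standard(other)),
               "version mismatch")
})

test_that("match rate on an empty analyzable set is absent, not zero", {
  log <- audit_log()
  res <- convert(f1, conversion_request("morphine", "oral", 60,
                                        "buprenorphine", "oral"))
  log <- append_record(log, as_audit_record(
    conversion_request("morphine", "oral", 60, "buprenorphine", "oral"), res,
    timestamp = "2017-05-01T08:00:00Z"))
  ms <- match_rate(log, make_gold_standard(f1))
  expect_identical(ms$analyzed, 0L)
  expect_true(is.na(ms$match_rate))
})

test_that("percentages are rounded half-up to one decimal", {
  expect_equal(round_half_up(96.25, 1), 96.3)
  expect_equal(round_half_up(96.24, 1), 96.2)
  expect_equal(round_half_up(2.45, 1), 2.5)  # base round() would give 2.4
})

test_that("usage and audit CSV exports carry the fixed headers", {
  log <- small_log(n_conv = 6, n_bt = 2)
  s <- summarize_usage(log)
  upath <- withr::local_tempfile(fileext = ".csv")
  export_usage_csv(s, upath)
  lines <- readLines(upath)
  expect_true(any(grepl("^# total_conversions,6", lines)))
  header <- lines[!startsWith(lines, "#")][1]
  expect_match(header, "Opioid")
  expect_match(header, "As Index Opioid \\(n\\)")
  expect_match(header, "As Target Opioid \\(n\\)")
  df <- utils::read.csv(upath, comment.char = "#", check.names = FALSE)
  expect_identical(sum(df$`As Index Opioid (n)`), 6L)
  expect_identical(sum(df$`As Target Opioid (n)`), 6L)

  apath <- withr::local_tempfile(fileext = ".csv")
  export_audit_csv(log, apath)
  adf <- utils::read.csv(apath)
  expect_identical(nrow(adf), 8L)
  expect_identical(names(adf)[1:3], c("record_id", "timestamp", "kind"))
})
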