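test_that("the shipped narrow-scope SMQ carries the six QT/TdP preferred terms", {
  smq <- qt_smq()
  expect_s3_class(smq, "smq_definition")
  expect_equal(smq$code, 20000001L)
  expect_equal(nrow(smq$pts), 6L)
  expect_equal(
    smq$pts$code[match(c("Torsade de pointes", "Long QT syndrome congenital",
                         "Electrocardiogram QT prolonged"), smq$pts$name)],
    c(10044066L, 10057926L, 10014387L)
  )
  # stable data asset: repeated calls are bit-identical
  expect_identical(qt_smq(), qt_smq())
})

test_that("smq_definition rejects degenerate PT sets", {
  expect_error(smq_definition("x", 1, tibble::tibble(name = character(0),
                                                     code = integer(0))))
  expect_error(smq_definition("x", 1,
                              tibble::tibble(name = c("A", "A"), code = c(1, 1))),
               "duplicate")
  expect_error(smq_definition("x", 1, tibble::tibble(name = "A", code = -5)))
})

test_that("parse_report maps openFDA fields and leaves gaps as unknown/NA", {
  rec <- fx_record("R1", date = "20200115",
                   reactions = c("Torsade de pointes", "Nausea"),
                   drugs = list(fx_drug("furosemide", char = "1"),
                                fx_drug("aspirin", char = 2),
                                fx_drug(char = 3, raw = "MYSTERY PILL")),
                   age = 63, qualification = "1", country = "US",
                   outcomes = c("seriousnessdeath", "seriousnesshospitalization"))
  x <- parse_report(rec)
  expect_equal(nrow(x$reports), 1L)
  expect_equal(nrow(x$reactions), 2L)
  expect_equal(nrow(x$drugs), 3L)
  expect_equal(x$drugs$characterization, c(1L, 2L, 3L))
  expect_equal(x$drugs$generic_name, c("furosemide", "aspirin", NA))
  expect_equal(x$reports$receipt_date, as.Date("2020-01-15"))
  expect_equal(x$reports$qualification, "physician")
  expect_equal(x$reports$sex, "unknown")  # patientsex absent
  expect_setequal(x$reports$outcomes[[1]], c("death", "hospitalization"))
})

test_that("parse_report tolerates unknown fields and foreign enum values", {
  rec <- fx_record("R2", reactions = "Nausea", sex = "9", qualification = "42",
                   extra = list(futurefield = list(a = 1), companynumb = "X"))
  x <- expect_silent(parse_report(rec))
  expect_equal(x$reports$sex, "unknown")
  expect_equal(x$reports$qualification, "unknown")
  expect_equal(x$reports$outcomes[[1]], "unknown")
})

test_that("malformed records error in parse_report and are skip-logged by the reader", {
  no_id <- fx_record("R1")
  no_id$safetyreportid <- NULL
  expect_error(parse_report(no_id), "report ID")
  no_reac <- fx_record("R1")
  no_reac$patient$reaction <- NULL
  expect_error(parse_report(no_reac), "reaction")

  recs <- c(lapply(1:9, function(i) fx_record(paste0("R", i))), list(no_reac))
  x <- fx_stream(recs)
  expect_equal(nrow(x$reports), 9L)
  expect_equal(nrow(attr(x, "skip_log")), 1L)
})

test_that("stream reader applies the study window and counts exclusions", {
  dates <- c(rep("20100601", 7), "20030101", "20230501", "19990101")
  recs <- purrr::imap(dates, ~ fx_record(paste0("R", .y), date = .x))
  win <- study_window("2004-01-01", "2022-12-31")
  x <- fx_stream(recs, window = win)
  expect_equal(nrow(x$reports), 7L)
  expect_equal(attr(x, "n_window_excluded"), 3L)
  # without a window all ten load
  expect_equal(nrow(fx_stream(recs)$reports), 10L)
})

test_that("reader auto-detects the JSON-array and results-envelope dialects", {
  recs <- lapply(1:4, function(i) fx_record(paste0("R", i)))
  arr <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(recs, auto_unbox = TRUE)), arr)
  expect_equal(nrow(read_faers_reports(arr)$reports), 4L)
  env <- tempfile(fileext = ".json")
  writeLines(as.character(jsonlite::toJSON(list(results = recs),
                                           auto_unbox = TRUE)), env)
  expect_equal(nrow(read_faers_reports(env)$reports), 4L)
})

test_that("write/read round-trip reproduces a generated stream field for field", {
  sim <- simulate_faers(faers_sim_config(n_reports = 60, seed = 42))
  path <- tempfile(fileext = ".ndjson")
  write_faers_reports(sim$reports, path)
  back <- read_faers_reports(path)
  a <- sim$reports; b <- back
  expect_equal(b$reactions, a$reactions)
  expect_equal(b$drugs, a$drugs)
  cols <- setdiff(names(a$reports), "outcomes")
  expect_equal(as.data.frame(b$reports[cols]), as.data.frame(a$reports[cols]))
  expect_equal(lapply(b$reports$outcomes, sort), lapply(a$reports$outcomes, sort))
})

test_that("build_api_query OR-s every PT over the date range, deterministically", {
  win <- study_window("2004-01-01", "2022-12-31")
  q <- build_api_query(qt_smq(), win)
  for (pt in qt_smq()$pts$name) expect_match(q, pt, fixed = TRUE)
  expect_match(q, "20040101")
  expect_match(q, "20221231")
  expect_identical(q, build_api_query(qt_smq(), win))

  single <- smq_definition("one", 1, tibble::tibble(name = "Torsade de pointes",
                                                    code = 10044066L))
  q1 <- build_api_query(single, win)
  expect_match(q1, "Torsade de pointes", fixed = TRUE)
  expect_false(grepl("Long QT syndrome", q1))
})

test_that("study_window validates ordering", {
  expect_error(study_window("2022-01-01", "2004-01-01"))
  expect_s3_class(study_window("2004-01-01", "2004-01-01"), "study_window")
})
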