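test_that("out-of-range measurements raise exactly one alert each", {
  # the pilot's cold-object check: 30 degC against a 36-38 range
  rec <- vitals_record(1L, timestamp = 1000, temperature_c = 30,
                       hr_bpm = 72, spo2_pct = 97, respiration_bpm = 14)
  ev <- check_record(rec)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$measurement, "temperature_c")
  expect_identical(ev$bound, "min")
  expect_equal(ev$value, 30)
})

test_that("in-range records with no fall raise nothing", {
  rec <- vitals_record(1L, 0, temperature_c = 37, hr_bpm = 80,
                       spo2_pct = 97, respiration_bpm = 16, fall = FALSE)
  expect_identical(nrow(check_record(rec)), 0L)
})

test_that("a set fall flag always raises one alert, ranges regardless", {
  rec <- vitals_record(1L, 0, temperature_c = 37, hr_bpm = 80,
                       spo2_pct = 97, respiration_bpm = 16, fall = TRUE)
  ev <- check_record(rec)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$measurement, "fall")
})

test_that("absent fields are skipped, both bounds are checked", {
  # station record: no temperature / HR / fall at all
  rec <- vitals_record(2L, 0, spo2_pct = 90, respiration_bpm = 25,
                       gsr_ohms = 2e5)
  ev <- check_record(rec)
  expect_setequal(ev$measurement, c("spo2_pct", "respiration_bpm"))
  expect_setequal(ev$bound, c("min", "max"))
})

test_that("no false alerts strictly inside all ranges (property)", {
  set.seed(5)
  for (i in 1:25) {
    rec <- vitals_record(i, i, temperature_c = runif(1, 36.01, 37.99),
                         hr_bpm = runif(1, 60.1, 99.9),
                         spo2_pct = runif(1, 94.1, 99.9),
                         respiration_bpm = runif(1, 12.1, 19.9),
                         fall = FALSE)
    expect_identical(nrow(check_record(rec)), 0L)
  }
})

test_that("checking a record twice yields identical event lists", {
  rec <- vitals_record(3L, 60, hr_bpm = 130, fall = TRUE)
  expect_identical(check_record(rec), check_record(rec))
})

test_that("unknown measurements are skipped with a warning", {
  rec <- vitals_record(1L, 0, hr_bpm = 72)
  expect_warning(check_record(rec, data.frame(measurement = "spo2_pct",
                                              min = 94, max = 100)),
                 "no threshold range")
})

test_that("invalid ranges are rejected", {
  rec <- vitals_record(1L, 0, hr_bpm = 72)
  expect_error(check_record(rec, data.frame(measurement = "hr_bpm",
                                            min = 100, max = 60)),
               "min < max")
})

test_that("JSON serialization round-trips records exactly", {
  rec <- vitals_record(4L, timestamp = 1700000000.123,
                       temperature_c = 36.9, hr_bpm = 71.25,
                       spo2_pct = 96.5, respiration_bpm = 15,
                       gsr_ohms = 150000, fall = FALSE, location = 7L)
  back <- record_from_json(record_to_json(rec))
  expect_equal(back, rec)
})

test_that("absent fields are omitted from JSON, never null-filled", {
  rec <- vitals_record(5L, 0, hr_bpm = 70)
  js <- record_to_json(rec)
  expect_false(grepl("spo2", js))
  expect_false(grepl("null", js))
  back <- record_from_json(js)
  expect_null(back$spo2_pct)
  expect_equal(back$hr_bpm, 70)
})

test_that("JSON keys appear in canonical order with ISO timestamps", {
  rec <- vitals_record(6L, 86400, temperature_c = 37, hr_bpm = 70)
  js <- record_to_json(rec)
  expect_match(js, '"patient_id":6,"timestamp":"1970-01-02T00:00:00.000Z"',
               fixed = TRUE)
  expect_lt(regexpr("temperature_c", js), regexpr("hr_bpm", js))
})

test_that("non-finite values cannot be serialized", {
  rec <- vitals_record(7L, 0, hr_bpm = 70)
  rec$hr_bpm <- Inf
  expect_error(record_to_json(rec), "non-finite")
})

test_that("alerts append to a JSON-lines log", {
  rec <- vitals_record(1L, 0, temperature_c = 30)
  path <- withr::local_tempfile(fileext = ".jsonl")
  append_alert_log(check_record(rec), path)
  append_alert_log(check_record(rec), path)
  lines <- readLines(path)
  expect_length(lines, 2)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_identical(parsed$measurement, "temperature_c")
  expect_true(nzchar(parsed$logged_at))
})
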