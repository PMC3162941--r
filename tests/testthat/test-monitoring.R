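wide_stream <- function(mbp, spo2, patient_id = "p1",
                        start = "2026-01-01T00:00:00") {
  t0 <- as.POSIXct(start, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  data.frame(patient_id = patient_id,
             timestamp = t0 + seq_along(mbp) - 1L,
             ABP_mean = mbp, SpO2 = spo2, stringsAsFactors = FALSE)
}

test_that("extract_inputs prefers ABP_mean and falls back to SBP/DBP", {
  direct <- extract_inputs(list(ABP_mean = 95, SpO2 = 97))
  expect_equal(direct[c("mbp", "spo2")], list(mbp = 95, spo2 = 97))
  expect_equal(direct$mbp_source, "ABP_mean")
  fallback <- extract_inputs(list(ABP_sys = 120, ABP_dia = 60, SpO2 = 98))
  expect_equal(fallback$mbp, 80)   # (120 + 2*60)/3
  expect_equal(fallback$mbp_source, "sys_dia")
  none <- extract_inputs(list(SpO2 = 98))
  expect_true(is.na(none$mbp))
  expect_true(is.na(none$mbp_source))
})

test_that("an unstable-to-low-MBP stream emits exactly two alerts in order", {
  eng <- test_engine()
  recs <- wide_stream(mbp = c(rep(50, 10), rep(60, 10)),
                      spo2 = c(rep(85, 10), rep(97, 10)))
  res <- process_stream(recs, eng)
  expect_equal(nrow(res$timeline), 20L)
  expect_equal(unique(res$timeline$label), c("instability", "low_MBP"))
  expect_equal(nrow(res$alerts), 2L)
  expect_equal(res$alerts$label, c("instability", "low_MBP"))
  expect_equal(res$alerts$previous_label, c("", "instability"))
  expect_equal(res$alerts$urgency, c("high", "low"))
})

test_that("an all-stable stream emits no alerts", {
  eng <- test_engine()
  res <- process_stream(wide_stream(rep(105, 24), rep(97, 24)), eng)
  expect_equal(nrow(res$alerts), 0L)
  expect_true(all(res$timeline$label == "stable"))
  expect_true(all(res$timeline$urgency == "none"))
})

test_that("debouncing suppresses repeat alerts for the same label", {
  eng <- test_engine()
  # alternate stable / hypoxemia, one tick each, for 10 ticks
  mbp <- rep(105, 10)
  spo2 <- rep(c(97, 85), 5)
  recs <- wide_stream(mbp, spo2)
  no_db <- process_stream(recs, eng, debounce_seconds = 0)
  expect_equal(sum(no_db$alerts$label == "hypoxemia"), 5L)
  with_db <- process_stream(recs, eng, debounce_seconds = 10)
  expect_equal(sum(with_db$alerts$label == "hypoxemia"), 1L)
})

test_that("missing inputs carry the last label forward flagged stale", {
  eng <- test_engine()
  recs <- wide_stream(c(105, NA, NA, 105), c(97, NA, NA, 97))
  res <- process_stream(recs, eng)
  expect_equal(nrow(res$timeline), 4L)
  expect_equal(res$timeline$stale, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(res$timeline$label, rep("stable", 4))
  expect_true(all(is.na(res$timeline$score[res$timeline$stale])))
  # usable-input rows match the record count with usable inputs
  expect_equal(sum(!res$timeline$stale), 2L)
})

test_that("a long sensor gap raises one sensor-fault notice", {
  eng <- test_engine()
  recs <- wide_stream(c(105, rep(NA, 40)), c(97, rep(NA, 40)))
  res <- process_stream(recs, eng, stale_gap_seconds = 30)
  faults <- res$alerts[res$alerts$label == "sensor_fault", ]
  expect_equal(nrow(faults), 1L)
  expect_equal(faults$urgency, "medium")
})

test_that("alert counts never exceed label transitions and stay urgent", {
  eng <- test_engine()
  set.seed(505)
  recs <- wide_stream(runif(100, 30, 180), runif(100, 80, 100))
  res <- process_stream(recs, eng)
  transitions <- sum(res$timeline$label[-1] !=
                       res$timeline$label[-nrow(res$timeline)]) + 1L
  expect_lte(nrow(res$alerts), transitions)
  expect_false(any(res$alerts$urgency == "none"))
  expect_false(any(res$alerts$label == "stable"))
})

test_that("streams must be time-ordered; empty streams are fine", {
  eng <- test_engine()
  recs <- wide_stream(c(105, 105), c(97, 97))
  recs$timestamp <- rev(recs$timestamp)
  expect_error(process_stream(recs, eng), "non-decreasing")
  empty <- data.frame(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      ABP_mean = numeric(0), SpO2 = numeric(0))
  res <- process_stream(empty, eng)
  expect_equal(nrow(res$timeline), 0L)
  expect_equal(nrow(res$alerts), 0L)
})

test_that("the alert log is deterministic JSON Lines with full schema", {
  eng <- test_engine()
  recs <- wide_stream(c(rep(50, 5), rep(60, 5)),
                      c(rep(85, 5), rep(97, 5)))
  res <- process_stream(recs, eng)
  f1 <- tempfile(); f2 <- tempfile()
  write_alert_log(res$alerts, f1)
  write_alert_log(res$alerts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  lines <- readLines(f1)
  expect_equal(length(lines), nrow(res$alerts))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("patient_id", "timestamp", "label", "urgency",
                    "message") %in% names(parsed)))
  expect_match(parsed$timestamp, "^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}:\\d{2}$")
  # empty alert list -> empty file
  f3 <- tempfile()
  write_alert_log(res$alerts[0, ], f3)
  expect_equal(file.size(f3), 0)
})

test_that("read_records handles wide and long CSV and skips bad rows", {
  wide <- wide_stream(c(105, 110, 100), c(97, 96, 98))
  f <- tempfile(fileext = ".csv")
  out <- wide
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, f, row.names = FALSE)
  got <- read_records(f, "wide")
  expect_equal(nrow(got), 3L)
  expect_equal(got$ABP_mean, wide$ABP_mean)

  lng <- data.frame(
    patient_id = "p1",
    timestamp = rep(out$timestamp, each = 2),
    channel = rep(c("ABP_mean", "SpO2"), 3),
    value = as.character(c(105, 97, 110, 96, 100, 98)),
    stringsAsFactors = FALSE)
  lng$value[3] <- "oops"
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(lng, f2, row.names = FALSE)
  expect_warning(got2 <- read_records(f2, "long"), "1 malformed")
  expect_equal(sum(!is.na(got2$ABP_mean)), 2L)

  # empty file with header -> empty stream, no error
  f3 <- tempfile(fileext = ".csv")
  utils::write.csv(out[0, ], f3, row.names = FALSE)
  expect_equal(nrow(read_records(f3, "wide")), 0L)
  # mostly-broken file -> abort
  bad <- out; bad$timestamp <- "not-a-time"
  f4 <- tempfile(fileext = ".csv")
  utils::write.csv(bad, f4, row.names = FALSE)
  expect_error(read_records(f4, "wide"), "50%")
})
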