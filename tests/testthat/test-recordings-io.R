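test_that("WAV write/read round trip preserves structure exactly and amplitudes to 1 LSB", {
  set.seed(11)
  x <- runif(10000, -0.9, 0.9)
  rec <- recording(x, 10000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(rec, path)
  back <- read_wav(path)
  expect_equal(back$channel_count, 1L)
  expect_equal(back$sampling_rate, 10000)
  expect_equal(nrow(back$samples), 10000L)
  expect_equal(duration_s(back), 1)
  expect_true(all(back$samples >= -1 & back$samples <= 1))
  expect_lt(max(abs(back$samples[, 1] - x)), 2^-15)

  # stereo round trip
  rec2 <- recording(cbind(x, rev(x)), 10000)
  write_wav(rec2, path)
  back2 <- read_wav(path)
  expect_equal(back2$channel_count, 2L)
  expect_lt(max(abs(back2$samples - rec2$samples)), 2^-15)
})

test_that("all-zero WAV reads back as zero signal", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(recording(numeric(1000), 10000), path)
  back <- read_wav(path)
  expect_identical(max(back$samples) - min(back$samples), 0)
})

test_that("WAV reader rejects missing and malformed files", {
  expect_error(read_wav(file.path(tempdir(), "no_such.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), bad)
  expect_error(read_wav(bad), "RIFF")
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(matrix(0, 5, 3), 100), "channel_count")
  expect_error(recording(1:10, -1), "sampling_rate")
})

test_that("event files parse, sort, and validate", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "1, 30.00", "2, 33.50"), path)
  ev <- read_events(path)
  expect_equal(ev$time_s, c(30, 33.5))
  expect_equal(ev$kind, c("stimulus_on", "stimulus_off"))

  # unordered lines come back time-sorted
  writeLines(c("2, 33.5", "1, 30.0"), path)
  ev2 <- read_events(path)
  expect_equal(ev2$time_s, c(30, 33.5))
  expect_equal(ev2$kind, c("stimulus_on", "stimulus_off"))

  # empty file is a valid empty log
  writeLines(character(0), path)
  expect_equal(nrow(read_events(path)), 0L)

  # parse errors carry the line number
  writeLines(c("1, 30.0", "bogus line here"), path)
  expect_error(read_events(path), "line 2")

  # structurally invalid marker order
  writeLines(c("2, 10.0"), path)
  expect_error(read_events(path), "no prior stimulus_on")
})

test_that("both event-file dialects round trip", {
  ev <- event_log(c(30, 33.5, 60, 62), rep(c("stimulus_on", "stimulus_off"), 2))
  for (d in c("marker_time", "time_marker")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_events(ev, path, dialect = d)
    back <- read_events(path, dialect = d)
    expect_equal(back$time_s, ev$time_s)
    expect_equal(back$kind, ev$kind)
  }
})

test_that("packaged species catalog loads and matches the cohort table", {
  cat16 <- load_catalog()
  expect_equal(nrow(cat16), 16L)
  basil <- cat16[cat16$common_name == "Basil", ]
  expect_equal(basil$latin_name, "Ocimum basilicum")
  expect_true(basil$electrical_response)
  expect_equal(basil$n_recordings, 42L)
  expect_equal(basil$n_plants, 6L)
})

test_that("catalog summary equals independent column sums", {
  cat16 <- load_catalog()
  s <- catalog_summary(cat16)
  # one-line oracle over the same rows
  expect_equal(s$n_recordings_total, sum(cat16$n_recordings))
  expect_equal(s$n_plants_total, sum(cat16$n_plants))
  expect_equal(s$pct_responsive,
               100 * sum(cat16$electrical_response) / nrow(cat16))
})

test_that("catalog summary handles small and degenerate inputs", {
  one <- data.frame(common_name = "x", latin_name = "y",
                    electrical_response = TRUE, n_recordings = 7L,
                    n_plants = 2L)
  s <- catalog_summary(one)
  expect_equal(s$n_recordings_total, 7L)
  expect_equal(s$n_plants_total, 2L)
  expect_equal(s$pct_responsive, 100)

  two <- rbind(one, within(one, electrical_response <- FALSE))
  expect_equal(catalog_summary(two)$pct_responsive, 50)

  expect_error(catalog_summary(one[0, ]), "empty")
})

test_that("catalog loader validates header and values, accepts empty table", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("common_name,latin_name,electrical_response,n_recordings,n_plants",
             path)
  expect_equal(nrow(load_catalog(path)), 0L)

  writeLines(c("common_name,latin_name,n_recordings,n_plants", "a,b,1,1"), path)
  expect_error(load_catalog(path), "missing column")

  writeLines(c("common_name,latin_name,electrical_response,n_recordings,n_plants",
               "a,b,Maybe,1,1"), path)
  expect_error(load_catalog(path), "Yes or No")
})
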