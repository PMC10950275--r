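test_that("baseline subtraction zeroes the pre-stimulus median", {
  ev <- std_events()
  # constant trace -> identically zero
  rec <- recording(rep(5, 1000), 10)
  out <- baseline_subtract(rec, ev)
  expect_true(all(out$samples == 0))

  # pre-stimulus median 0.2 -> post-subtraction median 0
  set.seed(21)
  x <- rnorm(1000, 0, 0.01)
  pre_idx <- 1:300
  x[pre_idx] <- x[pre_idx] - median(x[pre_idx]) + 0.2
  out2 <- baseline_subtract(recording(x, 10), ev)
  expect_equal(median(out2$samples[pre_idx, 1]), 0, tolerance = 1e-12)

  # ramp: compare against a brute-force median oracle
  ramp <- seq(0, 1, length.out = 1000)
  oracle <- median(ramp[1:300])
  out3 <- baseline_subtract(recording(ramp, 10), ev)
  expect_equal(out3$samples[, 1], ramp - oracle)
})

test_that("baseline subtraction handles missing and early markers", {
  rec <- recording(rnorm(100), 10)
  expect_error(baseline_subtract(rec, event_log()), "no stimulus_on")
  early <- event_log(c(2, 5), c("stimulus_on", "stimulus_off"))
  expect_warning(baseline_subtract(rec, early, window_s = 30), "truncated")
})

test_that("sign inversion follows the negative-minimum rule with a no-inversion tie-break", {
  ep <- epoch(c(-5, 1, 3), 10)
  out <- sign_invert_if_negative(ep)
  expect_equal(out$samples, c(5, -1, -3))
  expect_true(out$inverted)

  ep2 <- sign_invert_if_negative(epoch(c(-2, 4), 10))
  expect_equal(ep2$samples, c(-2, 4))
  expect_false(ep2$inverted)

  tie <- sign_invert_if_negative(epoch(c(-3, 3), 10))
  expect_equal(tie$samples, c(-3, 3))
  expect_false(tie$inverted)

  # idempotent: applying twice equals applying once
  set.seed(5)
  for (i in 1:10) {
    e <- epoch(rnorm(50), 10)
    once <- sign_invert_if_negative(e)
    expect_identical(sign_invert_if_negative(once)$samples, once$samples)
  }
})

test_that("amplitude normalization fixes the extremum at exactly 1", {
  out <- normalize_amplitude(epoch(c(0, 2, 4), 10))
  expect_equal(out$samples, c(0, 0.5, 1))
  expect_true(out$normalized)

  # idempotence
  expect_equal(normalize_amplitude(out)$samples, out$samples)

  set.seed(6)
  r <- normalize_amplitude(epoch(rnorm(100), 10))
  expect_identical(max(abs(r$samples)), 1)

  expect_error(normalize_amplitude(epoch(numeric(10), 10)), "all-zero")
})

test_that("peak alignment puts every extremum at the anchor index", {
  fs <- 10
  t <- seq(0, 99.9, by = 0.1)
  e1 <- epoch(exp(-(t - 40)^2 / 8), fs)
  e2 <- epoch(exp(-(t - 45)^2 / 8), fs)
  aligned <- peak_align(list(e1, e2), pre_s = 10, post_s = 20)
  n_expected <- round(30 * fs) + 1
  anchor <- round(10 * fs) + 1
  for (a in aligned) {
    expect_length(a$samples, n_expected)
    expect_equal(which.max(abs(a$samples)), anchor)
  }

  # peak near the record end -> zero-padded and flagged
  e3 <- epoch(exp(-(t - 99)^2 / 0.5), fs)
  a3 <- peak_align(list(e3), pre_s = 5, post_s = 10)[[1]]
  expect_true(a3$padded)
  expect_equal(tail(a3$samples, 50), numeric(50))

  expect_identical(peak_align(list()), list())
})

test_that("invert -> normalize -> align composition anchors the extremum at +1", {
  fs <- 50
  set.seed(77)
  for (i in 1:8) {
    t <- seq(0, 59.98, by = 1 / fs)
    pol <- sample(c(-1, 1), 1)
    x <- pol * exp(-(t - runif(1, 20, 40))^2 / 6) + rnorm(length(t), 0, 0.02)
    ep <- normalize_amplitude(sign_invert_if_negative(epoch(x, fs)))
    al <- peak_align(list(ep), pre_s = 5, post_s = 10)[[1]]
    expect_equal(al$samples[round(5 * fs) + 1], 1)
    expect_equal(max(abs(al$samples)), 1)
  }
})

test_that("classification is invariant to constant offsets and to decimation", {
  sim <- generate_recording(fast_wound_preset(), seed = 13)
  res <- classify_response(sim$recording, sim$events)

  shifted <- sim$recording
  shifted$samples <- shifted$samples + 0.17
  res2 <- classify_response(shifted, sim$events)
  expect_equal(res2$responsive, res$responsive)
  expect_equal(res2$onset_latency_s, res$onset_latency_s)

  dec <- decimate_recording(sim$recording, 100)
  expect_equal(dec$sampling_rate, 100)
  res3 <- classify_response(dec, sim$events)
  expect_equal(res3$responsive, res$responsive)
  expect_equal(res3$onset_latency_s, res$onset_latency_s, tolerance = 0.1)
})

test_that("epoch export carries the anchor-relative time axis", {
  df <- epoch_to_df(epoch(1:5, 10, t0_offset_s = -0.2))
  expect_equal(df$time_s, c(-0.2, -0.1, 0, 0.1, 0.2))
  expect_equal(df$value, 1:5)
})
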