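test_that("generation is fully determined by (preset, seed)", {
  p <- fast_wound_preset()
  a <- generate_recording(p, seed = 7)
  b <- generate_recording(p, seed = 7)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$ground_truth, b$ground_truth)

  c <- generate_recording(p, seed = 8)
  expect_false(identical(a$recording$samples, c$recording$samples))
  expect_identical(names(a$ground_truth), names(c$ground_truth))
})

test_that("generator does not disturb the caller's RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(generate_recording(fast_wound_preset(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("responsive preset embeds a clear post-stimulus response", {
  sim <- generate_recording("wound_flame", seed = 1)
  x <- sim$recording$samples[, 1]
  fs <- sim$recording$sampling_rate
  pre_sd <- sd(x[seq_len(30 * fs)])
  post_ext <- max(abs(x[(30 * fs + 1):(90 * fs)]))
  expect_gt(post_ext, 5 * pre_sd)
})

test_that("ground-truth latencies stay inside the configured window", {
  p <- fast_wound_preset()
  lat <- vapply(1:20, function(i)
    generate_recording(p, seed = i)$ground_truth$latency_s, numeric(1))
  expect_true(all(lat >= 3 & lat <= 6))
  # and both polarities occur under the default 50/50 mixing
  pol <- vapply(1:20, function(i)
    generate_recording(p, seed = i)$ground_truth$polarity, numeric(1))
  expect_setequal(unique(pol), c(-1, 1))
})

test_that("propagation spec arithmetic matches hand calculation", {
  expect_equal(propagation_spec(16, 3.2)$delta_t_s, 5)
  expect_equal(propagation_spec(18, 9)$delta_t_s, 2)
  expect_error(propagation_spec(-1, 3), "separation_mm")
})

test_that("noiseless two-channel generation delays the peak by exactly the true lag", {
  p <- fast_two_channel_preset(fs = 1000, noiseless = TRUE)
  sim <- generate_two_channel(p, propagation_spec(16, 3.2), seed = 2)
  i1 <- which.max(abs(sim$recording$samples[, 1]))
  i2 <- which.max(abs(sim$recording$samples[, 2]))
  expect_identical(i2 - i1, as.integer(round(sim$ground_truth$delta_t_s * 1000)))
})

test_that("two-channel generation refuses non-responsive presets", {
  expect_error(
    generate_two_channel(fast_noise_preset(), propagation_spec(15, 3), seed = 1),
    "no propagating event")
})

test_that("amplifier model confines broadband noise to its band", {
  set.seed(31)
  fs <- 10000
  y <- amplifier_bandpass(rnorm(fs * 60), fs, 0.07, 8.8)
  pg <- tapered_periodogram(y, fs)
  outside <- sum(pg$power[pg$freq_hz < 0.07 | pg$freq_hz > 8.8])
  expect_lt(outside / sum(pg$power), 0.01)
  # the stopband above the upper corner is exactly empty
  expect_lt(sum(pg$power[pg$freq_hz > 8.8]) / sum(pg$power), 1e-9)
})

test_that("generated recordings carry no power above the amplifier's upper corner", {
  sim <- generate_recording(fast_wound_preset(fs = 1000), seed = 4)
  pg <- tapered_periodogram(sim$recording$samples[, 1], 1000)
  expect_lt(sum(pg$power[pg$freq_hz > 8.8]) / sum(pg$power), 1e-9)
})

test_that("two-channel preset velocity tables match the study design", {
  sundew <- preset("sundew_two_channel")
  expect_equal(sundew$velocity_list_mm_s, seq(2.2, 4.2, by = 0.2))
  expect_length(sundew$velocity_list_mm_s, 11L)
  expect_equal(mean(sundew$velocity_list_mm_s), 3.2)
  expect_equal(preset("tomato_two_channel")$velocity_list_mm_s, 9)
  expect_equal(preset("mimosa_two_channel")$velocity_list_mm_s, 8)
})

test_that("cohort generation matches the requested composition", {
  cohort <- generate_cohort(2, 1, seed = 9)
  expect_length(cohort, 3L)
  resp <- vapply(cohort, function(s) s$ground_truth$responsive, logical(1))
  expect_equal(sum(resp), 2L)
  expect_equal(sum(!resp), 1L)
  # determinism across calls
  again <- generate_cohort(2, 1, seed = 9)
  expect_identical(cohort[[1]]$recording$samples, again[[1]]$recording$samples)

  one <- generate_cohort(1, 0, seed = 9)
  expect_length(one, 1L)
  expect_true(one[[1]]$ground_truth$responsive)
  expect_error(generate_cohort(0, 0, seed = 9), "at least one")
})

test_that("artifact injection validates its kind and preserves full scale", {
  sim <- generate_recording(fast_wound_preset(), seed = 3)
  expect_error(inject_artifact(sim$recording, "wobble", seed = 1))
  for (k in c("fast_spike", "clipping", "baseline_jump")) {
    out <- inject_artifact(sim$recording, k, seed = 1)
    expect_true(all(abs(out$samples) <= 1))
    expect_false(identical(out$samples, sim$recording$samples))
  }
})

test_that("preset validation enforces the responsive/waveform pairing", {
  expect_error(species_preset("x", TRUE, NULL, "flame"), "waveform")
  expect_error(species_preset("x", FALSE, wound_potential_model(), "flame"),
               "waveform")
  expect_error(preset("unknown_species"), "unknown preset")
})
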