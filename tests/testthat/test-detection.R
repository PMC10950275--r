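test_that("pre-stimulus range equals a brute-force min/max oracle", {
  ev <- std_events()
  rec <- excursion_recording(height = 0)  # alternating +/-1 baseline
  rng <- prestimulus_range(rec, ev)
  expect_equal(c(rng$lo, rng$hi), c(-1, 1))
  expect_false(rng$degenerate)

  set.seed(101)
  x <- rnorm(1000)
  rec2 <- recording(x, 10)
  rng2 <- prestimulus_range(rec2, ev)
  fs <- 10
  oracle_idx <- (floor((30 - 30) * fs) + 1):ceiling(30 * fs)
  expect_identical(rng2$lo, min(x[oracle_idx]))
  expect_identical(rng2$hi, max(x[oracle_idx]))
})

test_that("a flat pre-stimulus baseline is widened to the range floor and flagged", {
  rec <- recording(rep(0.3, 1000), 10)
  rng <- prestimulus_range(rec, std_events())
  expect_true(rng$degenerate)
  expect_equal(rng$hi - rng$lo, detection_config()$min_prestim_range)
  expect_error(prestimulus_range(rec, event_log(0, "stimulus_on")),
               "no pre-stimulus data")
})

test_that("the 75% deviation rule applies strictly above the threshold", {
  ev <- std_events()
  # pre-range (-1, 1), R = 2: threshold at hi + 0.75 R = 2.5
  expect_true(classify_response(excursion_recording(2.6), ev)$responsive)
  expect_false(classify_response(excursion_recording(2.4), ev)$responsive)
  # boundary: exactly at the threshold is NOT a response ("more than")
  expect_false(classify_response(excursion_recording(2.5), ev)$responsive)
  expect_true(classify_response(excursion_recording(2.5 + 1e-6), ev)$responsive)
})

test_that("classification is symmetric under sign flip", {
  ev <- std_events()
  rec <- excursion_recording(2.6)
  neg <- rec; neg$samples <- -neg$samples
  a <- classify_response(rec, ev)
  b <- classify_response(neg, ev)
  expect_equal(a$responsive, b$responsive)
  expect_equal(a$onset_latency_s, b$onset_latency_s)

  sim <- generate_recording(fast_wound_preset(), seed = 112)
  neg2 <- sim$recording; neg2$samples <- -neg2$samples
  c1 <- classify_response(sim$recording, sim$events)
  c2 <- classify_response(neg2, sim$events)
  expect_equal(c1$responsive, c2$responsive)
  expect_equal(c1$onset_latency_s, c2$onset_latency_s)
})

test_that("scaling the response up never flips responsive to non-responsive", {
  p <- fast_wound_preset()
  sim <- generate_recording(p, seed = 113)
  stopifnot(classify_response(sim$recording, sim$events)$responsive)
  p2 <- p
  p2$waveform$amplitude <- 3
  sim2 <- generate_recording(p2, seed = 113)
  expect_true(classify_response(sim2$recording, sim2$events)$responsive)
})

test_that("latency is recovered on seeded wound fixtures", {
  # fixed 4.0 s latency fixture: recovery within +/- 0.5 s
  p4 <- fast_wound_preset(latency_s = 4)
  sim <- generate_recording(p4, seed = 120)
  res <- classify_response(sim$recording, sim$events)
  expect_true(res$responsive)
  expect_equal(res$onset_latency_s, 4, tolerance = 0.5 / 4)

  # randomized latencies: small-n recovery check (the full 100-fixture
  # suite runs in the acceptance tests)
  errs <- vapply(1:10, function(i) {
    s <- generate_recording(fast_wound_preset(), seed = 130 + i)
    r <- classify_response(s$recording, s$events)
    expect_true(r$responsive)
    r$onset_latency_s - s$ground_truth$latency_s
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.5)
})

test_that("detection result invariants hold", {
  sim <- generate_recording(fast_wound_preset(), seed = 140)
  res <- classify_response(sim$recording, sim$events)
  expect_identical(res$responsive, !is.na(res$onset_latency_s))
  expect_gte(res$onset_latency_s, 0)
  expect_equal(max(abs(res$epoch$samples)), 1)  # normalized epoch

  simn <- generate_recording(fast_noise_preset(), seed = 141)
  resn <- classify_response(simn$recording, simn$events)
  expect_false(resn$responsive)
  expect_true(is.na(resn$onset_latency_s))
  expect_null(resn$epoch)
})

test_that("species library pools epochs with a brute-force mean/sd oracle", {
  fs <- 50
  mk_result <- function(shift) {
    t <- seq(-5, 10, by = 1 / fs)
    samp <- exp(-(t)^2 / 2) + shift
    list(responsive = TRUE,
         epoch = epoch(samp / max(abs(samp)), fs, t0_offset_s = -5,
                       normalized = TRUE))
  }
  results <- lapply(seq(0, 0.11, by = 0.01), mk_result)  # 12 epochs
  entry <- build_species_library(results, library_config(), species = "test_sp")
  expect_equal(entry$status, "ok")
  expect_equal(entry$n_epochs, 12L)
  m <- sapply(results, function(r) r$epoch$samples)
  expect_equal(entry$mean_trace, rowMeans(m))
  expect_equal(entry$sd_trace, apply(m, 1, sd))
  expect_equal(entry$responsive_fraction, 1)

  # identical epochs -> SD identically zero
  same <- replicate(10, mk_result(0), simplify = FALSE)
  expect_true(all(build_species_library(same)$sd_trace == 0))

  # below the minimum-peaks rule -> explicit outcome, not an entry
  few <- build_species_library(results[1:3], library_config(min_peaks = 10))
  expect_equal(few$status, "insufficient_peaks")
  expect_equal(few$n_epochs, 3L)
})

test_that("cohort summary reports the responsive-species percentage", {
  s <- summarize_cohort(c(rep(TRUE, 9), rep(FALSE, 7)))
  expect_equal(s$n_species, 16L)
  expect_equal(s$n_responsive, 9L)
  expect_equal(s$pct_responsive_rounded, 56L)
  expect_equal(s$fraction, 9 / 16)

  expect_equal(summarize_cohort(rep(TRUE, 5))$pct_responsive, 100)
  expect_equal(summarize_cohort(rep(FALSE, 5))$pct_responsive, 0)
  expect_error(summarize_cohort(logical(0)), "empty")
})

test_that("multiple stimulations yield one result per trial", {
  fs <- 10
  x <- rep(c(-0.1, 0.1), length.out = 2000)
  x[round(40 * fs)] <- 2     # response after the first stimulus only
  rec <- recording(x, fs)
  ev <- event_log(c(30, 33, 120, 123),
                  rep(c("stimulus_on", "stimulus_off"), 2))
  out <- classify_trials(rec, ev)
  expect_length(out$trials, 2L)
  expect_true(out$trials[[1]]$responsive)
  expect_false(out$trials[[2]]$responsive)
  expect_true(out$responsive)
})
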