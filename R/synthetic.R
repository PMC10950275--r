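# Seeded synthetic recording generator.
#
# Emulates what the acquisition rig sees: a slow wound potential or an
# action potential embedded at a randomized latency after the stimulus
# marker, summed with white electrode noise, slow thermal/electrode drift
# and mains hum, then passed through the AC-coupled amplifier band limits
# and quantized onto a normalized ADC full scale of +/-1. Waveforms are
# phenomenological (double exponential), not biophysical. All randomness
# flows from one explicit integer seed per call.

#' Wound-potential waveform model
#'
#' Monophasic seconds-scale deflection: a double exponential with fast rise
#' and slow decay, scaled so its peak equals `amplitude`. The onset latency
#' after the stimulus is drawn uniformly from `latency_s` when a range is
#' given (the seconds-scale delay seen after flame stimulation), or fixed
#' when a single value is given.
#'
#' @param amplitude Peak amplitude in pre-amplifier arbitrary units.
#' @param latency_s Either a length-2 range (uniform draw, default
#'   `c(3, 6)` seconds) or a single fixed latency.
#' @param rise_tau_s,decay_tau_s Rise and decay time constants in seconds.
#' @param polarity `+1`, `-1`, or `NULL` to draw each polarity with
#'   probability 1/2 (exercises the sign-inversion rule downstream).
#' @return An object of class `wound_potential_model`.
#' @export
wound_potential_model <- function(amplitude = 1, latency_s = c(3, 6),
                                  rise_tau_s = 1, decay_tau_s = 8,
                                  polarity = NULL) {
  stopifnot(amplitude > 0, all(latency_s > 0), rise_tau_s > 0, decay_tau_s > 0)
  if (!is.null(polarity)) stopifnot(polarity %in% c(-1, 1))
  structure(list(amplitude = amplitude, latency_s = latency_s,
                 rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 polarity = polarity),
            class = c("wound_potential_model", "response_model"))
}

#' Action-potential waveform model
#'
#' Transient impulse of total duration `duration_s` (fast signals 1-3 s,
#' slow signals 5-15 s), modelled as a double exponential with
#' `rise = duration/6` and `decay = duration/3`.
#'
#' @param duration_s Impulse duration in seconds.
#' @param amplitude Peak amplitude in pre-amplifier arbitrary units.
#' @param latency_s Onset latency after the stimulus: range or fixed value,
#'   as in [wound_potential_model()].
#' @param polarity `+1`, `-1`, or `NULL` for a random sign.
#' @return An object of class `action_potential_model`.
#' @export
action_potential_model <- function(duration_s = 2, amplitude = 1,
                                   latency_s = c(3, 6), polarity = NULL) {
  stopifnot(duration_s > 0, amplitude > 0, all(latency_s > 0))
  if (!is.null(polarity)) stopifnot(polarity %in% c(-1, 1))
  structure(list(duration_s = duration_s, amplitude = amplitude,
                 latency_s = latency_s, polarity = polarity,
                 rise_tau_s = duration_s / 6, decay_tau_s = duration_s / 3),
            class = c("action_potential_model", "response_model"))
}

#' Amplifier model
#'
#' Band limits, gain and ADC scale of the acquisition chain. The
#' single-channel rig is gain 72x with a 0.07-8.8 Hz band at 10 kHz
#' sampling; the two-channel rig is gain ~55x with a 0.2-130 Hz band.
#'
#' @param gain Dimensionless amplifier gain.
#' @param band_low_hz,band_high_hz Corner frequencies in Hz.
#' @param sampling_rate_hz ADC sampling rate in Hz.
#' @param adc_full_scale Post-gain amplitude (arbitrary units) that maps to
#'   normalized full scale 1.0; larger signals clip.
#' @return An object of class `amplifier_model`.
#' @export
amplifier_model <- function(gain = 72, band_low_hz = 0.07, band_high_hz = 8.8,
                            sampling_rate_hz = 10000, adc_full_scale = 144) {
  stopifnot(gain > 0, band_low_hz > 0, band_low_hz < band_high_hz,
            band_high_hz < sampling_rate_hz / 2, adc_full_scale > 0)
  structure(list(gain = gain, band_low_hz = band_low_hz,
                 band_high_hz = band_high_hz,
                 sampling_rate_hz = sampling_rate_hz,
                 adc_full_scale = adc_full_scale),
            class = "amplifier_model")
}

#' Two-channel amplifier model
#'
#' Convenience constructor for the two-channel conduction-velocity rig
#' (0.2-130 Hz, gain ~55x).
#' @inheritParams amplifier_model
#' @export
amplifier_model_two_channel <- function(gain = 55, band_low_hz = 0.2,
                                        band_high_hz = 130,
                                        sampling_rate_hz = 10000,
                                        adc_full_scale = 144) {
  amplifier_model(gain, band_low_hz, band_high_hz, sampling_rate_hz,
                  adc_full_scale)
}

#' Noise model
#'
#' Pre-amplifier noise: white electrode noise, slow sinusoidal drift, and
#' mains hum at 50/60 Hz (random phases per recording).
#'
#' @param white_sd Standard deviation of white electrode noise (arbitrary
#'   units), referred to the 10 kHz acquisition rate; the generator keeps
#'   the noise density constant across sampling rates.
#' @param drift_amplitude,drift_period_s Slow drift sinusoid. Electrode
#'   polarization and thermal drift act on multi-minute scales (default
#'   period 300 s); the AC coupling suppresses it about 20-fold, leaving
#'   a visible but subdominant slow wander.
#' @param hum_amplitude,hum_freq_hz Mains hum.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(white_sd = 0.1, drift_amplitude = 0.3,
                        drift_period_s = 300, hum_amplitude = 0.2,
                        hum_freq_hz = 50) {
  stopifnot(white_sd >= 0, drift_amplitude >= 0, hum_amplitude >= 0,
            drift_period_s > 0, hum_freq_hz > 0)
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 drift_period_s = drift_period_s,
                 hum_amplitude = hum_amplitude, hum_freq_hz = hum_freq_hz),
            class = "noise_model")
}

#' Propagation specification for two-channel generation
#'
#' @param separation_mm Electrode separation along the branch in mm
#'   (electrodes were placed roughly 10-20 mm apart).
#' @param true_velocity_mm_s True propagation velocity in mm/s.
#' @return An object of class `propagation_spec` with the implied lag
#'   `delta_t_s = separation_mm / true_velocity_mm_s`.
#' @export
propagation_spec <- function(separation_mm = 15, true_velocity_mm_s) {
  stopifnot(separation_mm > 0, true_velocity_mm_s > 0)
  structure(list(separation_mm = separation_mm,
                 true_velocity_mm_s = true_velocity_mm_s,
                 delta_t_s = separation_mm / true_velocity_mm_s),
            class = "propagation_spec")
}

#' Species preset for the synthetic generator
#'
#' Bundles a response waveform (or none), stimulus type, amplifier and
#' noise models, and -- for two-channel presets -- the list of true
#' conduction velocities the preset emulates.
#'
#' @param name Preset name.
#' @param responsive Logical; must agree with `waveform` being non-NULL.
#' @param waveform A [wound_potential_model()], [action_potential_model()],
#'   or `NULL` for a non-responsive (noise-only) preset.
#' @param stimulus `"flame"` or `"tactile"`.
#' @param stimulus_duration_s Stimulus hold time in seconds (the flame was
#'   applied for 2-4 s; default 3).
#' @param amplifier An [amplifier_model()].
#' @param noise A [noise_model()].
#' @param velocity_list_mm_s Optional vector of true velocities for
#'   two-channel studies.
#' @return An object of class `species_preset`.
#' @export
species_preset <- function(name, responsive, waveform = NULL,
                           stimulus = c("flame", "tactile"),
                           stimulus_duration_s = 3,
                           amplifier = amplifier_model(),
                           noise = noise_model(),
                           velocity_list_mm_s = NULL) {
  stimulus <- match.arg(stimulus)
  if (responsive != !is.null(waveform))
    stop("responsive presets need a waveform; non-responsive presets must not have one")
  stopifnot(stimulus_duration_s >= 2, stimulus_duration_s <= 4,
            inherits(amplifier, "amplifier_model"),
            inherits(noise, "noise_model"))
  structure(list(name = name, responsive = responsive, waveform = waveform,
                 stimulus = stimulus,
                 stimulus_duration_s = stimulus_duration_s,
                 amplifier = amplifier, noise = noise,
                 velocity_list_mm_s = velocity_list_mm_s),
            class = "species_preset")
}

#' Built-in species presets
#'
#' @param name One of `"wound_flame"` (generic flame-stimulated wound
#'   potential), `"flytrap_ap"`, `"mimosa_fast"`, `"mimosa_slow"`
#'   (action potentials of 2, 2 and 10 s duration), `"noise_only"`,
#'   and the two-channel conduction-velocity presets
#'   `"sundew_two_channel"` (11 true velocities 2.2, 2.4, ..., 4.2 mm/s,
#'   mean 3.2 mm/s), `"tomato_two_channel"` (9 mm/s, flame) and
#'   `"mimosa_two_channel"` (8 mm/s, tactile).
#' @return A [species_preset()].
#' @export
preset <- function(name) {
  two_ch <- amplifier_model_two_channel()
  quiet_hum <- noise_model(white_sd = 0.05, hum_amplitude = 0.02)
  switch(name,
    wound_flame = species_preset("wound_flame", TRUE, wound_potential_model(),
                                 "flame"),
    flytrap_ap = species_preset("flytrap_ap", TRUE,
                                action_potential_model(duration_s = 2),
                                "tactile"),
    mimosa_fast = species_preset("mimosa_fast", TRUE,
                                 action_potential_model(duration_s = 2),
                                 "tactile"),
    mimosa_slow = species_preset("mimosa_slow", TRUE,
                                 action_potential_model(duration_s = 10),
                                 "tactile"),
    noise_only = species_preset("noise_only", FALSE, NULL, "flame"),
    sundew_two_channel = species_preset(
      "sundew_two_channel", TRUE,
      wound_potential_model(polarity = 1), "flame",
      amplifier = two_ch, noise = quiet_hum,
      velocity_list_mm_s = seq(2.2, 4.2, by = 0.2)),
    tomato_two_channel = species_preset(
      "tomato_two_channel", TRUE,
      wound_potential_model(polarity = 1), "flame",
      amplifier = two_ch, noise = quiet_hum,
      velocity_list_mm_s = 9),
    mimosa_two_channel = species_preset(
      "mimosa_two_channel", TRUE,
      action_potential_model(duration_s = 2, polarity = 1), "tactile",
      amplifier = two_ch, noise = quiet_hum,
      velocity_list_mm_s = 8),
    stop("unknown preset: ", name)
  )
}

#' Names of the built-in presets
#' @return Character vector of preset names accepted by [preset()].
#' @export
list_presets <- function() {
  c("wound_flame", "flytrap_ap", "mimosa_fast", "mimosa_slow", "noise_only",
    "sundew_two_channel", "tomato_two_channel", "mimosa_two_channel")
}

# settling lead-in (seconds) generated before t = 0 and discarded after
# filtering, so the AC-coupling transient never reaches the recording
.settle_s <- 30

# evaluate a response model on a time axis; returns the unit-polarity
# waveform scaled to `amplitude` plus its analytic peak offset after onset
eval_waveform <- function(model, t, onset_s) {
  r <- model$rise_tau_s; d <- model$decay_tau_s
  u <- pmax(t - onset_s, 0)
  w <- (1 - exp(-u / r)) * exp(-u / d)
  pk <- r * log(1 + d / r)
  wmax <- (1 - exp(-pk / r)) * exp(-pk / d)
  list(samples = model$amplitude * w / wmax, peak_offset_s = pk)
}

# draw latency and polarity for a response model (consumes RNG)
draw_response_params <- function(model) {
  lat <- if (length(model$latency_s) == 2L)
    stats::runif(1, model$latency_s[1], model$latency_s[2])
  else model$latency_s
  pol <- if (is.null(model$polarity)) sample(c(-1, 1), 1) else model$polarity
  list(latency_s = lat, polarity = pol)
}

# noise realization on time axis t (consumes RNG). White noise has a
# fixed spectral density: white_sd is referred to the 10 kHz acquisition
# rate, so the sampled SD scales with sqrt(fs / 10 kHz) and the in-band
# noise power is sampling-rate independent.
draw_noise <- function(noise, t, fs) {
  ph <- stats::runif(2, 0, 2 * pi)
  stats::rnorm(length(t), 0, noise$white_sd * sqrt(fs / 10000)) +
    noise$drift_amplitude * sin(2 * pi * t / noise$drift_period_s + ph[1]) +
    noise$hum_amplitude * sin(2 * pi * noise$hum_freq_hz * t + ph[2])
}

# amplifier chain: band limit, apply gain, quantize onto ADC scale
through_amplifier <- function(x, amp) {
  y <- amp$gain * amplifier_bandpass(x, amp$sampling_rate_hz,
                                     amp$band_low_hz, amp$band_high_hz)
  pmin(pmax(y / amp$adc_full_scale, -1), 1)
}

new_ground_truth <- function(responsive, latency_s = NA_real_,
                             onset_time_s = NA_real_, peak_time_s = NA_real_,
                             polarity = NA_real_, snr = NA_real_,
                             delta_t_s = NA_real_) {
  structure(list(responsive = responsive, latency_s = latency_s,
                 onset_time_s = onset_time_s, peak_time_s = peak_time_s,
                 polarity = polarity, snr = snr, delta_t_s = delta_t_s),
            class = "ground_truth")
}

#' Generate a synthetic single-channel recording
#'
#' Draws latency, polarity and noise from `seed`, embeds the preset's
#' waveform after the stimulus marker, applies the amplifier model, and
#' returns the recording with its event log and generation ground truth.
#' Identical `(preset, seed)` give bit-identical output.
#'
#' @param preset A [species_preset()] or the name of a built-in preset.
#' @param seed Integer seed; sole source of randomness.
#' @param duration_s Recording length in seconds (default 120).
#' @param stimulus_on_s Stimulus marker time (default 30 s; the off marker
#'   follows after the preset's stimulus duration).
#' @return A list with elements `recording` ([recording()]), `events`
#'   ([event_log()]), and `ground_truth` (true latency, onset and peak
#'   times, polarity, pre-filter SNR).
#' @examples
#' sim <- generate_recording("wound_flame", seed = 1)
#' sim$ground_truth$latency_s
#' @export
generate_recording <- function(preset, seed, duration_s = 120,
                               stimulus_on_s = 30) {
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(inherits(preset, "species_preset"),
            duration_s > stimulus_on_s, stimulus_on_s > 0)
  amp <- preset$amplifier
  fs <- amp$sampling_rate_hz
  # lead-in discarded after filtering: recordings begin with the AC
  # coupling settled, as when acquisition starts on a stable signal
  warm <- .settle_s
  t <- (seq_len(round((duration_s + warm) * fs)) - 1) / fs - warm
  events <- event_log(c(stimulus_on_s, stimulus_on_s + preset$stimulus_duration_s),
                      c("stimulus_on", "stimulus_off"))
  with_seed(seed, {
    if (preset$responsive) {
      par <- draw_response_params(preset$waveform)
      wv <- eval_waveform(preset$waveform, t, stimulus_on_s + par$latency_s)
      x <- par$polarity * wv$samples + draw_noise(preset$noise, t, fs)
      gt <- new_ground_truth(
        TRUE, latency_s = par$latency_s,
        onset_time_s = stimulus_on_s + par$latency_s,
        peak_time_s = stimulus_on_s + par$latency_s + wv$peak_offset_s,
        polarity = par$polarity,
        snr = if (preset$noise$white_sd > 0)
          preset$waveform$amplitude / preset$noise$white_sd else Inf)
    } else {
      x <- draw_noise(preset$noise, t, fs)
      gt <- new_ground_truth(FALSE)
    }
    y <- through_amplifier(x, amp)[t >= 0]
    rec <- recording(y, fs, species = preset$name,
                     plant_id = sprintf("synthetic_seed%d", as.integer(seed)))
    list(recording = rec, events = events, ground_truth = gt)
  })
}

#' Generate a synthetic two-channel recording with a propagating event
#'
#' Channel 2 carries the same response waveform as channel 1 delayed by
#' `delta_t = separation_mm / true_velocity_mm_s`, with independent noise
#' on each channel; the true lag is stored in the ground truth.
#'
#' @param preset A responsive [species_preset()] (or name) with a
#'   two-channel amplifier.
#' @param prop A [propagation_spec()].
#' @inheritParams generate_recording
#' @return As [generate_recording()], with `ground_truth$delta_t_s` set and
#'   a two-channel [recording()].
#' @export
generate_two_channel <- function(preset, prop, seed, duration_s = 120,
                                 stimulus_on_s = 30) {
  if (is.character(preset)) preset <- preset(preset)
  stopifnot(inherits(preset, "species_preset"),
            inherits(prop, "propagation_spec"))
  if (!preset$responsive)
    stop("two-channel generation needs a responsive preset: no propagating event exists")
  amp <- preset$amplifier
  fs <- amp$sampling_rate_hz
  warm <- .settle_s
  t <- (seq_len(round((duration_s + warm) * fs)) - 1) / fs - warm
  dt <- prop$delta_t_s
  events <- event_log(c(stimulus_on_s, stimulus_on_s + preset$stimulus_duration_s),
                      c("stimulus_on", "stimulus_off"))
  with_seed(seed, {
    par <- draw_response_params(preset$waveform)
    onset <- stimulus_on_s + par$latency_s
    w1 <- eval_waveform(preset$waveform, t, onset)
    w2 <- eval_waveform(preset$waveform, t, onset + dt)
    x1 <- par$polarity * w1$samples + draw_noise(preset$noise, t, fs)
    x2 <- par$polarity * w2$samples + draw_noise(preset$noise, t, fs)
    rec <- recording(cbind(through_amplifier(x1, amp)[t >= 0],
                           through_amplifier(x2, amp)[t >= 0]),
                     fs, species = preset$name,
                     plant_id = sprintf("synthetic_seed%d", as.integer(seed)))
    gt <- new_ground_truth(
      TRUE, latency_s = par$latency_s, onset_time_s = onset,
      peak_time_s = onset + w1$peak_offset_s, polarity = par$polarity,
      snr = if (preset$noise$white_sd > 0)
        preset$waveform$amplitude / preset$noise$white_sd else Inf,
      delta_t_s = dt)
    list(recording = rec, events = events, ground_truth = gt)
  })
}

#' Generate a synthetic cohort of one recording per species
#'
#' `n_responsive` recordings come from the responsive single-channel
#' presets (cycled) with response amplitude 10x the white-noise SD;
#' `n_nonresponsive` are noise-only. Species are labelled
#' `synthetic_resp_XX` / `synthetic_null_XX`, one recording each.
#'
#' @param n_responsive,n_nonresponsive Non-negative counts, not both zero.
#' @param seed Integer seed; each recording uses a derived child seed.
#' @return List of `list(recording, events, ground_truth)` with an `id`
#'   element added to each ground truth.
#' @export
generate_cohort <- function(n_responsive, n_nonresponsive, seed) {
  stopifnot(n_responsive >= 0, n_nonresponsive >= 0)
  if (n_responsive + n_nonresponsive == 0L)
    stop("cohort must contain at least one recording")
  resp_cycle <- c("wound_flame", "mimosa_fast", "mimosa_slow", "flytrap_ap")
  out <- list()
  for (i in seq_len(n_responsive)) {
    p <- preset(resp_cycle[(i - 1L) %% length(resp_cycle) + 1L])
    sim <- generate_recording(p, child_seed(seed, i))
    sim$recording$species <- sprintf("synthetic_resp_%02d", i)
    sim$id <- sprintf("synthetic_resp_%02d", i)
    out[[length(out) + 1L]] <- sim
  }
  for (i in seq_len(n_nonresponsive)) {
    sim <- generate_recording("noise_only", child_seed(seed, n_responsive + i))
    sim$recording$species <- sprintf("synthetic_null_%02d", i)
    sim$id <- sprintf("synthetic_null_%02d", i)
    out[[length(out) + 1L]] <- sim
  }
  out
}

#' Inject an artifact into a recording
#'
#' Adds one of the trace-level artifacts the rejection filters target:
#' `fast_spike` -- a transient of half-width drawn in 50-300 ms with
#' amplitude 10x the trace SD (a wire-touch); `clipping` -- at least
#' 200 ms of samples saturated at full scale; `baseline_jump` -- a
#' sustained step of at least 75% of the trace's peak amplitude
#' (a normalization-breaking baseline shift).
#'
#' @param rec A [recording()].
#' @param kind `"fast_spike"`, `"clipping"`, or `"baseline_jump"`.
#' @param seed Integer seed for the artifact's time/width/sign.
#' @return The recording with the artifact added to channel 1 (clamped to
#'   the `[-1, 1]` full scale).
#' @export
inject_artifact <- function(rec, kind = c("fast_spike", "clipping", "baseline_jump"),
                            seed) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "plant_recording"))
  fs <- rec$sampling_rate
  x <- rec$samples[, 1]
  n <- length(x)
  dur <- duration_s(rec)
  with_seed(seed, {
    if (kind == "fast_spike") {
      width <- stats::runif(1, 0.05, 0.3)             # half-prominence width, s
      center <- stats::runif(1, 10, dur - 10)
      sgn <- sample(c(-1, 1), 1)
      sd_x <- stats::sd(x)
      tt <- (seq_len(n) - 1) / fs
      sigma <- width / (2 * sqrt(2 * log(2)))         # FWHM -> Gaussian sigma
      x <- x + sgn * 10 * sd_x * exp(-(tt - center)^2 / (2 * sigma^2))
    } else if (kind == "clipping") {
      run <- stats::runif(1, 0.2, 0.5)
      t0 <- stats::runif(1, 10, dur - 10 - run)
      idx <- seq(round(t0 * fs) + 1, round((t0 + run) * fs))
      x[idx] <- sample(c(-1, 1), 1)
    } else {
      peak <- max(abs(x))
      step <- min(0.9, 1.6 * max(peak, 0.05))
      t0 <- stats::runif(1, 0.5 * dur, 0.85 * dur)    # after the response peak
      idx <- seq(round(t0 * fs) + 1, n)
      x[idx] <- x[idx] + step
    }
    rec$samples[, 1] <- pmin(pmax(x, -1), 1)
    rec
  })
}
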