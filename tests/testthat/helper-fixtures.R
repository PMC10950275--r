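# Small deterministic fixtures. Unit tests mostly run at reduced sampling
# rates (the container types are rate-agnostic); the acceptance suite uses
# the generator defaults (10 kHz, 120 s).

# single-channel wound preset at a reduced sampling rate for fast loops
fast_wound_preset <- function(fs = 500, latency_s = c(3, 6), polarity = NULL) {
  species_preset(
    "wound_flame_fast", TRUE,
    wound_potential_model(latency_s = latency_s, polarity = polarity),
    "flame",
    amplifier = amplifier_model(sampling_rate_hz = fs))
}

fast_noise_preset <- function(fs = 500) {
  species_preset("noise_only_fast", FALSE, NULL, "flame",
                 amplifier = amplifier_model(sampling_rate_hz = fs))
}

# two-channel preset at reduced rate, optionally noiseless
fast_two_channel_preset <- function(fs = 1000, noiseless = FALSE) {
  species_preset(
    "two_channel_fast", TRUE,
    wound_potential_model(latency_s = 4, polarity = 1), "flame",
    amplifier = amplifier_model_two_channel(sampling_rate_hz = fs),
    noise = if (noiseless) noise_model(0, 0, 300, 0, 50)
            else noise_model(white_sd = 0.05, hum_amplitude = 0.02))
}

# deterministic event log: stimulus at 30 s for 3 s
std_events <- function(on = 30, off = 33) {
  event_log(c(on, off), c("stimulus_on", "stimulus_off"))
}

# recording with alternating +/-1 pre-stimulus samples (range (-1, 1),
# median 0) and a single post-stimulus excursion of given height
excursion_recording <- function(height, fs = 10, dur = 100, stim = 30,
                                at = 40) {
  n <- dur * fs
  x <- rep(c(-1, 1), length.out = n)
  x[round(at * fs) + 1] <- height
  recording(x, fs)
}

# two-channel recording of clean Gaussian bumps with a known peak lag
bump_pair <- function(t1 = 42, t2 = 47, fs = 100, dur = 120, sd_s = 2,
                      amp = 0.5) {
  t <- (seq_len(dur * fs) - 1) / fs
  recording(cbind(amp * exp(-(t - t1)^2 / (2 * sd_s^2)),
                  amp * exp(-(t - t2)^2 / (2 * sd_s^2))), fs)
}
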