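# Zero-phase FFT low-pass and causal RC high-pass.
#
# The acquisition front end is AC-coupled: a single-pole RC high-pass sets
# the lower corner, and the anti-aliasing/analog chain sets the upper
# corner. The high-pass must be causal -- a zero-phase high-pass smears an
# acausal trough ahead of every slow deflection, which would contaminate
# the pre-stimulus window the detection criterion is anchored to.

#' Zero-phase FFT low-pass filter
#'
#' Applies a frequency-domain gain with a raised-cosine transition that
#' ends exactly at `f_hi`, so the output carries no power above the corner.
#' Zero-phase: peak times of in-band components are not shifted.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param f_hi Upper corner frequency in Hz (gain is 0 at and above it).
#' @param transition_frac Fractional width of the raised-cosine transition
#'   band, placed inside the passband: gain falls from 1 at
#'   `f_hi * (1 - transition_frac)` to 0 at `f_hi`.
#' @return Filtered numeric vector, same length as `x`.
#' @export
fft_lowpass <- function(x, fs, f_hi, transition_frac = 0.1) {
  n <- length(x)
  if (n == 0L) return(x)
  if (f_hi >= fs / 2) return(x)
  # reflect-pad so the implicit circular boundary is value-continuous;
  # otherwise start/end discontinuities ring through the whole kernel
  pad <- min(n, ceiling(4 * fs / (f_hi * transition_frac)))
  xr <- c(rev(x[seq_len(pad)]), x, rev(x[seq(n - pad + 1L, n)]))
  np <- length(xr)
  # pad further to a 2-3-5-smooth length so the FFT stays O(n log n)
  m <- stats::nextn(np, factors = c(2, 3, 5))
  xp <- c(xr, rep(xr[np], m - np))
  f <- (seq_len(m) - 1) / m * fs
  f <- pmin(f, fs - f)
  hi1 <- f_hi * (1 - transition_frac)
  g <- rep(1, m)
  idx <- f > hi1 & f < f_hi
  g[idx] <- 0.5 * (1 + cos(pi * (f[idx] - hi1) / (f_hi - hi1)))
  g[f >= f_hi] <- 0
  y <- Re(stats::fft(stats::fft(xp) * g, inverse = TRUE)) / m
  y[pad + seq_len(n)]
}

#' Causal single-pole RC high-pass filter
#'
#' Discrete-time model of an AC-coupling capacitor: `y[n] = a * (y[n-1] +
#' x[n] - x[n-1])` with `a = RC / (RC + 1/fs)` and `RC = 1 / (2 pi fc)`.
#' Causal, so slow deflections droop and undershoot *after* their onset,
#' as in a real amplifier, and never before.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param fc Lower corner (-3 dB) frequency in Hz.
#' @return Filtered numeric vector, same length as `x`.
#' @export
rc_highpass <- function(x, fs, fc) {
  n <- length(x)
  if (n == 0L) return(x)
  rc <- 1 / (2 * pi * fc)
  a <- rc / (rc + 1 / fs)
  dx <- c(0, diff(x))
  as.numeric(stats::filter(a * dx, a, method = "recursive"))
}

#' Amplifier band-limiting model
#'
#' Applies the acquisition chain's band limits to a pre-amplifier signal:
#' causal RC high-pass at `band_low_hz` (AC coupling) followed by a
#' zero-phase low-pass ending at `band_high_hz`.
#'
#' @param x Numeric vector at sampling rate `fs`.
#' @param fs Sampling rate in Hz.
#' @param band_low_hz,band_high_hz Corner frequencies in Hz,
#'   `0 < band_low_hz < band_high_hz < fs/2`.
#' @return Band-limited numeric vector.
#' @export
amplifier_bandpass <- function(x, fs, band_low_hz, band_high_hz) {
  if (!(band_low_hz > 0 && band_low_hz < band_high_hz && band_high_hz < fs / 2))
    stop("require 0 < band_low_hz < band_high_hz < fs/2")
  fft_lowpass(rc_highpass(x, fs, band_low_hz), fs, band_high_hz)
}

# anti-aliased decimation of one channel to (about) target_hz; returns
# list(x, fs). Keeps the original rate when it is already at or below target.
decimate_signal <- function(x, fs, target_hz) {
  if (fs <= target_hz) return(list(x = x, fs = fs))
  by <- max(1L, floor(fs / target_hz))
  fs_out <- fs / by
  xl <- fft_lowpass(x, fs, 0.45 * fs_out)
  list(x = xl[seq(1L, length(xl), by = by)], fs = fs_out)
}

#' Hann-tapered periodogram
#'
#' Single-taper power spectrum used as the oracle for the generator's
#' spectral contract. The taper controls leakage from the finite window and
#' from filter edge transients, which would otherwise masquerade as
#' low-frequency power.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return A data.frame with columns `freq_hz` (0 to Nyquist) and `power`.
#' @export
tapered_periodogram <- function(x, fs) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  sp <- Mod(stats::fft(x * w))^2
  half <- seq_len(floor(n / 2) + 1L)
  data.frame(freq_hz = (half - 1) / n * fs, power = sp[half])
}
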