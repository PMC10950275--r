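# Epoch-level preprocessing: the analysis convention is that recordings
# are baseline-subtracted, normalized for signal amplitude, peak-aligned,
# and sign inverted when the peak response is a negative minimum, so that
# traces from different plants and polarities can be averaged.

#' Construct an epoch
#'
#' A fixed-length signal segment cut around an anchor (peak or stimulus).
#'
#' @param samples Numeric vector of amplitudes.
#' @param sampling_rate Sampling rate in Hz.
#' @param t0_offset_s Time of `samples[1]` relative to the anchor, in
#'   seconds (negative when the window starts before the anchor).
#' @param normalized,inverted,padded Bookkeeping flags.
#' @return An object of class `epoch`.
#' @export
epoch <- function(samples, sampling_rate, t0_offset_s = 0,
                  normalized = FALSE, inverted = FALSE, padded = FALSE) {
  stopifnot(is.numeric(samples), sampling_rate > 0)
  structure(list(samples = as.numeric(samples), sampling_rate = sampling_rate,
                 t0_offset_s = t0_offset_s, normalized = normalized,
                 inverted = inverted, padded = padded),
            class = "epoch")
}

#' @export
print.epoch <- function(x, ...) {
  cat(sprintf("<epoch> %d samples @ %g Hz, t0 %+0.2f s%s%s%s\n",
              length(x$samples), x$sampling_rate, x$t0_offset_s,
              if (x$normalized) ", normalized" else "",
              if (x$inverted) ", sign-inverted" else "",
              if (x$padded) ", zero-padded" else ""))
  invisible(x)
}

#' Subtract the pre-stimulus baseline from a recording
#'
#' The median of the window `[stimulus_on - window_s, stimulus_on)` is
#' subtracted from every sample of every channel (channel 1's window sets
#' the baseline per channel independently). The median is robust to
#' pre-stimulus artifacts. If the stimulus sits closer to the recording
#' start than `window_s`, the window shrinks to the available data with a
#' warning.
#'
#' @param rec A [recording()].
#' @param events An [event_log()] with at least one `stimulus_on`.
#' @param window_s Baseline window length in seconds (default 30).
#' @return The recording with per-channel baselines removed.
#' @export
baseline_subtract <- function(rec, events, window_s = 30) {
  stopifnot(window_s > 0)
  ons <- stimulus_onsets(events)
  if (!length(ons)) stop("no stimulus_on marker: cannot anchor baseline window")
  stim <- ons[1]
  fs <- rec$sampling_rate
  start_s <- stim - window_s
  if (start_s < 0) {
    warning("baseline window truncated to available pre-stimulus data")
    start_s <- 0
  }
  i0 <- floor(start_s * fs) + 1L
  i1 <- max(i0, ceiling(stim * fs))
  for (ch in seq_len(rec$channel_count)) {
    rec$samples[, ch] <- rec$samples[, ch] -
      stats::median(rec$samples[i0:i1, ch])
  }
  rec
}

#' Invert an epoch's sign when its extremum is a negative minimum
#'
#' If `|min| > |max|` every sample is multiplied by -1 and the `inverted`
#' flag set, so the extremum is non-negative. Ties (`|min| == |max|`) are
#' left unchanged. Idempotent.
#'
#' @param ep An [epoch()].
#' @return The (possibly inverted) epoch.
#' @export
sign_invert_if_negative <- function(ep) {
  stopifnot(inherits(ep, "epoch"), length(ep$samples) > 0)
  if (abs(min(ep$samples)) > abs(max(ep$samples))) {
    ep$samples <- -ep$samples
    ep$inverted <- TRUE
  }
  ep
}

#' Normalize an epoch's amplitude
#'
#' Divides all samples by the extremum magnitude so that
#' `max(abs(samples)) == 1` exactly.
#'
#' @param ep An [epoch()].
#' @return The normalized epoch.
#' @export
normalize_amplitude <- function(ep) {
  stopifnot(inherits(ep, "epoch"))
  m <- max(abs(ep$samples))
  if (m == 0) stop("cannot normalize an all-zero epoch")
  ep$samples <- ep$samples / m
  ep$normalized <- TRUE
  ep
}

# cut [center - pre_s, center + post_s] out of a signal vector,
# zero-padding where the window leaves the data
extract_window <- function(x, fs, center_idx, pre_s, post_s) {
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  idx <- (center_idx - npre):(center_idx + npost)
  inside <- idx >= 1L & idx <= length(x)
  out <- numeric(length(idx))
  out[inside] <- x[idx[inside]]
  list(samples = out, padded = !all(inside))
}

#' Extract an epoch around a time point
#'
#' @param rec A [recording()].
#' @param center_s Anchor time in seconds.
#' @param pre_s,post_s Window extent before/after the anchor in seconds.
#' @param ch Channel to extract (default 1).
#' @return An [epoch()] with `t0_offset_s = -pre_s`; zero-padded (and
#'   flagged) where the window extends past the recording.
#' @export
extract_epoch <- function(rec, center_s, pre_s = 10, post_s = 60, ch = 1L) {
  fs <- rec$sampling_rate
  w <- extract_window(channel(rec, ch), fs, round(center_s * fs) + 1L,
                      pre_s, post_s)
  epoch(w$samples, fs, t0_offset_s = -pre_s, padded = w$padded)
}

#' Align epochs on their extrema
#'
#' Re-windows each epoch so that its extremum (after any sign handling the
#' caller applied) sits at `pre_s`, making all outputs the same length
#' `round((pre_s + post_s) * fs) + 1` with the peak at index
#' `round(pre_s * fs) + 1`. Windows reaching past an epoch's data are
#' zero-padded and flagged.
#'
#' @param epochs List of [epoch()] objects with a common sampling rate.
#' @param pre_s,post_s Output window extent around the extremum (defaults
#'   10 and 60 s, covering the seconds-scale responses).
#' @return List of aligned epochs (empty list in, empty list out).
#' @export
peak_align <- function(epochs, pre_s = 10, post_s = 60) {
  stopifnot(pre_s > 0, post_s > 0)
  lapply(epochs, function(ep) {
    stopifnot(inherits(ep, "epoch"))
    pk <- which.max(abs(ep$samples))
    w <- extract_window(ep$samples, ep$sampling_rate, pk, pre_s, post_s)
    epoch(w$samples, ep$sampling_rate, t0_offset_s = -pre_s,
          normalized = ep$normalized, inverted = ep$inverted,
          padded = w$padded || ep$padded)
  })
}

#' Decimate a recording with anti-aliasing
#'
#' Low-passes at 0.45x the target rate and subsamples. Useful to speed up
#' detection on 10 kHz recordings whose information lives below ~10 Hz;
#' classification is insensitive to this when the band limit of the
#' amplifier is respected.
#'
#' @param rec A [recording()].
#' @param target_hz Target sampling rate in Hz.
#' @return A decimated [recording()] (unchanged if already at or below
#'   `target_hz`).
#' @export
decimate_recording <- function(rec, target_hz = 100) {
  if (rec$sampling_rate <= target_hz) return(rec)
  cols <- lapply(seq_len(rec$channel_count), function(ch) {
    decimate_signal(channel(rec, ch), rec$sampling_rate, target_hz)
  })
  out <- rec
  out$samples <- do.call(cbind, lapply(cols, `[[`, "x"))
  out$sampling_rate <- cols[[1]]$fs
  out
}

#' Export an epoch as a time/value data.frame
#'
#' @param ep An [epoch()].
#' @return data.frame with columns `time_s` (relative to the anchor) and
#'   `value`.
#' @export
epoch_to_df <- function(ep) {
  data.frame(
    time_s = ep$t0_offset_s + (seq_along(ep$samples) - 1) / ep$sampling_rate,
    value = ep$samples)
}
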