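# Trace-level artifact rejection: the three filters applied before any
# response is trusted -- (1) spikes faster than 500 ms (wire-touch
# artifacts), (2) clipping at the recording range, (3) spikes riding on an
# elevated baseline (normalization artifacts). Traces are accepted or
# rejected whole; nothing is repaired.

#' Artifact-rejection configuration
#'
#' @param fast_spike_max_width_s Excursions narrower than this (width at
#'   half prominence) are movement/touch artifacts; default 0.5 s.
#' @param spike_threshold_mads Excursion threshold as a multiple of the raw
#'   (unscaled) median absolute deviation of the detrended trace. Default
#'   10 raw MADs (about 6.7 Gaussian SDs): over a 120 s band-limited trace
#'   the expected number of threshold upcrossings from noise alone is then
#'   far below one, so clean traces do not fire.
#' @param clip_margin Samples within this fraction of normalized full scale
#'   (+/-1) count as saturated; default 0.01.
#' @param clip_min_run_s Minimum saturated run to call clipping; default
#'   0.05 s.
#' @param baseline_fraction A spike sitting on a rolling-median baseline
#'   whose magnitude exceeds this fraction of the trace's global extremum
#'   is a normalization artifact; default 0.75.
#' @param baseline_window_s Rolling-median window for the baseline
#'   estimate. Default 30 s: much longer than the seconds-scale responses
#'   (so genuine wound potentials do not register as elevated baseline)
#'   and much shorter than the record.
#' @param spike_min_amplitude Absolute excursion floor on the normalized
#'   full scale (default 0.05, i.e. 5% of the recording range). Movement
#'   and touch artifacts are large by nature; the floor keeps drift-scale
#'   wiggles in quiet traces from counting as spikes when the local noise
#'   estimate happens to be small.
#' @param analysis_rate_hz Spike detection runs on an anti-aliased
#'   decimated copy at this rate (default 100 Hz; 10 ms resolution, well
#'   under the 50 ms narrowest artifact of interest). Clipping is always
#'   checked at the native rate.
#' @return An object of class `artifact_config`.
#' @export
artifact_config <- function(fast_spike_max_width_s = 0.5,
                            spike_threshold_mads = 10,
                            clip_margin = 0.01,
                            clip_min_run_s = 0.05,
                            baseline_fraction = 0.75,
                            baseline_window_s = 30,
                            spike_min_amplitude = 0.05,
                            analysis_rate_hz = 100) {
  stopifnot(fast_spike_max_width_s > 0, spike_threshold_mads > 0,
            clip_margin > 0, clip_min_run_s > 0,
            baseline_fraction > 0, baseline_fraction <= 1,
            baseline_window_s > 0, spike_min_amplitude >= 0,
            analysis_rate_hz > 0)
  structure(as.list(environment()), class = "artifact_config")
}

# detrended-trace machinery shared by detect_spikes and reject_trace:
# decimate, rolling-median baseline, residual, MAD threshold, excursions.
# Decimation is by plain stride: the amplifier band limit (zero power
# above its upper corner) makes single-channel subsampling alias-free,
# and for wider-band two-channel data aliased broadband noise only feeds
# the (floored) threshold estimate, never a spike shape.
spike_analysis <- function(rec, cfg, events = NULL, ch = 1L) {
  x0 <- channel(rec, ch)
  by <- max(1L, floor(rec$sampling_rate / cfg$analysis_rate_hz))
  x <- x0[seq(1L, length(x0), by = by)]
  fs <- rec$sampling_rate / by
  k <- min(2L * floor(cfg$baseline_window_s * fs / 2) + 1L,
           2L * floor((length(x) - 1) / 2) + 1L)
  # trailing (causal) median: a centered rolling median follows a
  # persistent baseline step with zero lag (the step fills half the
  # window immediately), so steps would never leave a residual. The
  # trailing median lags by half a window, turning a step into a wide
  # excursion over an elevated baseline -- exactly what the filter is for.
  ctr <- stats::runmed(x, k, endrule = "constant")
  h <- (k - 1L) %/% 2L
  baseline <- ctr[pmax(1L, seq_along(x) - h)]
  resid <- x - baseline
  mad_win <- resid
  if (!is.null(events)) {
    ons <- stimulus_onsets(events)
    if (length(ons) && ons[1] * fs >= 10) {
      mad_win <- resid[seq_len(floor(ons[1] * fs))]
    }
  }
  thr <- max(cfg$spike_threshold_mads * stats::mad(mad_win, constant = 1),
             cfg$spike_min_amplitude)
  list(x = x, fs = fs, baseline = baseline, resid = resid, threshold = thr)
}

# excursions of |resid| above thr; width measured at half the excursion's
# prominence (on |resid|, expanding from the excursion's peak)
find_excursions <- function(resid, fs, thr) {
  if (thr <= 0) return(data.frame(time_s = numeric(), width_s = numeric(),
                                  amplitude = numeric()))
  above <- abs(resid) > thr
  if (!any(above)) return(data.frame(time_s = numeric(), width_s = numeric(),
                                     amplitude = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- lapply(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    seg <- abs(resid[i0:i1])
    pk <- i0 + which.max(seg) - 1L
    prom <- abs(resid[pk])
    half <- prom / 2
    lo <- pk
    while (lo > 1L && abs(resid[lo - 1L]) >= half) lo <- lo - 1L
    hi <- pk
    while (hi < length(resid) && abs(resid[hi + 1L]) >= half) hi <- hi + 1L
    data.frame(time_s = (pk - 1) / fs, width_s = (hi - lo + 1) / fs,
               amplitude = resid[pk])
  })
  do.call(rbind, out)
}

#' Detect spike excursions in a trace
#'
#' An excursion is a contiguous run where the magnitude of the detrended
#' signal (signal minus rolling-median baseline) exceeds
#' `spike_threshold_mads` raw MADs; its width is measured at half its
#' prominence and its time is the residual's peak. The MAD is estimated on
#' the pre-stimulus part when `events` is supplied, so genuine responses
#' do not inflate the noise estimate.
#'
#' @param rec A [recording()] (channel `ch` is analysed).
#' @param cfg An [artifact_config()].
#' @param events Optional [event_log()] restricting the MAD estimate to
#'   pre-stimulus data.
#' @param ch Channel index.
#' @return data.frame with columns `time_s`, `width_s`, `amplitude`,
#'   sorted by time (empty for a flat trace).
#' @export
detect_spikes <- function(rec, cfg = artifact_config(), events = NULL,
                          ch = 1L) {
  sa <- spike_analysis(rec, cfg, events, ch)
  ex <- find_excursions(sa$resid, sa$fs, sa$threshold)
  ex[order(ex$time_s), , drop = FALSE]
}

# saturated runs near +/- full scale at the native rate
clipping_runs <- function(x, fs, cfg) {
  sat <- abs(x) >= 1 - cfg$clip_margin
  if (!any(sat)) return(numeric(0))
  r <- rle(sat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= cfg$clip_min_run_s * fs
  (starts[keep] - 1) / fs
}

#' Apply the three artifact filters to a trace
#'
#' Rejection reasons: `fast_spike` when any detected excursion is narrower
#' than `fast_spike_max_width_s`; `clipping` when any run of at least
#' `clip_min_run_s` sits within `clip_margin` of full scale;
#' `elevated_baseline` when, near any detected excursion, the
#' rolling-median baseline magnitude exceeds `baseline_fraction` of the
#' trace's global extremum magnitude. A trace is accepted iff no reason
#' fires.
#'
#' @param rec A [recording()]; channel `ch` is analysed.
#' @param events [event_log()] (used for the pre-stimulus MAD window).
#' @param cfg An [artifact_config()].
#' @param ch Channel index.
#' @return An object of class `artifact_report`: list with `accepted`,
#'   `reasons` (character vector), and `details` (per-reason first event
#'   times in seconds).
#' @export
reject_trace <- function(rec, events, cfg = artifact_config(), ch = 1L) {
  sa <- spike_analysis(rec, cfg, events, ch)
  ex <- find_excursions(sa$resid, sa$fs, sa$threshold)
  reasons <- character(0)
  details <- list()

  fast <- ex$width_s < cfg$fast_spike_max_width_s
  if (any(fast)) {
    reasons <- c(reasons, "fast_spike")
    details$fast_spike <- ex$time_s[fast]
  }

  clips <- clipping_runs(channel(rec, ch), rec$sampling_rate, cfg)
  if (length(clips)) {
    reasons <- c(reasons, "clipping")
    details$clipping <- clips
  }

  if (nrow(ex)) {
    global_ext <- max(abs(sa$x))
    pad <- round(cfg$baseline_window_s * sa$fs)
    elevated <- vapply(ex$time_s, function(ts) {
      i <- round(ts * sa$fs) + 1L
      win <- max(1L, i - pad):min(length(sa$baseline), i + pad)
      max(abs(sa$baseline[win])) > cfg$baseline_fraction * global_ext
    }, logical(1))
    if (any(elevated)) {
      reasons <- c(reasons, "elevated_baseline")
      details$elevated_baseline <- ex$time_s[elevated]
    }
  }

  structure(list(accepted = length(reasons) == 0L, reasons = reasons,
                 details = details),
            class = "artifact_report")
}

#' @export
print.artifact_report <- function(x, ...) {
  if (x$accepted) cat("<artifact_report> accepted\n")
  else cat("<artifact_report> rejected:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Batch artifact report
#'
#' @param sims List of `list(recording, events)` (optionally with `id`).
#' @param cfg An [artifact_config()].
#' @return data.frame with one row per trace: `id`, `accepted`, `reasons`
#'   (semicolon-joined) and `first_event_s`.
#' @export
batch_reject <- function(sims, cfg = artifact_config()) {
  rows <- lapply(seq_along(sims), function(i) {
    s <- sims[[i]]
    rep <- reject_trace(s$recording, s$events, cfg)
    data.frame(
      id = if (!is.null(s$id)) s$id else sprintf("trace_%03d", i),
      accepted = rep$accepted,
      reasons = paste(rep$reasons, collapse = ";"),
      first_event_s = if (length(rep$details)) min(unlist(rep$details)) else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
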