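# Stimulus-locked response detection: a plant is considered responsive
# when, after the stimulus, the signal deviates more than 75% outside the
# signal range observed before the stimulus. Onset latency is the first
# criterion crossing; the detected response is cut into a normalized,
# peak-aligned epoch for species averaging.

#' Detection configuration
#'
#' @param deviation_fraction The criterion: responsive iff some
#'   post-stimulus sample exceeds the pre-stimulus range's edges by more
#'   than this fraction of the range width (strict inequality). Default
#'   0.75.
#' @param pre_window_s Pre-stimulus window over which the reference range
#'   is taken; default 30 s.
#' @param response_window_s Post-stimulus search window; default 60 s.
#' @param min_prestim_range Floor on the pre-stimulus range width, so a
#'   perfectly flat baseline cannot make quantization noise "responsive";
#'   default 4 quantization steps of 16-bit full scale.
#' @param epoch_pre_s,epoch_post_s Peak-aligned epoch extent; defaults 10
#'   and 60 s.
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(deviation_fraction = 0.75, pre_window_s = 30,
                             response_window_s = 60,
                             min_prestim_range = 4 / 32768,
                             epoch_pre_s = 10, epoch_post_s = 60) {
  stopifnot(deviation_fraction > 0, pre_window_s > 0, response_window_s > 0,
            min_prestim_range >= 0, epoch_pre_s > 0, epoch_post_s > 0)
  structure(as.list(environment()), class = "detection_config")
}

#' Pre-stimulus signal range
#'
#' Min/max of the signal over `[stimulus_on - pre_window_s, stimulus_on)`.
#' A degenerate (narrower than `min_prestim_range`) range is widened
#' symmetrically to the floor and flagged.
#'
#' @param rec A [recording()].
#' @param events An [event_log()] with a `stimulus_on` marker.
#' @param cfg A [detection_config()].
#' @param ch Channel index.
#' @param which_stim Index of the stimulus_on marker to anchor on.
#' @return List with `lo`, `hi`, `degenerate` flag.
#' @export
prestimulus_range <- function(rec, events, cfg = detection_config(), ch = 1L,
                              which_stim = 1L) {
  ons <- stimulus_onsets(events)
  if (length(ons) < which_stim) stop("no stimulus_on marker")
  stim <- ons[which_stim]
  fs <- rec$sampling_rate
  if (stim <= 0 || floor(stim * fs) < 1)
    stop("stimulus at recording start: no pre-stimulus data")
  i0 <- max(1L, floor((stim - cfg$pre_window_s) * fs) + 1L)
  i1 <- ceiling(stim * fs)
  x <- channel(rec, ch)[i0:i1]
  lo <- min(x); hi <- max(x)
  degenerate <- (hi - lo) < cfg$min_prestim_range
  if (degenerate) {
    mid <- (hi + lo) / 2
    lo <- mid - cfg$min_prestim_range / 2
    hi <- mid + cfg$min_prestim_range / 2
  }
  list(lo = lo, hi = hi, degenerate = degenerate)
}

#' Classify a stimulus-locked response
#'
#' Baseline-subtracts the trace, takes the pre-stimulus range
#' `R = hi - lo`, and declares the trial responsive iff any sample in
#' `(stimulus_on, stimulus_on + response_window_s]` lies strictly above
#' `hi + deviation_fraction * R` or strictly below
#' `lo - deviation_fraction * R`. Onset latency is the departure from the
#' pre-stimulus range, backtracked from the first criterion crossing (the
#' crossing proves the response; the departure point estimates when it
#' began); the peak is the extremum of the response window, from which a
#' sign-normalized peak-aligned epoch is cut.
#'
#' @param rec A [recording()] (artifact-accepted).
#' @param events [event_log()].
#' @param cfg [detection_config()].
#' @param ch Channel index.
#' @param which_stim Index of the stimulus_on marker (one result per
#'   stimulation; see [classify_trials()]).
#' @return An object of class `detection_result`: `responsive`,
#'   `onset_latency_s` (NA when non-responsive), `peak_time_s`,
#'   `peak_amplitude` (signed, baseline-subtracted), `prestim_range`
#'   (width), `degenerate_baseline`, and `epoch` (normalized, peak-aligned,
#'   NULL when non-responsive).
#' @export
classify_response <- function(rec, events, cfg = detection_config(), ch = 1L,
                              which_stim = 1L) {
  rec <- baseline_subtract(rec, events, cfg$pre_window_s)
  rng <- prestimulus_range(rec, events, cfg, ch, which_stim)
  stim <- stimulus_onsets(events)[which_stim]
  fs <- rec$sampling_rate
  x <- channel(rec, ch)
  R <- rng$hi - rng$lo
  i0 <- floor(stim * fs) + 2L  # first sample strictly after the stimulus
  i1 <- min(length(x), ceiling((stim + cfg$response_window_s) * fs))
  win <- x[i0:i1]
  over <- win > rng$hi + cfg$deviation_fraction * R |
          win < rng$lo - cfg$deviation_fraction * R
  responsive <- any(over)
  onset <- NA_real_; peak_time <- NA_real_; peak_amp <- NA_real_
  ep <- NULL
  if (responsive) {
    # onset: backtrack from the criterion crossing to the departure from
    # the pre-stimulus range itself. The crossing proves the response;
    # the departure point estimates when it began (the crossing time
    # alone would be biased late by the rise to the 75% excursion).
    cross <- which(over)[1]
    inside <- win[seq_len(cross)] <= rng$hi & win[seq_len(cross)] >= rng$lo
    dep <- if (any(inside)) max(which(inside)) + 1L else 1L
    onset <- (i0 + min(dep, cross) - 2L) / fs - stim
    pk <- which.max(abs(win))
    peak_time <- (i0 + pk - 2L) / fs
    peak_amp <- win[pk]
    ep <- extract_epoch(rec, peak_time, cfg$epoch_pre_s, cfg$epoch_post_s, ch)
    ep <- normalize_amplitude(sign_invert_if_negative(ep))
  }
  structure(list(responsive = responsive, onset_latency_s = onset,
                 peak_time_s = peak_time, peak_amplitude = peak_amp,
                 prestim_range = R, degenerate_baseline = rng$degenerate,
                 epoch = ep),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  if (x$responsive)
    cat(sprintf("<detection_result> responsive; latency %.2f s, peak %.2f s (amp %.3g)\n",
                x$onset_latency_s, x$peak_time_s, x$peak_amplitude))
  else cat("<detection_result> non-responsive\n")
  invisible(x)
}

#' Classify every stimulation of a recording
#'
#' One [classify_response()] result per `stimulus_on` marker; the
#' recording counts as responsive if any trial is.
#'
#' @inheritParams classify_response
#' @return List with `trials` (list of `detection_result`) and
#'   `responsive` (any trial responsive).
#' @export
classify_trials <- function(rec, events, cfg = detection_config(), ch = 1L) {
  n <- length(stimulus_onsets(events))
  if (n == 0L) stop("no stimulus_on marker")
  trials <- lapply(seq_len(n), function(k)
    classify_response(rec, events, cfg, ch, which_stim = k))
  list(trials = trials, responsive = any(vapply(trials, `[[`, TRUE, "responsive")))
}

#' Library configuration
#'
#' @param min_peaks Minimum number of peak-aligned epochs a species must
#'   contribute before a mean trace is computed (default 10).
#' @export
library_config <- function(min_peaks = 10) {
  stopifnot(min_peaks >= 1)
  structure(list(min_peaks = min_peaks), class = "library_config")
}

#' Build a species response-library entry
#'
#' Pools the normalized peak-aligned epochs of the responsive detection
#' results and computes the pointwise mean and standard deviation -- the
#' species' mean response with SD band. An entry is produced only when at
#' least `min_peaks` epochs are available; otherwise an explicit
#' `insufficient_peaks` outcome is returned.
#'
#' @param results List of [classify_response()] results for one species.
#' @param lib_cfg A [library_config()].
#' @param species Species label for the entry.
#' @return An object of class `species_library_entry` with `status` "ok"
#'   (fields `species`, `n_epochs`, `time_s`, `mean_trace`, `sd_trace`,
#'   `responsive_fraction`) or status `"insufficient_peaks"` (fields
#'   `species`, `n_epochs`, `responsive_fraction`).
#' @export
build_species_library <- function(results, lib_cfg = library_config(),
                                  species = NA_character_) {
  stopifnot(length(results) > 0)
  resp <- vapply(results, `[[`, TRUE, "responsive")
  eps <- lapply(results[resp], `[[`, "epoch")
  frac <- mean(resp)
  if (length(eps) < lib_cfg$min_peaks) {
    return(structure(list(status = "insufficient_peaks", species = species,
                          n_epochs = length(eps),
                          responsive_fraction = frac),
                     class = "species_library_entry"))
  }
  lens <- vapply(eps, function(e) length(e$samples), 1L)
  if (length(unique(lens)) != 1L) stop("epochs must have equal length")
  m <- do.call(cbind, lapply(eps, `[[`, "samples"))
  structure(list(status = "ok", species = species, n_epochs = ncol(m),
                 time_s = epoch_to_df(eps[[1]])$time_s,
                 mean_trace = rowMeans(m),
                 sd_trace = apply(m, 1, stats::sd),
                 responsive_fraction = frac),
            class = "species_library_entry")
}

#' @export
print.species_library_entry <- function(x, ...) {
  if (x$status == "ok")
    cat(sprintf("<species_library_entry> %s: mean of %d epochs (responsive fraction %.2f)\n",
                x$species, x$n_epochs, x$responsive_fraction))
  else
    cat(sprintf("<species_library_entry> %s: insufficient peaks (%d)\n",
                x$species, x$n_epochs))
  invisible(x)
}

#' Summarize a cohort's responsive fraction
#'
#' Percentage of species with at least one responsive accepted recording,
#' reported as exact fraction and nearest-integer percent.
#'
#' @param per_species data.frame with columns `species` and `responsive`
#'   (logical, one row per species), or a logical vector.
#' @return List with `n_species`, `n_responsive`, `fraction`,
#'   `pct_responsive` (exact) and `pct_responsive_rounded`.
#' @export
summarize_cohort <- function(per_species) {
  resp <- if (is.data.frame(per_species)) per_species$responsive else per_species
  if (length(resp) == 0L) stop("empty cohort")
  pct <- 100 * mean(resp)
  list(n_species = length(resp), n_responsive = sum(resp),
       fraction = mean(resp), pct_responsive = pct,
       pct_responsive_rounded = as.integer(round(pct)))
}
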