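#' Construct a recording object
#'
#' A recording bundles one or two channels of AC-coupled amplitude samples
#' (arbitrary units on a normalized full scale of +/-1) with the sampling
#' rate and minimal provenance metadata. This is the container every
#' analysis stage consumes.
#'
#' @param samples Numeric vector (single channel) or matrix with one column
#'   per channel. All channels must have equal length.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param species Species label, free text.
#' @param plant_id Identifier of the individual plant.
#' @param source File path the recording was read from, or `"synthetic"`.
#' @return An object of class `plant_recording` with elements `samples`
#'   (matrix, samples x channels), `sampling_rate`, `channel_count`,
#'   `species`, `plant_id`, `source`.
#' @examples
#' rec <- recording(sin(seq(0, 2 * pi, length.out = 100)), sampling_rate = 100)
#' duration_s(rec)
#' @export
recording <- function(samples, sampling_rate, species = NA_character_,
                      plant_id = NA_character_, source = "synthetic") {
  if (is.vector(samples)) samples <- matrix(as.numeric(samples), ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric vector or matrix")
  nch <- ncol(samples)
  if (nch < 1L || nch > 2L)
    stop("channel_count must be 1 or 2, got ", nch)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_count = nch, species = species, plant_id = plant_id,
         source = source),
    class = "plant_recording")
}

#' @export
print.plant_recording <- function(x, ...) {
  cat(sprintf("<plant_recording> %d channel(s), %.1f s @ %g Hz",
              x$channel_count, duration_s(x), x$sampling_rate))
  if (!is.na(x$species)) cat(sprintf(", species: %s", x$species))
  cat(sprintf("\n  source: %s\n", x$source))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A `plant_recording`.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) nrow(rec$samples) / rec$sampling_rate

#' Sample time axis of a recording
#' @param rec A `plant_recording`.
#' @return Numeric vector of sample times in seconds, starting at 0.
#' @export
time_axis <- function(rec) (seq_len(nrow(rec$samples)) - 1) / rec$sampling_rate

#' Divide a recording by the amplifier gain
#'
#' Informational only: AC coupling makes true millivolt values
#' unrecoverable, so the result remains in arbitrary units; dividing by
#' the nominal gain (72 single-channel, ~55 two-channel) merely rescales
#' toward the electrode-referred order of magnitude.
#'
#' @param rec A `plant_recording`.
#' @param gain Nominal amplifier gain.
#' @return The rescaled recording.
#' @export
deamplify <- function(rec, gain = 72) {
  stopifnot(gain > 0)
  rec$samples <- rec$samples / gain
  rec
}

# extract one channel as a plain numeric vector
channel <- function(rec, ch = 1L) {
  if (ch < 1L || ch > rec$channel_count) stop("no channel ", ch)
  rec$samples[, ch]
}

#' Construct an event log of stimulus markers
#'
#' Stimulus markers are the manually keyed "1" (stimulus applied) and "2"
#' (stimulus removed) annotations stored next to each recording. The log is
#' kept sorted by time and validated: every `stimulus_off` must follow a
#' `stimulus_on`.
#'
#' @param time_s Numeric vector of marker times in seconds from recording
#'   start.
#' @param kind Character vector, `"stimulus_on"` or `"stimulus_off"`,
#'   same length as `time_s`.
#' @return An object of class `event_log`: a data.frame with columns
#'   `time_s` and `kind`, sorted by time.
#' @export
event_log <- function(time_s = numeric(), kind = character()) {
  if (length(time_s) != length(kind)) stop("time_s and kind lengths differ")
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), c("stimulus_on", "stimulus_off"))
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "))
  ord <- order(time_s)
  df <- data.frame(time_s = as.numeric(time_s)[ord], kind = kind[ord],
                   stringsAsFactors = FALSE)
  # structural validity: an off marker needs a preceding unmatched on marker
  depth <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$kind[i] == "stimulus_on") depth <- depth + 1L
    else {
      depth <- depth - 1L
      if (depth < 0L)
        stop("stimulus_off at ", df$time_s[i], " s has no prior stimulus_on")
    }
  }
  class(df) <- c("event_log", "data.frame")
  df
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> %d marker(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Times of stimulus-onset markers
#' @param events An `event_log`.
#' @return Numeric vector of `stimulus_on` times in seconds.
#' @export
stimulus_onsets <- function(events) events$time_s[events$kind == "stimulus_on"]

# evaluate code with a temporary RNG seed, restoring global state afterwards.
# All generator randomness flows through this; no global state leaks.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# derive a child seed from a parent seed and an index, staying inside the
# 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(i)) %% 2147483647)
}
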