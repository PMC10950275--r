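# Event-marker text files: the stimulus annotations keyed during the
# experiment ("1" = stimulus applied, "2" = stimulus removed), stored next
# to each WAV. The on-disk dialect is not standardized, so two are
# supported behind a flag.

#' Read a stimulus event-marker file
#'
#' Parses a UTF-8 text file of stimulus markers. Marker `1` maps to
#' `stimulus_on`, `2` to `stimulus_off`; lines starting with `#` are
#' comments, blank lines are ignored, and the output is sorted by time.
#'
#' Dialects: `"marker_time"` lines look like `"1, 30.00"` (comma-separated
#' marker then seconds); `"time_marker"` lines look like `"30.00<TAB>1"`
#' (tab- or whitespace-separated seconds then marker).
#'
#' @param path Path to the marker text file.
#' @param dialect `"marker_time"` (default) or `"time_marker"`.
#' @return An [event_log()]. Empty files yield an empty log (downstream
#'   detection refuses logs without a `stimulus_on`).
#' @export
read_events <- function(path, dialect = c("marker_time", "time_marker")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  time_s <- numeric(0); marker <- character(0)
  for (i in which(keep)) {
    parts <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    if (length(parts) != 2L)
      stop("cannot parse event line ", i, " of ", path, ": '", lines[i], "'")
    if (dialect == "marker_time") { mk <- parts[1]; tm <- parts[2] }
    else { tm <- parts[1]; mk <- parts[2] }
    tnum <- suppressWarnings(as.numeric(tm))
    if (is.na(tnum) || !mk %in% c("1", "2"))
      stop("cannot parse event line ", i, " of ", path, ": '", lines[i], "'")
    time_s <- c(time_s, tnum); marker <- c(marker, mk)
  }
  event_log(time_s, ifelse(marker == "1", "stimulus_on", "stimulus_off"))
}

#' Write a stimulus event-marker file
#'
#' @param events An [event_log()].
#' @param path Output path.
#' @param dialect See [read_events()].
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("marker_time", "time_marker")) {
  dialect <- match.arg(dialect)
  mk <- ifelse(events$kind == "stimulus_on", "1", "2")
  if (dialect == "marker_time") {
    header <- "# marker, time_s"
    lines <- sprintf("%s, %.4f", mk, events$time_s)
  } else {
    header <- "# time_s\tmarker"
    lines <- sprintf("%.4f\t%s", events$time_s, mk)
  }
  writeLines(c(header, lines), path)
  invisible(path)
}
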