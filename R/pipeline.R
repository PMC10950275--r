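# Pipeline orchestration: config-driven simulate / analyze / velocity
# stages producing files on disk (WAV + marker text + CSV/JSON reports),
# with deterministic seeds so identical inputs give byte-identical
# outputs. A thin command-line front end over these functions ships at
# inst/cli/plantephys.R.

#' Pipeline configuration
#'
#' Bundles the stage configurations and the seed; round-trips through YAML
#' without loss.
#'
#' @param detection A [detection_config()].
#' @param artifacts An [artifact_config()].
#' @param library A [library_config()].
#' @param seed Integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection = detection_config(),
                            artifacts = artifact_config(),
                            library = library_config(), seed = 1L) {
  structure(list(schema_version = 1L, detection = detection,
                 artifacts = artifacts, library = library,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   reconstructed `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(lapply(unclass(cfg), function(x)
    if (is.list(x)) unclass(x) else x), path, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  pipeline_config(
    detection = do.call(detection_config, y$detection),
    artifacts = do.call(artifact_config, y$artifacts),
    library = do.call(library_config, y$library),
    seed = y$seed)
}

#' Simulate a cohort to disk
#'
#' Writes one WAV + event-marker text file per synthetic recording, a
#' ground-truth sidecar CSV (id, species, responsive, latency_s,
#' peak_time_s, polarity, delta_t_s), and a manifest listing every output.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_responsive,n_nonresponsive Cohort composition (default the
#'   9 responsive / 7 non-responsive species split).
#' @param seed Integer seed.
#' @return Invisibly, the manifest data.frame (columns id, wav, events).
#' @export
run_simulate <- function(out_dir, n_responsive = 9, n_nonresponsive = 7,
                         seed = 42) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); gt_rows <- list()
  if (n_responsive + n_nonresponsive > 0) {
    cohort <- generate_cohort(n_responsive, n_nonresponsive, seed)
    for (sim in cohort) {
      wav <- file.path(out_dir, paste0(sim$id, ".wav"))
      evt <- file.path(out_dir, paste0(sim$id, "_events.txt"))
      write_wav(sim$recording, wav)
      write_events(sim$events, evt)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sim$id, wav = basename(wav), events = basename(evt),
        stringsAsFactors = FALSE)
      gt <- sim$ground_truth
      gt_rows[[length(gt_rows) + 1L]] <- data.frame(
        id = sim$id, species = sim$recording$species,
        responsive = gt$responsive, latency_s = gt$latency_s,
        peak_time_s = gt$peak_time_s, polarity = gt$polarity,
        delta_t_s = gt$delta_t_s, stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), wav = character(), events = character())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- if (length(gt_rows)) do.call(rbind, gt_rows) else
    data.frame(id = character(), species = character(), responsive = logical(),
               latency_s = numeric(), peak_time_s = numeric(),
               polarity = numeric(), delta_t_s = numeric())
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

# find WAV + matching "<id>_events.txt" pairs in a directory; orphans are
# reported, not fatal
pair_files <- function(in_dir) {
  wavs <- list.files(in_dir, pattern = "\\.wav$", full.names = TRUE)
  ids <- sub("\\.wav$", "", basename(wavs))
  evts <- file.path(in_dir, paste0(ids, "_events.txt"))
  has_evt <- file.exists(evts)
  list(ids = ids[has_evt], wavs = wavs[has_evt], evts = evts[has_evt],
       orphans = ids[!has_evt])
}

#' Analyse a directory of recordings
#'
#' Runs artifact rejection then response classification on every paired
#' WAV/event file. Writes `detection.csv` (one row per recording:
#' accepted, responsive, latency, peak, range, reasons), per-species
#' library CSVs `library_<species>.csv` (time_s, mean, sd) for species
#' meeting the minimum-peaks rule, and `cohort_summary.json`. Orphan WAVs
#' and unreadable files are listed and skipped with a warning.
#'
#' @param in_dir Directory with `<id>.wav` + `<id>_events.txt` pairs.
#' @param out_dir Report directory (created if missing).
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the detection data.frame.
#' @export
run_analyze <- function(in_dir, out_dir, cfg = pipeline_config()) {
  if (!dir.exists(in_dir)) stop("input directory not found: ", in_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pf <- pair_files(in_dir)
  for (o in pf$orphans)
    warning("orphan WAV without event file, skipped: ", o)
  # species labels: WAV carries no metadata, so use the ground-truth
  # sidecar when present, else the file id (one recording per species in
  # simulated cohorts)
  species_of <- NULL
  gt_path <- file.path(in_dir, "ground_truth.csv")
  if (file.exists(gt_path)) {
    gt <- utils::read.csv(gt_path, stringsAsFactors = FALSE)
    if (all(c("id", "species") %in% names(gt)))
      species_of <- stats::setNames(gt$species, gt$id)
  }
  rows <- list(); failures <- list(); results_by_species <- list()
  for (i in seq_along(pf$ids)) {
    id <- pf$ids[i]
    out <- tryCatch({
      rec <- read_wav(pf$wavs[i])
      events <- read_events(pf$evts[i])
      rep <- reject_trace(rec, events, cfg$artifacts)
      if (rep$accepted) {
        res <- classify_response(rec, events, cfg$detection)
        sp <- if (!is.null(species_of) && id %in% names(species_of))
          unname(species_of[id]) else id
        results_by_species[[sp]] <- c(results_by_species[[sp]], list(res))
        data.frame(id = id, species = sp, accepted = TRUE,
                   reasons = "", responsive = res$responsive,
                   onset_latency_s = res$onset_latency_s,
                   peak_time_s = res$peak_time_s,
                   prestim_range = res$prestim_range,
                   degenerate_baseline = res$degenerate_baseline,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(id = id, species = NA_character_, accepted = FALSE,
                   reasons = paste(rep$reasons, collapse = ";"),
                   responsive = FALSE, onset_latency_s = NA_real_,
                   peak_time_s = NA_real_, prestim_range = NA_real_,
                   degenerate_baseline = NA, stringsAsFactors = FALSE)
      }
    }, error = function(e) e)
    if (inherits(out, "error")) {
      warning("failed to analyse ", id, ": ", conditionMessage(out))
      failures[[length(failures) + 1L]] <- data.frame(
        id = id, error = conditionMessage(out), stringsAsFactors = FALSE)
    } else rows[[length(rows) + 1L]] <- out
  }
  if (!length(rows)) stop("no analysable recordings in ", in_dir)
  det <- do.call(rbind, rows)
  utils::write.csv(det, file.path(out_dir, "detection.csv"), row.names = FALSE)
  if (length(failures))
    utils::write.csv(do.call(rbind, failures),
                     file.path(out_dir, "errors.csv"), row.names = FALSE)

  for (sp in names(results_by_species)) {
    entry <- build_species_library(results_by_species[[sp]], cfg$library,
                                   species = sp)
    if (entry$status == "ok")
      utils::write.csv(
        data.frame(time_s = entry$time_s, mean = entry$mean_trace,
                   sd = entry$sd_trace),
        file.path(out_dir, paste0("library_", sp, ".csv")), row.names = FALSE)
  }

  acc <- det[det$accepted, , drop = FALSE]
  per_species <- vapply(split(acc$responsive, acc$species), any, logical(1))
  summ <- summarize_cohort(unname(per_species))
  summ$n_recordings <- nrow(det)
  summ$n_accepted <- sum(det$accepted)
  summ$n_failed <- length(failures)
  jsonlite::write_json(summ, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(det)
}

#' Run a conduction-velocity study over a directory
#'
#' Reads every two-channel WAV/event pair, joins electrode separations
#' from a sidecar CSV (columns `id`, `separation_mm`), runs
#' [run_velocity_study()], and writes `velocity.csv` plus
#' `velocity_summary.json`.
#'
#' @param in_dir Directory of two-channel recordings.
#' @param separations Path to the separations CSV, or a data.frame.
#' @param out_dir Report directory.
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the `velocity_study`.
#' @export
run_velocity <- function(in_dir, separations, out_dir,
                         cfg = pipeline_config()) {
  if (is.character(separations)) {
    if (!file.exists(separations))
      stop("separations CSV not found: ", separations)
    separations <- utils::read.csv(separations, stringsAsFactors = FALSE)
  }
  if (!all(c("id", "separation_mm") %in% names(separations)))
    stop("separations table needs columns id, separation_mm")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pf <- pair_files(in_dir)
  pairs <- list()
  for (i in seq_along(pf$ids)) {
    id <- pf$ids[i]
    sep <- separations$separation_mm[separations$id == id]
    if (!length(sep)) { warning("no separation for ", id, ", skipped"); next }
    pairs[[length(pairs) + 1L]] <- list(
      recording = read_wav(pf$wavs[i]), events = read_events(pf$evts[i]),
      separation_mm = sep[1], id = id)
  }
  if (!length(pairs)) stop("no usable recording/separation pairs in ", in_dir)
  study <- run_velocity_study(pairs, cfg$detection, cfg$artifacts)
  utils::write.csv(study$estimates, file.path(out_dir, "velocity.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_recordings = study$n_recordings,
         mean_velocity_mm_s = study$mean_velocity_mm_s,
         sd_velocity_mm_s = study$sd_velocity_mm_s),
    file.path(out_dir, "velocity_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(study)
}
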