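# Species catalog: the cohort summary table of every plant experimented
# on -- common and Latin name, whether an electrical response was ever
# seen, and how many recordings/plants contributed. A copy of the study
# cohort table ships as the package fixture
# `system.file("extdata", "species_catalog.csv", package = "plantephys")`.

#' Load a species catalog CSV
#'
#' The catalog must have header columns `common_name`, `latin_name`,
#' `electrical_response` (Yes/No, case-insensitive), `n_recordings`,
#' `n_plants`.
#'
#' @param path Path to the catalog CSV. Defaults to the packaged cohort
#'   table.
#' @return A data.frame of class `species_catalog`, one row per species,
#'   with `electrical_response` parsed to logical.
#' @examples
#' cat16 <- load_catalog()
#' catalog_summary(cat16)
#' @export
load_catalog <- function(path = system.file("extdata", "species_catalog.csv",
                                            package = "plantephys")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("common_name", "latin_name", "electrical_response",
            "n_recordings", "n_plants")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("catalog is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df)) {
    resp <- tolower(trimws(df$electrical_response))
    if (!all(resp %in% c("yes", "no")))
      stop("electrical_response must be Yes or No")
    df$electrical_response <- resp == "yes"
    for (col in c("n_recordings", "n_plants")) {
      v <- df[[col]]
      if (!is.numeric(v) || any(v != round(v)) || any(v < 1))
        stop(col, " must contain positive integers")
      df[[col]] <- as.integer(v)
    }
  } else {
    df$electrical_response <- logical(0)
    df$n_recordings <- integer(0)
    df$n_plants <- integer(0)
  }
  class(df) <- c("species_catalog", "data.frame")
  df
}

#' Summarize a species catalog
#'
#' Column totals and the percentage of species that ever showed an
#' electrical response, reported both exactly and rounded to the nearest
#' integer percent.
#'
#' @param entries A catalog as returned by [load_catalog()].
#' @return A list with `n_species`, `n_recordings_total`, `n_plants_total`,
#'   `n_responsive`, `pct_responsive` (exact) and `pct_responsive_rounded`.
#' @export
catalog_summary <- function(entries) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop("catalog is empty")
  pct <- 100 * sum(entries$electrical_response) / nrow(entries)
  structure(list(
    n_species = nrow(entries),
    n_recordings_total = sum(entries$n_recordings),
    n_plants_total = sum(entries$n_plants),
    n_responsive = sum(entries$electrical_response),
    pct_responsive = pct,
    pct_responsive_rounded = as.integer(round(pct))
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<catalog_summary> %d species, %d recordings, %d plants\n",
    "  responsive species: %d/%d (%d%%)\n"),
    x$n_species, x$n_recordings_total, x$n_plants_total,
    x$n_responsive, x$n_species, x$pct_responsive_rounded))
  invisible(x)
}
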