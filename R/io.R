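# Tidy CSV dialects for the three tables the pipeline exchanges, plus a JSON
# results writer. All times are decimal minutes from imaging start, booleans
# are written as 0/1, decimal separator is ".", encoding UTF-8. Schema
# violations fail loudly and name the offending column or cell.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_invalid("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

as_flag <- function(x, name, allow_na = FALSE) {
  if (is.logical(x)) {
    out <- x
  } else if (is.numeric(x) && all(x %in% c(0, 1) | is.na(x))) {
    out <- x == 1
  } else {
    stop_invalid("column `%s` must be boolean (0/1)", name)
  }
  if (!allow_na && anyNA(out)) {
    stop_invalid("column `%s` must not contain missing values", name)
  }
  unname(out)
}

check_layer_vocab <- function(x, name) {
  bad <- setdiff(unique(as.character(x)), layer_levels())
  if (length(bad) > 0L) {
    stop_invalid("column `%s` contains values outside {%s}: %s", name,
                 paste(layer_levels(), collapse = ", "),
                 paste(bad, collapse = ", "))
  }
  as.character(x)
}

#' Validate and canonicalize a cell-track frame table
#'
#' Checks the tracks schema (`cell_id`, `germarium_id`, `layer`, `time_min`,
#' `gfp`, `rfp`, `mitotic`), the closed layer vocabulary, and strictly
#' increasing frame times within each cell. Extra columns are preserved.
#'
#' @param tracks A data frame of per-frame observations.
#' @return A tibble with canonical column types (character ids, logical
#'   reporter states).
#' @export
as_cell_tracks <- function(tracks) {
  require_columns(tracks, c("cell_id", "germarium_id", "layer", "time_min",
                            "gfp", "rfp", "mitotic"), "tracks table")
  tracks <- tibble::as_tibble(tracks)
  tracks$cell_id <- as.character(tracks$cell_id)
  tracks$germarium_id <- as.character(tracks$germarium_id)
  tracks$layer <- check_layer_vocab(tracks$layer, "layer")
  if (!is.numeric(tracks$time_min) || any(tracks$time_min < 0)) {
    stop_invalid("column `time_min` must be non-negative minutes")
  }
  tracks$time_min <- as.numeric(tracks$time_min)
  for (col in c("gfp", "rfp", "mitotic")) {
    tracks[[col]] <- as_flag(tracks[[col]], col)
  }
  bad <- tracks |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ok = all(diff(.data$time_min) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0L) {
    stop_invalid("frame times must be strictly increasing within a cell; violated by: %s",
                 paste(bad$cell_id, collapse = ", "))
  }
  tracks
}

#' Validate and canonicalize a fixed-snapshot cell table
#'
#' Checks the snapshot schema (`cell_id`, `germarium_id`, `location`, `gfp`,
#' `rfp`, `edu`, `dapi`, `genotype`). The EdU channel may be missing per cell
#' (the DAPI-only protocol), but every cell must then be DAPI-positive so it
#' remains countable.
#'
#' @param records A data frame of snapshot cell records.
#' @return A canonicalized tibble.
#' @export
as_snapshot_records <- function(records) {
  require_columns(records, c("cell_id", "germarium_id", "location", "gfp",
                             "rfp", "edu", "dapi", "genotype"),
                  "snapshot table")
  records <- tibble::as_tibble(records)
  records$cell_id <- as.character(records$cell_id)
  records$germarium_id <- as.character(records$germarium_id)
  records$location <- check_layer_vocab(records$location, "location")
  records$genotype <- as.character(records$genotype)
  records$gfp <- as_flag(records$gfp, "gfp")
  records$rfp <- as_flag(records$rfp, "rfp")
  records$edu <- as_flag(records$edu, "edu", allow_na = TRUE)
  records$dapi <- as_flag(records$dapi, "dapi")
  orphan <- is.na(records$edu) & !records$dapi
  if (any(orphan)) {
    stop_invalid("cells with missing EdU must be DAPI-positive; violated by: %s",
                 paste(records$cell_id[orphan], collapse = ", "))
  }
  records
}

as_intensity_records <- function(records) {
  require_columns(records, c("cell_id", "germarium_id", "layer", "intensity",
                             "chase_day"), "intensity table")
  records <- tibble::as_tibble(records)
  records$cell_id <- as.character(records$cell_id)
  records$germarium_id <- as.character(records$germarium_id)
  records$layer <- check_layer_vocab(records$layer, "layer")
  if (!is.numeric(records$intensity) || any(records$intensity <= 0)) {
    stop_invalid("column `intensity` must be > 0")
  }
  if (!is.numeric(records$chase_day) || any(records$chase_day < 0)) {
    stop_invalid("column `chase_day` must be >= 0")
  }
  records
}

flags_to_int <- function(df, cols) {
  for (col in intersect(cols, names(df))) {
    if (is.logical(df[[col]])) df[[col]] <- as.integer(df[[col]])
  }
  df
}

#' Read or write cell-track tables
#'
#' `tracks.csv` columns: `cell_id, germarium_id, layer, time_min, gfp, rfp,
#' mitotic` with booleans as 0/1. `read_tracks(write_tracks(x))` is the
#' identity on canonical tables.
#'
#' @param path CSV file path.
#' @return `read_tracks()` returns a validated tibble of frames.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  as_cell_tracks(readr::read_csv(path, show_col_types = FALSE,
                                 progress = FALSE))
}

#' @rdname read_tracks
#' @param tracks A frame table as produced by [simulate_imaging()] or
#'   [as_cell_tracks()].
#' @export
write_tracks <- function(tracks, path) {
  tracks <- as_cell_tracks(tracks)
  readr::write_csv(flags_to_int(tracks, c("gfp", "rfp", "mitotic")), path,
                   progress = FALSE)
  invisible(path)
}

#' Read or write fixed-snapshot tables
#'
#' `snapshot.csv` columns: `cell_id, germarium_id, location, gfp, rfp, edu,
#' dapi, genotype`; `edu` may be empty when only DAPI was used.
#'
#' @param path CSV file path.
#' @return `read_snapshot()` returns a validated tibble of records.
#' @export
read_snapshot <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  as_snapshot_records(readr::read_csv(path, show_col_types = FALSE,
                                      progress = FALSE))
}

#' @rdname read_snapshot
#' @param records A snapshot table as produced by [simulate_snapshot()].
#' @export
write_snapshot <- function(records, path) {
  records <- as_snapshot_records(records)
  readr::write_csv(flags_to_int(records, c("gfp", "rfp", "edu", "dapi")), path,
                   progress = FALSE, na = "")
  invisible(path)
}

#' Read or write per-cell intensity tables
#'
#' `intensities.csv` columns: `cell_id, germarium_id, layer, intensity,
#' chase_day`.
#'
#' @param path CSV file path.
#' @return `read_intensities()` returns a validated tibble.
#' @export
read_intensities <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  as_intensity_records(readr::read_csv(path, show_col_types = FALSE,
                                       progress = FALSE))
}

#' @rdname read_intensities
#' @param records An intensity table as produced by [simulate_dilution()].
#' @export
write_intensities <- function(records, path) {
  records <- as_intensity_records(records)
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Write an analysis results file with provenance
#'
#' Serializes results as nested JSON with the structure
#' `{inputs, parameters, estimates, statistics}`; `inputs` always records the
#' package version and any seed supplied, so a results file is traceable to
#' the run that produced it. Unrounded values should be stored here even when
#' rounded values are reported elsewhere.
#'
#' @param estimates Named list (or coercible object) of point estimates.
#' @param path Output JSON path.
#' @param inputs,parameters,statistics Named lists of provenance, settings and
#'   test statistics.
#' @param seed Seed used for any randomness in the run, if applicable.
#' @return The path, invisibly.
#' @export
write_results <- function(estimates, path, inputs = list(),
                          parameters = list(), statistics = list(),
                          seed = NULL) {
  inputs$package <- "germcycle"
  inputs$version <- as.character(utils::packageVersion("germcycle"))
  if (!is.null(seed)) inputs$seed <- seed
  payload <- list(inputs = inputs, parameters = parameters,
                  estimates = estimates, statistics = statistics)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}
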