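# H2B-RFP dilution analysis. A stable chromatin label halves at each
# division; comparing a cell's intensity to slow-cycling layer-3 cells of the
# same germarium (internal normalization) and to pre-chase baselines yields
# fold-dilution classifications and approximate division counts.

#' Normalize intensities to layer-3 cells of the same germarium
#'
#' Divides each cell's intensity by the mean intensity of layer-3 cells in
#' its own germarium, removing per-germarium staining and imaging variation.
#' By construction the layer-3 mean relative intensity is 1 per germarium,
#' and the operation is idempotent. Germaria without any layer-3 cell are
#' excluded with a warning.
#'
#' @param records Intensity records (columns `cell_id`, `germarium_id`,
#'   `layer`, `intensity`, `chase_day`).
#' @return The records with a `rel_intensity` column.
#' @export
normalize_to_layer3 <- function(records) {
  records <- as_intensity_records(records)
  ref <- records |>
    dplyr::filter(.data$layer == "3") |>
    dplyr::group_by(.data$germarium_id) |>
    dplyr::summarise(layer3_mean = mean(.data$intensity), .groups = "drop")
  missing <- setdiff(unique(records$germarium_id), ref$germarium_id)
  if (length(missing) > 0L) {
    warning(sprintf("excluding germarium/a without layer-3 cells: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    records <- records[!records$germarium_id %in% missing, , drop = FALSE]
  }
  records |>
    dplyr::left_join(ref, by = "germarium_id") |>
    dplyr::mutate(rel_intensity = .data$intensity / .data$layer3_mean) |>
    dplyr::select(-"layer3_mean")
}

#' Fraction of cells diluted beyond a fold threshold
#'
#' Counts, per layer (and chase day, when present), the cells whose relative
#' intensity has fallen below `baseline / fold`, where the baseline is the
#' pre-chase mean relative intensity of the cell's layer (initial labeling
#' differs by layer: about 0.69 for layer 1 and 0.91 for layer 2, relative to
#' layer 3). A single global baseline may be supplied instead. The fraction
#' is monotone non-increasing in `fold`.
#'
#' @param records Intensity records with a `rel_intensity` column (see
#'   [normalize_to_layer3()]).
#' @param baseline Named numeric vector of per-layer pre-chase mean relative
#'   intensities (e.g. `c("1" = 0.69, "2" = 0.91, "3" = 1)`), or a single
#'   unnamed number used globally.
#' @param fold Dilution fold threshold (> 1; default 4).
#' @return A tibble per group: `n_cells`, `n_below`, `fraction_below`.
#' @examples
#' rec <- tibble::tibble(
#'   cell_id = sprintf("c%d", 1:11), germarium_id = "g1", layer = "1",
#'   intensity = 1, chase_day = 7,
#'   rel_intensity = c(rep(0.10, 5), rep(0.40, 6))
#' )
#' fraction_below_threshold(rec, c("1" = 0.69))  # 5/11 = 45%
#' @export
fraction_below_threshold <- function(records, baseline, fold = 4) {
  require_columns(records, c("layer", "rel_intensity"), "intensity table")
  check_scalar_number(fold, "fold", 1, strict_min = TRUE)
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    stop_invalid("`baseline` must be positive")
  }
  if (is.null(names(baseline))) {
    if (length(baseline) != 1L) {
      stop_invalid("a global `baseline` must be a single number")
    }
    records$.baseline <- baseline
  } else {
    missing <- setdiff(unique(records$layer), names(baseline))
    if (length(missing) > 0L) {
      stop_invalid("`baseline` missing layer(s): %s",
                   paste(missing, collapse = ", "))
    }
    records$.baseline <- unname(baseline[records$layer])
  }
  group <- intersect(c("layer", "chase_day"), names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_below = sum(.data$rel_intensity < .data$.baseline / fold),
      fraction_below = .data$n_below / .data$n_cells,
      .groups = "drop"
    )
}

#' Approximate division count from label dilution
#'
#' With two-fold dilution per division, `log2(baseline / observed)` estimates
#' the number of divisions since labeling; negative values (observed brighter
#' than baseline) are clipped at 0. Estimates are approximate: initial
#' labeling is heterogeneous, which systematically limits quantitative
#' inference from dilution.
#'
#' @param baseline_intensity Pre-chase intensity (> 0), recycled.
#' @param observed_intensity Observed intensity (> 0).
#' @return Estimated divisions (vectorized).
#' @examples
#' divisions_from_dilution(1, 0.25)  # 2
#' @export
divisions_from_dilution <- function(baseline_intensity, observed_intensity) {
  if (!is.numeric(baseline_intensity) || any(baseline_intensity <= 0)) {
    stop_invalid("`baseline_intensity` must be > 0")
  }
  if (!is.numeric(observed_intensity) || any(observed_intensity <= 0)) {
    stop_invalid("`observed_intensity` must be > 0")
  }
  pmax(0, log2(baseline_intensity / observed_intensity))
}
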