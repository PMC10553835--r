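# Frame-label classification of FUCCI tracks into phase intervals.

# Allowed transitions of the cyclic phase order.
next_phase <- c(G1 = "S", S = "G2", G2 = "M", M = "G1")

label_frames <- function(gfp, rfp, mitotic) {
  out <- character(length(gfp))
  out[mitotic] <- "M"
  out[!mitotic & gfp & !rfp] <- "G1"
  out[!mitotic & gfp & rfp] <- "G2"
  out[!mitotic & !gfp] <- "S"   # RFP-only (late S) or colorless (early S)
  out
}

#' Classify one FUCCI track into phase-labeled intervals
#'
#' Labels each frame from its reporter state (GFP-only = G1; GFP+RFP = G2, or
#' M when the mitotic flag is set; RFP-only or colorless = S) and merges
#' consecutive frames into intervals. A transition between phases is placed at
#' the midpoint between the last frame of the old phase and the first frame of
#' the new phase, which is unbiased when the true transition time is uniform
#' within the frame gap. The first and last observed frames bound censored
#' intervals: an interval whose start (end) coincides with the track boundary
#' has `entry_observed` (`exit_observed`) `FALSE`.
#'
#' A label sequence that violates the cyclic order G1 -> S -> G2 -> M -> G1
#' (for example G2 followed by G1 with no mitotic frame) marks the track
#' ambiguous; ambiguous tracks are excluded from dwell summaries with a logged
#' reason. A track starting colorless is assigned to S (the dominant case) but
#' flagged via the `starts_colorless` attribute.
#'
#' @param track Frames of a single cell (columns `time_min`, `gfp`, `rfp`,
#'   `mitotic`; extra columns ignored).
#' @return A tibble of intervals (`phase`, `start_min`, `end_min`,
#'   `duration_min`, `entry_observed`, `exit_observed`) with attributes
#'   `cell_id`, `ambiguous`, `ambiguous_reason` and `starts_colorless`.
#' @examples
#' tr <- tibble::tibble(
#'   cell_id = "c1", germarium_id = "g1", layer = "1",
#'   time_min = c(0, 20, 40), gfp = c(TRUE, TRUE, FALSE),
#'   rfp = FALSE, mitotic = FALSE
#' )
#' classify_track(tr)  # G1 interval, observed exit to S at t = 30
#' @export
classify_track <- function(track) {
  if (nrow(track) < 1L) stop_invalid("track must contain at least one frame")
  if (is.unsorted(track$time_min, strictly = TRUE)) {
    stop_invalid("track frame times must be strictly increasing")
  }
  labels <- label_frames(track$gfp, track$rfp, track$mitotic)
  runs <- rle(labels)
  k <- length(runs$lengths)
  last_idx <- cumsum(runs$lengths)
  first_idx <- last_idx - runs$lengths + 1L
  t_first <- track$time_min[first_idx]
  t_last <- track$time_min[last_idx]

  start <- c(t_first[1], (t_last[-k] + t_first[-1]) / 2)
  end <- c((t_last[-k] + t_first[-1]) / 2, t_last[k])

  ambiguous <- FALSE
  reason <- NA_character_
  if (k > 1L) {
    bad <- which(next_phase[runs$values[-k]] != runs$values[-1])
    if (length(bad) > 0L) {
      ambiguous <- TRUE
      reason <- sprintf("non-cyclic transition %s -> %s",
                        runs$values[bad[1]], runs$values[bad[1] + 1L])
    }
  }

  out <- tibble::tibble(
    phase = runs$values,
    start_min = start,
    end_min = end,
    duration_min = end - start,
    entry_observed = c(FALSE, rep(TRUE, k - 1L)),
    exit_observed = c(rep(TRUE, k - 1L), FALSE)
  )
  attr(out, "cell_id") <- if ("cell_id" %in% names(track)) {
    track$cell_id[1]
  } else {
    NA_character_
  }
  attr(out, "ambiguous") <- ambiguous
  attr(out, "ambiguous_reason") <- reason
  attr(out, "starts_colorless") <-
    !track$gfp[1] && !track$rfp[1] && !track$mitotic[1]
  out
}

# Classify every cell in a frame table (vectorized across cells; equivalent
# to applying classify_track per cell — covered by a test). Returns
# list(intervals = tibble with cell_id/germarium_id columns,
#      ambiguous = tibble of excluded tracks with reasons).
classify_all <- function(tracks) {
  tracks <- as_cell_tracks(tracks)
  tracks <- tracks[order(tracks$cell_id, tracks$time_min), , drop = FALSE]
  n <- nrow(tracks)
  lab <- label_frames(tracks$gfp, tracks$rfp, tracks$mitotic)
  cell <- tracks$cell_id
  new_cell <- c(TRUE, cell[-1] != cell[-n])
  new_run <- new_cell | c(TRUE, lab[-1] != lab[-n])
  first <- which(new_run)
  last <- c(first[-1] - 1L, n)
  m <- length(first)

  t_first <- tracks$time_min[first]
  t_last <- tracks$time_min[last]
  first_in_cell <- new_cell[first]
  last_in_cell <- c(first_in_cell[-1], TRUE)
  phase <- lab[first]

  prev_last <- c(NA_real_, t_last[-m])
  next_first <- c(t_first[-1], NA_real_)
  start <- ifelse(first_in_cell, t_first, (prev_last + t_first) / 2)
  end <- ifelse(last_in_cell, t_last, (t_last + next_first) / 2)

  runs <- tibble::tibble(
    phase = phase,
    start_min = start,
    end_min = end,
    duration_min = end - start,
    entry_observed = !first_in_cell,
    exit_observed = !last_in_cell,
    cell_id = cell[first],
    germarium_id = tracks$germarium_id[first],
    layer = tracks$layer[first]
  )

  prev_phase <- c(NA_character_, phase[-m])
  viol <- !first_in_cell & next_phase[prev_phase] != phase
  viol[is.na(viol)] <- FALSE
  ambiguous <- tibble::tibble(cell_id = character(0),
                              germarium_id = character(0),
                              reason = character(0))
  if (any(viol)) {
    first_viol <- runs[viol, , drop = FALSE] |>
      dplyr::mutate(reason = sprintf("non-cyclic transition %s -> %s",
                                     prev_phase[viol], .data$phase)) |>
      dplyr::distinct(.data$cell_id, .keep_all = TRUE)
    ambiguous <- first_viol[, c("cell_id", "germarium_id", "reason")]
    runs <- runs[!runs$cell_id %in% ambiguous$cell_id, , drop = FALSE]
  }
  list(intervals = runs, ambiguous = ambiguous)
}
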