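# The dwell-time/exit estimator for phase durations from partially observed
# tracks. Each tracked cell is captured at an arbitrary time within its
# current phase, so observed dwell intervals are a mixture of censored
# residuals, complete passages and censored entries; summing all observed
# minutes in a phase and dividing by the number of observed transitions out
# of that phase gives a consistent estimate of the mean phase duration
# (an occupancy / exit-rate identity for the stationary renewal population).

#' Pooled dwell summary for one phase
#'
#' The estimator's sufficient statistic: total minutes observed in a phase
#' across all cells, and the number of observed transitions out of that
#' phase. Use this constructor directly to enter published totals (e.g.
#' 8432 min of G2 with 16 exits across 92 tracked cells), or derive one from
#' tracks with [summarize_tracks()].
#'
#' @param phase One of `"G1"`, `"G2"`, `"M"` (S-phase is inferred from
#'   snapshot fractions instead, via [infer_s_duration()]).
#' @param total_observed_min Summed observed dwell minutes.
#' @param exits Count of observed transitions out of the phase.
#' @param cells_tracked Number of cells contributing observations.
#' @return An object of class `phase_dwell_summary`.
#' @export
phase_dwell_summary <- function(phase, total_observed_min, exits,
                                cells_tracked = NA_integer_) {
  phase <- match.arg(phase, c("G1", "G2", "M"))
  check_scalar_number(total_observed_min, "total_observed_min", 0)
  check_scalar_number(exits, "exits", 0)
  structure(
    list(phase = phase, total_observed_min = total_observed_min,
         exits = as.integer(exits), cells_tracked = cells_tracked),
    class = "phase_dwell_summary"
  )
}

#' @export
print.phase_dwell_summary <- function(x, ...) {
  cat(sprintf("<phase_dwell_summary> %s: %.6g min observed, %d exit(s), %s cell(s)\n",
              x$phase, x$total_observed_min, x$exits,
              ifelse(is.na(x$cells_tracked), "?", x$cells_tracked)))
  invisible(x)
}

# Aggregate a classified interval table into a dwell summary.
summarize_intervals <- function(intervals, phase, include_entering = TRUE) {
  iv <- intervals[intervals$phase == phase, , drop = FALSE]
  if (!include_entering) {
    iv <- iv[!iv$entry_observed, , drop = FALSE]
  }
  phase_dwell_summary(
    phase = phase,
    total_observed_min = sum(iv$duration_min),
    exits = sum(iv$exit_observed),
    cells_tracked = length(unique(iv$cell_id))
  )
}

#' Summarize observed dwell time and exits for one phase
#'
#' Accumulates dwell time for every interval during which a cell is observed
#' in the phase — including cells already in the phase at the window start and
#' cells entering during the window — and counts each observed transition out
#' of the phase once. Censored intervals (dropout or window end) contribute
#' time but no exit. Both kinds of interval are essential: omitting cells that
#' enter the phase during the window biases the duration estimate low, because
#' their (mostly censored) dwell time is discarded while the early exits of
#' cells caught near the end of their phase are kept.
#'
#' Tracks whose label sequence violates the cyclic phase order are excluded
#' with a message, as are (by default) germaria in which no G1 or G2 exits
#' were observed at all — mirroring the exclusion of inert, apparently
#' unhealthy germaria in live-imaging practice. Note this filter selects for
#' active germaria.
#'
#' @param tracks A frame table ([as_cell_tracks()] schema).
#' @param phase `"G1"`, `"G2"` or `"M"`.
#' @param include_entering Keep intervals whose entry into the phase was
#'   observed during the window (default `TRUE`; `FALSE` exists to demonstrate
#'   the selection bias).
#' @param drop_inert_germaria Drop germaria with zero observed G1 and G2
#'   exits (default `TRUE`).
#' @param quiet Suppress exclusion messages.
#' @return A [phase_dwell_summary()].
#' @export
summarize_tracks <- function(tracks, phase = c("G1", "G2", "M"),
                             include_entering = TRUE,
                             drop_inert_germaria = TRUE,
                             quiet = FALSE) {
  phase <- match.arg(phase)
  if (is.null(tracks) || nrow(tracks) == 0L) {
    stop_invalid("no tracks supplied")
  }
  cls <- classify_all(tracks)
  if (!quiet && nrow(cls$ambiguous) > 0L) {
    message(sprintf("excluded %d ambiguous track(s): %s",
                    nrow(cls$ambiguous),
                    paste(unique(cls$ambiguous$reason), collapse = "; ")))
  }
  intervals <- cls$intervals
  if (nrow(intervals) == 0L) stop_invalid("no classifiable tracks")
  if (drop_inert_germaria) {
    intervals <- drop_inert(intervals, quiet = quiet)
  }
  summarize_intervals(intervals, phase, include_entering)
}

drop_inert <- function(intervals, quiet = FALSE) {
  act <- intervals |>
    dplyr::group_by(.data$germarium_id) |>
    dplyr::summarise(
      exits = sum(.data$exit_observed & .data$phase %in% c("G1", "G2")),
      .groups = "drop"
    )
  inert <- act$germarium_id[act$exits == 0L]
  if (length(inert) > 0L && !quiet) {
    message(sprintf("excluded %d inert germarium/a (no G1 or G2 exits): %s",
                    length(inert), paste(inert, collapse = ", ")))
  }
  intervals[!intervals$germarium_id %in% inert, , drop = FALSE]
}

#' Estimate a mean phase duration from a dwell summary
#'
#' The point estimate is total observed minutes divided by observed exits.
#' A summary with zero exits carries no duration information and raises an
#' error (the same reason inert germaria are excluded upstream).
#'
#' @param summary A [phase_dwell_summary()].
#' @return An object of class `phase_duration_estimate` with the unrounded
#'   `minutes`, the reporting value `minutes_rounded` (nearest minute), and
#'   the inputs.
#' @examples
#' g2 <- estimate_phase_duration(phase_dwell_summary("G2", 8432, 16, 92))
#' g2$minutes_rounded  # 527
#' @export
estimate_phase_duration <- function(summary) {
  if (!inherits(summary, "phase_dwell_summary")) {
    stop_invalid("`summary` must be a `phase_dwell_summary`")
  }
  if (summary$exits < 1L) {
    stop_invalid("no transitions out of %s observed; duration is not estimable",
                 summary$phase)
  }
  minutes <- summary$total_observed_min / summary$exits
  structure(
    list(phase = summary$phase, minutes = minutes,
         minutes_rounded = round(minutes),
         total_observed_min = summary$total_observed_min,
         exits = summary$exits, cells_tracked = summary$cells_tracked),
    class = "phase_duration_estimate"
  )
}

#' @export
print.phase_duration_estimate <- function(x, ...) {
  cat(sprintf("<phase_duration_estimate> %s = %d min (%.6g/%d = %.2f min, %s cells)\n",
              x$phase, x$minutes_rounded, x$total_observed_min, x$exits,
              x$minutes, ifelse(is.na(x$cells_tracked), "?", x$cells_tracked)))
  invisible(x)
}

#' Infer S-phase duration from the snapshot S fraction
#'
#' S-phase entries and exits are rarely observed directly because most
#' S-phase cells are colorless, so S is inferred from the fraction of cells
#' in S-phase in fixed samples: if a fraction `fS` of the cycle is spent in
#' S, then `S = (G1 + G2 + M) * fS / (1 - fS)`.
#'
#' @param g1_min,g2_min,m_min Estimated durations of the other phases,
#'   minutes.
#' @param s_fraction Snapshot S-phase fraction `fS` in `[0, 1)`, pooled
#'   across germaria weighted by cell counts.
#' @return S-phase duration in minutes (monotone increasing in `fS`; 0 at
#'   `fS = 0`).
#' @examples
#' infer_s_duration(81, 527, 17, 0.337)  # ~318
#' @export
infer_s_duration <- function(g1_min, g2_min, m_min, s_fraction) {
  check_scalar_number(g1_min, "g1_min", 0)
  check_scalar_number(g2_min, "g2_min", 0)
  check_scalar_number(m_min, "m_min", 0)
  if (!is.numeric(s_fraction) || length(s_fraction) != 1L ||
      is.na(s_fraction) || s_fraction < 0 || s_fraction >= 1) {
    stop_invalid("`s_fraction` must be in [0, 1)")
  }
  (g1_min + g2_min + m_min) * s_fraction / (1 - s_fraction)
}

#' Per-class cell-cycle estimate
#'
#' Container for the four phase durations of one cell class (e.g. layer-1
#' follicle stem cells of one genotype) and their total.
#'
#' @param g1_min,s_min,g2_min,m_min Phase durations, minutes.
#' @param s_fraction_used Snapshot S fraction used to infer S, if any.
#' @param n_cells Number of tracked cells behind the estimate.
#' @return An object of class `cell_cycle_estimate` with `total_min`.
#' @export
cell_cycle_estimate <- function(g1_min, s_min, g2_min, m_min,
                                s_fraction_used = NA_real_,
                                n_cells = NA_integer_) {
  for (nm in c("g1_min", "s_min", "g2_min", "m_min")) {
    check_scalar_number(get(nm), nm, 0)
  }
  structure(
    list(g1_min = g1_min, s_min = s_min, g2_min = g2_min, m_min = m_min,
         total_min = g1_min + s_min + g2_min + m_min,
         s_fraction_used = s_fraction_used, n_cells = n_cells),
    class = "cell_cycle_estimate"
  )
}

#' @export
print.cell_cycle_estimate <- function(x, ...) {
  cat(sprintf(
    "<cell_cycle_estimate> G1 %d  S %d  G2 %d  M %d min; total %d min",
    round(x$g1_min), round(x$s_min), round(x$g2_min), round(x$m_min),
    round(x$total_min)
  ))
  if (!is.na(x$s_fraction_used)) {
    cat(sprintf(" (fS = %.3f)", x$s_fraction_used))
  }
  cat("\n")
  invisible(x)
}

#' Estimate a full cell cycle from tracks plus a snapshot S fraction
#'
#' Convenience wrapper: derives G1, G2 and M durations from the tracks via
#' [summarize_tracks()] and [estimate_phase_duration()], infers S from the
#' supplied snapshot S fraction, and returns a [cell_cycle_estimate()]
#' (unrounded values; rounding is applied only at reporting).
#'
#' @inheritParams summarize_tracks
#' @param s_fraction Snapshot S fraction in `[0, 1)`; alternatively a
#'   snapshot record table, from which the pooled fraction is computed with
#'   [s_fraction_from_snapshot()].
#' @param layer Optional layer to restrict the tracks to.
#' @return A [cell_cycle_estimate()].
#' @export
estimate_cell_cycle <- function(tracks, s_fraction, layer = NULL,
                                include_entering = TRUE,
                                drop_inert_germaria = TRUE, quiet = FALSE) {
  tracks <- as_cell_tracks(tracks)
  if (!is.null(layer)) {
    tracks <- tracks[tracks$layer == as.character(layer), , drop = FALSE]
  }
  if (is.data.frame(s_fraction)) {
    s_fraction <- s_fraction_from_snapshot(s_fraction, location = layer)
  }
  ests <- lapply(c("G1", "G2", "M"), function(p) {
    estimate_phase_duration(
      summarize_tracks(tracks, p, include_entering = include_entering,
                       drop_inert_germaria = drop_inert_germaria,
                       quiet = quiet)
    )
  })
  names(ests) <- c("G1", "G2", "M")
  s_min <- infer_s_duration(ests$G1$minutes, ests$G2$minutes, ests$M$minutes,
                            s_fraction)
  cell_cycle_estimate(
    g1_min = ests$G1$minutes, s_min = s_min, g2_min = ests$G2$minutes,
    m_min = ests$M$minutes, s_fraction_used = s_fraction,
    n_cells = length(unique(tracks$cell_id))
  )
}

#' Pooled snapshot S fraction
#'
#' Fraction of snapshot cells classified as S-phase, pooled across germaria
#' (each cell counts once, so germaria are weighted by their cell counts).
#'
#' @param records Snapshot records ([as_snapshot_records()] schema).
#' @param location,genotype Optional filters.
#' @return A proportion in `[0, 1]`.
#' @export
s_fraction_from_snapshot <- function(records, location = NULL,
                                     genotype = NULL) {
  records <- as_snapshot_records(records)
  if (!is.null(location)) {
    records <- records[records$location == as.character(location), ,
                       drop = FALSE]
  }
  if (!is.null(genotype)) {
    records <- records[records$genotype == genotype, , drop = FALSE]
  }
  if (nrow(records) == 0L) stop_invalid("no snapshot records after filtering")
  mean(classify_phase(records) == "S")
}

#' Ratio of two total cycle times
#'
#' @param est_a,est_b [cell_cycle_estimate()] objects or plain total cycle
#'   times in minutes.
#' @return The unrounded ratio `total_a / total_b`; report to one decimal.
#' @examples
#' round(cycle_ratio(3223, 943), 1)  # 3.4
#' @export
cycle_ratio <- function(est_a, est_b) {
  total_of <- function(x, name) {
    if (inherits(x, "cell_cycle_estimate")) x <- x$total_min
    check_scalar_number(x, name, 0, strict_min = TRUE)
    x
  }
  total_of(est_a, "est_a") / total_of(est_b, "est_b")
}

#' Bootstrap confidence interval for a phase duration
#'
#' Germaria are the independent sampling units, so the interval resamples
#' whole germaria with replacement, re-runs the dwell/exit estimator on each
#' resample, and reports percentile bounds. Resamples in which no exits from
#' the phase were observed are counted and skipped.
#'
#' @inheritParams summarize_tracks
#' @param n_reps Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95 for 2.5/97.5 percentiles).
#' @return A list with `point`, `lower`, `upper`, `conf`, `n_reps`,
#'   `n_failed` and the vector of resample `estimates`.
#' @export
bootstrap_ci <- function(tracks, phase = c("G1", "G2", "M"), n_reps = 1000,
                         seed = 1L, conf = 0.95, include_entering = TRUE,
                         drop_inert_germaria = TRUE) {
  phase <- match.arg(phase)
  check_scalar_number(n_reps, "n_reps", 1)
  cls <- classify_all(tracks)
  intervals <- cls$intervals
  if (nrow(intervals) == 0L) stop_invalid("no classifiable tracks")
  if (drop_inert_germaria) intervals <- drop_inert(intervals, quiet = TRUE)
  germs <- unique(intervals$germarium_id)
  if (length(germs) < 2L) {
    stop_invalid("bootstrap requires >= 2 germaria (have %d)", length(germs))
  }
  point <- estimate_phase_duration(
    summarize_intervals(intervals, phase, include_entering)
  )$minutes

  by_germ <- split(intervals, intervals$germarium_id)
  set.seed(as.integer(seed))
  estimates <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    pick <- sample(germs, length(germs), replace = TRUE)
    iv <- dplyr::bind_rows(by_germ[pick])
    s <- summarize_intervals(iv, phase, include_entering)
    if (s$exits >= 1L) estimates[r] <- s$total_observed_min / s$exits
  }
  ok <- estimates[!is.na(estimates)]
  if (length(ok) == 0L) stop_invalid("all bootstrap resamples had zero exits")
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
  list(point = point, lower = qs[1], upper = qs[2], conf = conf,
       n_reps = n_reps, n_failed = sum(is.na(estimates)), estimates = estimates)
}
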