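#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
NULL

# Cyclic phase order: G1 -> S -> G2 -> M -> (division, back to G1).
phase_order <- function() c("G1", "S", "G2", "M")

# Closed anatomical vocabulary: FSC layers 1-3 and the two escort-cell regions.
layer_levels <- function() c("1", "2", "3", "r2a", "r1")

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (strict_min && x <= min) stop_invalid("`%s` must be > %s", name, min)
  if (!strict_min && x < min) stop_invalid("`%s` must be >= %s", name, min)
  invisible(x)
}

#' Cell-cycle phase durations
#'
#' Bundle the mean durations of the four cell-cycle phases, in minutes,
#' optionally with a coefficient of variation for per-cell gamma-distributed
#' variability around those means. The control layer-1 follicle stem cell
#' values are G1 = 81, S = 318, G2 = 527, M = 17 minutes (total 943).
#'
#' @param g1_min,s_min,g2_min,m_min Positive mean phase durations in minutes.
#' @param cv Coefficient of variation for per-cell phase-duration draws;
#'   `0` (the default) makes every cell's durations exactly the means.
#'
#' @return An object of class `phase_durations`: a list with the four
#'   durations, `cv`, and `total_min`.
#' @examples
#' wt <- phase_durations(81, 318, 527, 17)
#' wt$total_min
#' @export
phase_durations <- function(g1_min, s_min, g2_min, m_min, cv = 0) {
  check_scalar_number(g1_min, "g1_min", 0, strict_min = TRUE)
  check_scalar_number(s_min, "s_min", 0, strict_min = TRUE)
  check_scalar_number(g2_min, "g2_min", 0, strict_min = TRUE)
  check_scalar_number(m_min, "m_min", 0, strict_min = TRUE)
  check_scalar_number(cv, "cv", 0)
  structure(
    list(
      g1_min = g1_min, s_min = s_min, g2_min = g2_min, m_min = m_min,
      cv = cv, total_min = g1_min + s_min + g2_min + m_min
    ),
    class = "phase_durations"
  )
}

#' @export
print.phase_durations <- function(x, ...) {
  cat(sprintf(
    "<phase_durations> G1 %.4g  S %.4g  G2 %.4g  M %.4g min (total %.4g, cv %.3g)\n",
    x$g1_min, x$s_min, x$g2_min, x$m_min, x$total_min, x$cv
  ))
  invisible(x)
}

duration_vector <- function(durations) {
  c(G1 = durations$g1_min, S = durations$s_min,
    G2 = durations$g2_min, M = durations$m_min)
}

#' FUCCI reporter and EdU pulse configuration
#'
#' Detection lags of the FUCCI reporter pair and the length of the EdU
#' incorporation pulse applied before fixation. The RFP reporter takes an
#' appreciable time to accumulate to detectable levels after S entry
#' (observed average 114 minutes), so early S-phase cells are colorless;
#' GFP accumulates quickly at the end of S-phase, so the default GFP lag
#' is zero.
#'
#' @param rfp_onset_lag_min Minutes after S entry before RFP is detectable.
#' @param gfp_onset_lag_min Minutes after S exit before GFP is detectable.
#' @param edu_pulse_min Length of the EdU pulse immediately before fixation,
#'   minutes (default one hour).
#'
#' @return An object of class `reporter_config`.
#' @export
reporter_config <- function(rfp_onset_lag_min = 114, gfp_onset_lag_min = 0,
                            edu_pulse_min = 60) {
  check_scalar_number(rfp_onset_lag_min, "rfp_onset_lag_min", 0)
  check_scalar_number(gfp_onset_lag_min, "gfp_onset_lag_min", 0)
  check_scalar_number(edu_pulse_min, "edu_pulse_min", 0, strict_min = TRUE)
  structure(
    list(
      rfp_onset_lag_min = rfp_onset_lag_min,
      gfp_onset_lag_min = gfp_onset_lag_min,
      edu_pulse_min = edu_pulse_min
    ),
    class = "reporter_config"
  )
}

#' Live-imaging window configuration
#'
#' Imaging windows in the source protocol are deliberately short (average
#' 148 minutes) with a frame collected roughly every 20 minutes; some cells
#' leave the imaged z-range permanently during the window.
#'
#' @param window_min Total imaging duration, minutes.
#' @param frame_interval_min Sampling interval between frames, minutes.
#' @param dropout_prob Per-frame probability that a tracked cell permanently
#'   leaves the observed z-range (right-censoring; no re-entry).
#' @param seed Integer seed for the imaging-simulation RNG.
#'
#' @return An object of class `imaging_config`.
#' @export
imaging_config <- function(window_min = 150, frame_interval_min = 20,
                           dropout_prob = 0, seed = 1L) {
  check_scalar_number(window_min, "window_min", 0, strict_min = TRUE)
  check_scalar_number(frame_interval_min, "frame_interval_min", 0, strict_min = TRUE)
  if (frame_interval_min > window_min) {
    stop_invalid("`frame_interval_min` must be <= `window_min`")
  }
  check_scalar_number(dropout_prob, "dropout_prob", 0)
  if (dropout_prob >= 1) stop_invalid("`dropout_prob` must be < 1")
  check_scalar_number(seed, "seed")
  structure(
    list(
      window_min = window_min, frame_interval_min = frame_interval_min,
      dropout_prob = dropout_prob, seed = as.integer(seed)
    ),
    class = "imaging_config"
  )
}

#' Tissue-level parameters for the production/differentiation calculus
#'
#' Layer occupancies and output constants of the follicle stem cell (FSC)
#' domain: about eight layer-1 FSCs, six layer-2 FSCs and two layer-3 FSCs;
#' one egg chamber buds every ~12 h (720 min), consuming 5-6 (nominally 5.5)
#' proliferative follicle cells (FCs) from layer 1, while escort cells (ECs)
#' are produced from anterior FSCs at about a quarter of the FC rate.
#'
#' @param cells_per_layer Numeric vector of FSC counts for layers 1-3.
#' @param budding_period_min Egg-chamber budding period, minutes.
#' @param fc_per_cycle Follicle cells consumed per budding cycle.
#' @param ec_to_fc_ratio EC production rate as a fraction of FC production.
#'
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(cells_per_layer = c(8, 6, 2),
                          budding_period_min = 720,
                          fc_per_cycle = 5.5,
                          ec_to_fc_ratio = 0.25) {
  if (!is.numeric(cells_per_layer) || length(cells_per_layer) != 3L ||
      any(cells_per_layer < 0)) {
    stop_invalid("`cells_per_layer` must be 3 non-negative counts (layers 1-3)")
  }
  check_scalar_number(budding_period_min, "budding_period_min", 0, strict_min = TRUE)
  check_scalar_number(fc_per_cycle, "fc_per_cycle", 0, strict_min = TRUE)
  check_scalar_number(ec_to_fc_ratio, "ec_to_fc_ratio", 0, strict_min = TRUE)
  structure(
    list(
      cells_per_layer = stats::setNames(cells_per_layer, c("1", "2", "3")),
      budding_period_min = budding_period_min,
      fc_per_cycle = fc_per_cycle,
      ec_to_fc_ratio = ec_to_fc_ratio
    ),
    class = "tissue_params"
  )
}
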