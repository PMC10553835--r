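# Synthetic asynchronous cell populations, imaging windows, fixed snapshots
# and label-dilution series. Everything is seeded and reproducible; one RNG
# stream per germarium, so enlarging a simulated experiment never perturbs
# germaria that were already generated.

# Per-cell phase durations: independent gamma draws per phase with shared cv
# (shape 1/cv^2 keeps the mean at the configured value); cv = 0 is exact.
draw_durations <- function(durations, n) {
  means <- duration_vector(durations)
  out <- matrix(rep(means, each = n), nrow = n,
                dimnames = list(NULL, names(means)))
  if (durations$cv > 0) {
    shape <- 1 / durations$cv^2
    for (p in names(means)) {
      out[, p] <- stats::rgamma(n, shape = shape, rate = shape / means[p])
    }
  }
  out
}

germarium_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

split_germaria <- function(n_cells, n_germaria) {
  idx <- sort(rep_len(seq_len(n_germaria), n_cells))
  sprintf("g%02d", idx)
}

#' Simulate an asynchronous steady-state cell population
#'
#' Draws `n_cells` cells observed at an arbitrary instant of an asynchronous,
#' steadily cycling population: each cell's current phase is sampled with
#' probability proportional to that cell's phase duration (the length-biased
#' occupancy of a renewal process), and its elapsed time within the phase is
#' uniform over the phase. Cells are grouped into germaria, each with its own
#' RNG substream.
#'
#' @param durations A [phase_durations()] object.
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @param n_germaria Number of germaria to spread cells over; defaults to
#'   roughly 6 cells per germarium, matching typical tracked-cell counts.
#' @param layer Anatomical layer label for all cells (one of
#'   `"1","2","3","r2a","r1"`).
#'
#' @return A tibble with one row per cell: `cell_id`, `germarium_id`, `layer`,
#'   `phase`, `time_in_phase_min`, and the cell's own `g1_min`, `s_min`,
#'   `g2_min`, `m_min`.
#' @examples
#' pop <- simulate_population(phase_durations(81, 318, 527, 17), 100, seed = 7)
#' table(pop$phase)
#' @export
simulate_population <- function(durations, n_cells, seed,
                                n_germaria = NULL, layer = "1") {
  if (!inherits(durations, "phase_durations")) {
    stop_invalid("`durations` must be a `phase_durations` object")
  }
  check_scalar_number(n_cells, "n_cells", 1)
  layer <- match.arg(as.character(layer), layer_levels())
  if (is.null(n_germaria)) n_germaria <- max(1L, round(n_cells / 6))
  check_scalar_number(n_germaria, "n_germaria", 1)

  germ <- split_germaria(n_cells, n_germaria)
  seeds <- germarium_seeds(seed, n_germaria)
  germ_ids <- sprintf("g%02d", seq_len(n_germaria))

  pieces <- vector("list", n_germaria)
  for (g in seq_len(n_germaria)) {
    ids <- which(germ == germ_ids[g])
    n <- length(ids)
    if (n == 0L) next
    set.seed(seeds[g])
    durs <- draw_durations(durations, n)
    totals <- rowSums(durs)
    u <- stats::runif(n) * totals
    cum <- cbind(durs[, 1], durs[, 1] + durs[, 2],
                 durs[, 1] + durs[, 2] + durs[, 3], totals)
    phase_idx <- 1L + (u > cum[, 1]) + (u > cum[, 2]) + (u > cum[, 3])
    phase <- phase_order()[phase_idx]
    time_in <- stats::runif(n) * durs[cbind(seq_len(n), phase_idx)]
    pieces[[g]] <- tibble::tibble(
      cell_id = sprintf("%sc%03d", germ_ids[g], seq_len(n)),
      germarium_id = germ_ids[g],
      layer = layer,
      phase = phase,
      time_in_phase_min = time_in,
      g1_min = durs[, "G1"], s_min = durs[, "S"],
      g2_min = durs[, "G2"], m_min = durs[, "M"]
    )
  }
  dplyr::bind_rows(pieces)
}

# FUCCI color state at cycle age `a` given phase boundaries `b` (cumsum of
# the cell's four durations) and reporter lags. Returns list(gfp, rfp, phase).
color_state <- function(a, b, reporters) {
  b <- unname(b)
  if (a < b[1]) {
    list(gfp = TRUE, rfp = FALSE, phase = "G1")
  } else if (a < b[2]) {
    list(gfp = FALSE, rfp = (a - b[1]) >= reporters$rfp_onset_lag_min, phase = "S")
  } else if (a < b[3]) {
    list(gfp = (a - b[2]) >= reporters$gfp_onset_lag_min, rfp = TRUE, phase = "G2")
  } else {
    list(gfp = TRUE, rfp = TRUE, phase = "M")
  }
}

# Simulate one imaged lineage. The track follows a cell through any divisions
# that occur inside the window (the imaged lineage keeps the parent cell_id);
# each division also emits one new daughter track whose first frame is the
# shared mitotic frame. Each daughter independently remains in the monitored
# field with probability `retention` (a homeostatic stem pool exports on
# average one daughter per division to differentiation); a lineage whose
# continuing daughter leaves ends at the mitotic frame. Returns
# list(frames = tibble, daughters = list of (birth, m_frame)).
sim_lineage_frames <- function(cell_id, germarium_id, layer, a0, durs0,
                               birth, durations, reporters, imaging,
                               retention = 0.5, first_frame = NULL) {
  window <- imaging$window_min
  dt <- imaging$frame_interval_min
  grid <- seq(0, window, by = dt)
  grid <- grid[grid >= birth]

  times <- numeric(0); gfp <- logical(0); rfp <- logical(0); mit <- logical(0)
  if (!is.null(first_frame)) {
    times <- first_frame$time; gfp <- first_frame$gfp
    rfp <- first_frame$rfp; mit <- TRUE
    grid <- grid[grid > first_frame$time]
  }

  daughters <- list()
  division_index <- 0L
  cycle_start <- birth - a0
  durs <- durs0
  guard <- 0L
  while (cycle_start < window) {
    guard <- guard + 1L
    if (guard > 10000L) stop_invalid("degenerate durations: too many cycles in window")
    b <- cumsum(durs)
    division <- cycle_start + b[4]
    in_cycle <- grid[grid >= cycle_start & grid < min(division, window + dt / 2)]
    cyc_idx <- integer(0)
    for (t in in_cycle) {
      st <- color_state(t - cycle_start, b, reporters)
      times <- c(times, t); gfp <- c(gfp, st$gfp); rfp <- c(rfp, st$rfp)
      mit <- c(mit, st$phase == "M")
      cyc_idx <- c(cyc_idx, length(times))
    }
    if (division > window) break
    # Division observed inside the window: guarantee a mitotic-flagged frame
    # (mitosis is recognized morphologically in a single frame even when the
    # short M phase falls between two sampling times).
    if (length(cyc_idx) > 0L && !any(mit[cyc_idx])) {
      mit[cyc_idx[length(cyc_idx)]] <- TRUE
    }
    m_frames <- cyc_idx[mit[cyc_idx]]
    keep_a <- stats::runif(1) < retention
    keep_b <- stats::runif(1) < retention
    if (keep_b && length(m_frames) > 0L) {
      k <- m_frames[length(m_frames)]
      division_index <- division_index + 1L
      daughters[[length(daughters) + 1L]] <- list(
        birth = division,
        cell_id = sprintf("%s.%d", cell_id, division_index),
        m_frame = list(time = times[k], gfp = gfp[k], rfp = rfp[k])
      )
    }
    if (!keep_a) break
    # Imaged lineage continues through mitosis with fresh duration draws.
    durs <- drop(draw_durations(durations, 1))
    cycle_start <- division
    a0 <- 0
    grid <- grid[grid >= cycle_start]
  }

  frames <- tibble::tibble(
    cell_id = cell_id, germarium_id = germarium_id, layer = layer,
    time_min = times, gfp = gfp, rfp = rfp, mitotic = mit
  )
  list(frames = frames, daughters = daughters)
}

# Permanent dropout: first frame whose uniform draw falls below dropout_prob
# truncates the track there (cells that leave the z-range never re-enter).
apply_dropout <- function(frames, dropout_prob) {
  n <- nrow(frames)
  if (n == 0L || dropout_prob <= 0) {
    return(list(frames = frames, cutoff = Inf))
  }
  hit <- which(stats::runif(n) < dropout_prob)
  if (length(hit) == 0L) return(list(frames = frames, cutoff = Inf))
  k <- hit[1]
  list(frames = frames[seq_len(k - 1L), , drop = FALSE],
       cutoff = frames$time_min[k])
}

#' Simulate live FUCCI imaging of a cell population
#'
#' Images a simulated population through a finite window at a fixed frame
#' interval. Each frame records the FUCCI color state implied by the cell's
#' true phase and the reporter onset lags (G1: GFP-only; early S: colorless;
#' late S: RFP-only; G2: GFP+RFP; mitosis flagged morphologically in a single
#' frame). Cells progress through the cycle during the window; a division
#' produces two G1 daughters — the imaged lineage continues under the parent
#' `cell_id`, and a second daughter track starts at the shared mitotic frame.
#' Dropout permanently truncates a track.
#'
#' Each daughter independently remains in the monitored cell pool with
#' probability `daughter_retention_prob`. The default 0.5 keeps the imaged
#' population stationary, emulating a homeostatic stem-cell field in which
#' differentiation consumes, on average, one daughter per division; without
#' it the pool grows during the window and phase occupancies drift away from
#' the steady-state duration fractions. Set it to 1 to watch both daughters
#' of every division.
#'
#' @param population Output of [simulate_population()].
#' @param durations The [phase_durations()] used to draw daughters' cycles.
#' @param reporters A [reporter_config()].
#' @param imaging An [imaging_config()]; its `seed` drives all randomness here.
#' @param daughter_retention_prob Probability that each daughter of a division
#'   stays in the imaged pool (default 0.5, homeostasis).
#'
#' @return A tibble of frames: `cell_id`, `germarium_id`, `layer`, `time_min`,
#'   `gfp`, `rfp`, `mitotic`.
#' @export
simulate_imaging <- function(population, durations,
                             reporters = reporter_config(),
                             imaging = imaging_config(),
                             daughter_retention_prob = 0.5) {
  if (!inherits(durations, "phase_durations")) {
    stop_invalid("`durations` must be a `phase_durations` object")
  }
  if (!inherits(reporters, "reporter_config")) {
    stop_invalid("`reporters` must be a `reporter_config` object")
  }
  if (!inherits(imaging, "imaging_config")) {
    stop_invalid("`imaging` must be an `imaging_config` object")
  }
  check_scalar_number(daughter_retention_prob, "daughter_retention_prob", 0)
  if (daughter_retention_prob > 1) {
    stop_invalid("`daughter_retention_prob` must be in [0, 1]")
  }
  germ_ids <- unique(population$germarium_id)
  seeds <- germarium_seeds(imaging$seed, length(germ_ids))
  phase_starts <- c(G1 = 0L, S = 1L, G2 = 2L, M = 3L)

  out <- vector("list", length(germ_ids))
  for (g in seq_along(germ_ids)) {
    set.seed(seeds[g])
    cells <- population[population$germarium_id == germ_ids[g], , drop = FALSE]
    queue <- vector("list", nrow(cells))
    for (i in seq_len(nrow(cells))) {
      durs <- c(G1 = cells$g1_min[i], S = cells$s_min[i],
                G2 = cells$g2_min[i], M = cells$m_min[i])
      before <- phase_starts[[cells$phase[i]]]
      a0 <- if (before > 0) sum(durs[seq_len(before)]) else 0
      a0 <- a0 + cells$time_in_phase_min[i]
      queue[[i]] <- list(cell_id = cells$cell_id[i], layer = cells$layer[i],
                         a0 = a0, durs = durs, birth = 0, first_frame = NULL)
    }
    pieces <- list()
    while (length(queue) > 0L) {
      job <- queue[[1]]
      queue <- queue[-1]
      res <- sim_lineage_frames(job$cell_id, germ_ids[g], job$layer, job$a0,
                                job$durs, job$birth, durations, reporters,
                                imaging, retention = daughter_retention_prob,
                                first_frame = job$first_frame)
      dropped <- apply_dropout(res$frames, imaging$dropout_prob)
      pieces[[length(pieces) + 1L]] <- dropped$frames
      for (d in res$daughters) {
        if (d$birth <= dropped$cutoff) {
          queue[[length(queue) + 1L]] <- list(
            cell_id = d$cell_id, layer = job$layer, a0 = 0,
            durs = drop(draw_durations(durations, 1)),
            birth = d$birth, first_frame = d$m_frame
          )
        }
      }
    }
    out[[g]] <- dplyr::bind_rows(pieces)
  }
  res <- dplyr::bind_rows(out)
  res[nzchar(res$cell_id) & !is.na(res$time_min), , drop = FALSE]
}

#' Simulate a fixed FUCCI/EdU snapshot
#'
#' Fixes a simulated asynchronous population at a single instant after an EdU
#' pulse. Color states follow the reporter lags exactly as in
#' [simulate_imaging()]; a cell is EdU-positive if any part of the pulse
#' window overlapped S-phase (including S time spent in the previous cycle
#' for recently divided cells). All cells are DAPI-positive.
#'
#' @inheritParams simulate_population
#' @param reporters A [reporter_config()]; `edu_pulse_min` sets the pulse.
#' @param location Anatomical location label for all cells.
#' @param genotype Genotype label stored in the output.
#' @param edu If `FALSE`, the EdU channel is recorded as missing (`NA`),
#'   emulating the DAPI-only protocol.
#'
#' @return A tibble: `cell_id`, `germarium_id`, `location`, `gfp`, `rfp`,
#'   `edu`, `dapi`, `genotype`.
#' @export
simulate_snapshot <- function(durations, n_cells, reporters = reporter_config(),
                              seed = 1L, n_germaria = NULL,
                              location = "1", genotype = "control",
                              edu = TRUE) {
  pop <- simulate_population(durations, n_cells, seed = seed,
                             n_germaria = n_germaria, layer = location)
  phase_starts <- c(G1 = 0L, S = 1L, G2 = 2L, M = 3L)
  n <- nrow(pop)
  gfp <- rfp <- edu_pos <- logical(n)
  pulse <- reporters$edu_pulse_min
  for (i in seq_len(n)) {
    durs <- c(pop$g1_min[i], pop$s_min[i], pop$g2_min[i], pop$m_min[i])
    b <- cumsum(durs)
    before <- phase_starts[[pop$phase[i]]]
    a <- (if (before > 0) b[before] else 0) + pop$time_in_phase_min[i]
    st <- color_state(a, b, reporters)
    gfp[i] <- st$gfp
    rfp[i] <- st$rfp
    # Pulse interval [a - pulse, a] vs S at [b1, b2] (this cycle) or
    # [b1 - total, b2 - total] (previous cycle, for recently divided cells).
    edu_pos[i] <- (a > b[1] && a - pulse < b[2]) || (a - pulse < b[2] - b[4])
  }
  tibble::tibble(
    cell_id = pop$cell_id, germarium_id = pop$germarium_id,
    location = pop$layer, gfp = gfp, rfp = rfp,
    edu = if (edu) edu_pos else NA,
    dapi = TRUE, genotype = genotype
  )
}

#' Simulate H2B-RFP label dilution
#'
#' A stable chromatin-bound label halves at each division:
#' `intensity = initial * 2^(-divisions) * noise`, with optional multiplicative
#' lognormal noise of a given coefficient of variation (mean 1).
#'
#' @param initial_intensities Positive initial intensities, one per cell.
#' @param divisions_per_cell Non-negative division counts (recycled).
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param seed Integer seed.
#' @param layer,germarium_id,chase_day Labels stored in the output table.
#'
#' @return A tibble: `cell_id`, `germarium_id`, `layer`, `intensity`,
#'   `chase_day`, plus `divisions` and `initial_intensity` for reference.
#' @examples
#' simulate_dilution(1, 2)$intensity  # 0.25
#' @export
simulate_dilution <- function(initial_intensities, divisions_per_cell,
                              noise_cv = 0, seed = 1L,
                              layer = "1", germarium_id = "g01",
                              chase_day = 0) {
  if (!is.numeric(initial_intensities) || any(initial_intensities <= 0)) {
    stop_invalid("`initial_intensities` must all be > 0")
  }
  if (!is.numeric(divisions_per_cell) || any(divisions_per_cell < 0)) {
    stop_invalid("`divisions_per_cell` must all be >= 0")
  }
  check_scalar_number(noise_cv, "noise_cv", 0)
  n <- length(initial_intensities)
  div <- rep_len(divisions_per_cell, n)
  set.seed(as.integer(seed))
  noise <- if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    rep(1, n)
  }
  tibble::tibble(
    cell_id = sprintf("c%04d", seq_len(n)),
    germarium_id = rep_len(as.character(germarium_id), n),
    layer = rep_len(as.character(layer), n),
    intensity = initial_intensities * 2^(-div) * noise,
    chase_day = rep_len(chase_day, n),
    divisions = div,
    initial_intensity = initial_intensities
  )
}
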