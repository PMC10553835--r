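test_that("steady-state occupancy is proportional to phase duration", {
  wt <- wt_durations()
  pop <- simulate_population(wt, 10000, seed = 42)
  # binomial oracle: 3 SE band around the length-biased expectation
  for (ph in c("G1", "S", "G2", "M")) {
    p <- switch(ph, G1 = 81, S = 318, G2 = 527, M = 17) / 943
    se <- sqrt(p * (1 - p) / 10000)
    expect_lt(abs(mean(pop$phase == ph) - p), 3 * se)
  }
})

test_that("occupancy stays at duration fractions with per-cell variability", {
  pop <- simulate_population(wt_durations(cv = 0.3), 10000, seed = 43)
  p <- 527 / 943
  se <- sqrt(p * (1 - p) / 10000)
  # slightly wider band: with heterogeneous cells the occupancy expectation
  # carries a small ratio-of-gammas correction of the same order as 1 SE
  expect_lt(abs(mean(pop$phase == "G2") - p), 4 * se)
})

test_that("a phase holding almost the whole cycle captures all cells", {
  eps <- 1e-6
  pop <- simulate_population(phase_durations(eps, eps, 1000, eps), 500, seed = 1)
  expect_true(all(pop$phase == "G2"))
})

test_that("population generation is deterministic given the seed", {
  wt <- wt_durations(cv = 0.2)
  expect_identical(simulate_population(wt, 200, seed = 9),
                   simulate_population(wt, 200, seed = 9))
})

test_that("invalid simulator parameters are rejected", {
  expect_error(phase_durations(-1, 318, 527, 17), "must be >")
  expect_error(phase_durations(81, 318, 527, 17, cv = -0.1), "cv")
  expect_error(simulate_population(wt_durations(), 0, seed = 1), "n_cells")
  expect_error(imaging_config(frame_interval_min = 200, window_min = 100),
               "frame_interval_min")
  expect_error(imaging_config(dropout_prob = 1), "dropout_prob")
  expect_error(simulate_dilution(1, -2), "divisions_per_cell")
  expect_error(simulate_dilution(-1, 2), "initial_intensities")
})

test_that("an observed division flags one mitotic frame and yields two G1 daughters", {
  wt <- wt_durations()
  # one cell 30 min from the end of G2: division ~47 min into the window
  pop <- tibble::tibble(
    cell_id = "g01c001", germarium_id = "g01", layer = "1", phase = "G2",
    time_in_phase_min = 497, g1_min = 81, s_min = 318, g2_min = 527, m_min = 17
  )
  tr <- simulate_imaging(pop, wt, reporter_config(),
                         imaging_config(window_min = 150,
                                        frame_interval_min = 20, seed = 5),
                         daughter_retention_prob = 1)
  # exactly one mitotic frame per track for this single division
  per_track_m <- tapply(tr$mitotic, tr$cell_id, sum)
  expect_true(all(per_track_m <= 1))
  expect_identical(sum(tr$mitotic), 2L)  # shared frame appears in both tracks
  m_time <- unique(tr$time_min[tr$mitotic])
  expect_length(m_time, 1)
  # after mitosis, two tracks show GFP-only G1 frames
  g1_after <- tr[tr$time_min > m_time & tr$gfp & !tr$rfp, ]
  expect_setequal(unique(g1_after$cell_id), c("g01c001", "g01c001.1"))
})

test_that("early S-phase cells are colorless for the RFP onset lag", {
  # direct integration oracle: fraction of S-phase occupancy that is
  # colorless = lag / S duration
  snap <- simulate_snapshot(wt_durations(), 20000,
                            reporter_config(rfp_onset_lag_min = 114),
                            seed = 11)
  s_cells <- snap[!snap$gfp, ]
  frac_colorless <- mean(!s_cells$rfp)
  expected <- 114 / 318
  se <- sqrt(expected * (1 - expected) / nrow(s_cells))
  expect_lt(abs(frac_colorless - expected), 3 * se)
})

test_that("imaging is deterministic and respects the frame grid", {
  wt <- wt_durations()
  pop <- simulate_population(wt, 60, seed = 3)
  cfg <- imaging_config(window_min = 150, frame_interval_min = 20, seed = 3)
  tr1 <- simulate_imaging(pop, wt, imaging = cfg)
  tr2 <- simulate_imaging(pop, wt, imaging = cfg)
  expect_identical(tr1, tr2)
  expect_true(all(tr1$time_min %% 20 == 0))
  expect_true(all(tr1$time_min <= 150))
  # frames strictly ordered within each track (valid schema)
  expect_silent(as_cell_tracks(tr1))
})

test_that("tracks only ever step through the cyclic phase order", {
  wt <- wt_durations(cv = 0.2)
  pop <- simulate_population(wt, 300, seed = 17)
  tr <- simulate_imaging(pop, wt, reporter_config(),
                         imaging_config(window_min = 300,
                                        frame_interval_min = 15, seed = 17))
  cls <- germcycle:::classify_all(tr)
  expect_identical(nrow(cls$ambiguous), 0L)
})

test_that("dropout truncates tracks permanently", {
  wt <- wt_durations()
  pop <- simulate_population(wt, 200, seed = 8)
  cfg_drop <- imaging_config(window_min = 150, frame_interval_min = 20,
                             dropout_prob = 0.2, seed = 8)
  cfg_keep <- imaging_config(window_min = 150, frame_interval_min = 20,
                             dropout_prob = 0, seed = 8)
  tr_drop <- simulate_imaging(pop, wt, imaging = cfg_drop)
  tr_keep <- simulate_imaging(pop, wt, imaging = cfg_keep)
  expect_lt(nrow(tr_drop), nrow(tr_keep))
  # no gaps: each track's frames form a prefix of the grid it was born on
  by_cell <- split(tr_drop$time_min, tr_drop$cell_id)
  expect_true(all(vapply(by_cell, function(t) all(diff(t) == 20), logical(1))))
})

test_that("snapshot S fraction matches the duration fraction", {
  snap <- simulate_snapshot(wt_durations(), 10000, seed = 21)
  p <- 318 / 943
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(classify_phase(snap) == "S") - p), 3 * se)
})

test_that("EdU marks pulse-overlap with S and exceeds the instantaneous S fraction", {
  snap <- simulate_snapshot(wt_durations(), 10000, seed = 22)
  edu_index <- mean(snap$edu)
  s_frac <- mean(classify_phase(snap) == "S")
  expect_gt(edu_index, s_frac)
  p <- (318 + 60) / 943  # 1 h pulse widens the window of S overlap
  expect_lt(abs(edu_index - p), 3 * sqrt(p * (1 - p) / 10000))
})

test_that("with a vanishing S phase only pulse-edge cells are EdU positive", {
  dur <- phase_durations(81, 1e-3, 527, 17)
  snap <- simulate_snapshot(dur, 5000, seed = 23)
  expect_identical(sum(classify_phase(snap) == "S"), 0L)
  p_edge <- 60 / dur$total_min
  expect_lt(mean(snap$edu), p_edge + 3 * sqrt(p_edge * (1 - p_edge) / 5000))
})

test_that("a population forced into G1 is entirely GFP-only", {
  eps <- 1e-9
  snap <- simulate_snapshot(phase_durations(100, eps, eps, eps), 300, seed = 2)
  expect_true(all(snap$gfp & !snap$rfp))
  expect_true(all(classify_phase(snap) == "G1"))
})

test_that("label dilution halves intensity per division", {
  expect_equal(simulate_dilution(1, 2)$intensity, 0.25)
  expect_equal(simulate_dilution(c(0.5, 2), 0)$intensity, c(0.5, 2))
})

test_that("division counts are recoverable from noisy dilution", {
  # simulation oracle: Poisson divisions over a 3 d chase at the wild-type
  # cycle time, recovered via log2 within 10% at n = 1000
  lambda <- 3 * 1440 / 943
  set.seed(99)
  div <- stats::rpois(1000, lambda)
  tab <- simulate_dilution(rep(1, 1000), div, noise_cv = 0.2, seed = 99)
  recovered <- mean(divisions_from_dilution(1, tab$intensity))
  expect_lt(abs(recovered - mean(div)) / mean(div), 0.1)
})
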