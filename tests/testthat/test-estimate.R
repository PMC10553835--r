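test_that("dwell summaries match hand counts, with censoring", {
  # two cells each observed 60 min in G2; one exits to M, one is censored
  tracks <- dplyr::bind_rows(
    make_track(c("G2", "G2", "G2", "G2", "M", "G1"), cell_id = "a", dt = 20),
    make_track(c("G2", "G2", "G2", "G2"), cell_id = "b", dt = 20)
  )
  s <- summarize_tracks(tracks, "G2", drop_inert_germaria = FALSE)
  # cell a: 0 -> midpoint(60, 80) = 70; cell b: 0 -> 60 censored
  expect_equal(s$total_observed_min, 70 + 60)
  expect_identical(s$exits, 1L)
  expect_identical(s$cells_tracked, 2L)
})

test_that("a cell in phase for the whole window adds time but no exit", {
  s <- summarize_tracks(make_track(rep("G2", 8)), "G2",
                        drop_inert_germaria = FALSE)
  expect_equal(s$total_observed_min, 140)
  expect_identical(s$exits, 0L)
  expect_error(estimate_phase_duration(s), "no transitions out of G2")
})

test_that("summaries equal a naive frame-by-frame recount on simulated cohorts", {
  wt <- wt_durations(cv = 0.1)
  pop <- simulate_population(wt, 300, seed = 12)
  tr <- simulate_imaging(pop, wt, imaging = imaging_config(
    window_min = 200, frame_interval_min = 20, dropout_prob = 0.05, seed = 12
  ))
  for (ph in c("G1", "G2", "M")) {
    s <- summarize_tracks(tr, ph, drop_inert_germaria = FALSE, quiet = TRUE)
    oracle <- naive_dwell(tr, ph)
    expect_equal(s$total_observed_min, oracle$total, tolerance = 1e-10)
    expect_identical(s$exits, oracle$exits)
  }
})

test_that("the duration estimate is total observed time over observed exits", {
  est <- estimate_phase_duration(phase_dwell_summary("G1", 100, 4))
  expect_equal(est$minutes, 25)
  expect_identical(est$minutes_rounded, 25)
  expect_error(phase_dwell_summary("S", 10, 1), "'arg'")
})

test_that("inert germaria are excluded by default with a message", {
  active <- make_track(c("G1", "G1", "S-"), cell_id = "a", germarium_id = "gA")
  quiet <- make_track(rep("G2", 3), cell_id = "b", germarium_id = "gB")
  tracks <- dplyr::bind_rows(active, quiet)
  expect_message(s <- summarize_tracks(tracks, "G2"), "inert")
  expect_equal(s$total_observed_min, 0)
  s_all <- summarize_tracks(tracks, "G2", drop_inert_germaria = FALSE)
  expect_equal(s_all$total_observed_min, 40)
})

test_that("S duration follows from the snapshot fraction", {
  expect_equal(round(infer_s_duration(81, 527, 17, 0.337)), 318)
  expect_equal(round(infer_s_duration(407, 1958, 20, 0.26)), 838)
  expect_equal(infer_s_duration(81, 527, 17, 0), 0)
  expect_error(infer_s_duration(81, 527, 17, 1), "s_fraction")
  # monotone increasing in fS
  fs <- seq(0, 0.9, by = 0.05)
  vals <- vapply(fs, function(f) infer_s_duration(81, 527, 17, f), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("snapshot S fractions pool across germaria by cell count", {
  big <- simulate_snapshot(phase_durations(1, 1000, 1, 1), 90, seed = 1,
                           n_germaria = 1)
  small <- simulate_snapshot(phase_durations(1000, 1, 1, 1), 10, seed = 2,
                             n_germaria = 1)
  small$germarium_id <- "g99"
  pooled <- s_fraction_from_snapshot(dplyr::bind_rows(big, small))
  expect_equal(pooled, (sum(classify_phase(big) == "S") +
                          sum(classify_phase(small) == "S")) / 100)
  expect_gt(pooled, 0.85)  # dominated by the large all-S germarium
})

test_that("cycle ratios divide total cycle times", {
  expect_equal(cycle_ratio(943, 943), 1)
  a <- cell_cycle_estimate(81, 318, 527, 17)
  b <- cell_cycle_estimate(205, 288, 277, 27)
  expect_equal(cycle_ratio(a, b), 943 / 797)
})

test_that("the full-cycle wrapper combines tracks and snapshot fraction", {
  wt <- wt_durations()
  pop <- simulate_population(wt, 800, seed = 14)
  tr <- simulate_imaging(pop, wt, imaging = imaging_config(seed = 14))
  est <- estimate_cell_cycle(tr, s_fraction = 318 / 943,
                             drop_inert_germaria = FALSE, quiet = TRUE)
  expect_s3_class(est, "cell_cycle_estimate")
  expect_equal(est$total_min,
               est$g1_min + est$s_min + est$g2_min + est$m_min)
  expect_lt(abs(est$total_min - 943) / 943, 0.2)
})

test_that("bootstrap over identical germaria degenerates to the point estimate", {
  tracks <- dplyr::bind_rows(lapply(1:4, function(g) {
    make_track(c("G2", "G2", "M", "G1"), cell_id = sprintf("c%d", g),
               germarium_id = sprintf("g%d", g))
  }))
  ci <- bootstrap_ci(tracks, "G2", n_reps = 50, seed = 1)
  expect_equal(ci$lower, ci$point)
  expect_equal(ci$upper, ci$point)
  expect_error(bootstrap_ci(tracks, "G2", n_reps = 0), "n_reps")
  one <- make_track(c("G2", "M", "G1"))
  expect_error(bootstrap_ci(one, "G2", n_reps = 10), ">= 2 germaria")
})

test_that("bootstrap intervals cover the true duration across meta-replicates", {
  wt <- wt_durations()
  covered <- 0L
  n_meta <- 10L
  for (m in seq_len(n_meta)) {
    pop <- simulate_population(wt, 600, seed = 1000 + m)
    tr <- simulate_imaging(pop, wt,
                           imaging = imaging_config(seed = 1000 + m))
    ci <- bootstrap_ci(tr, "G2", n_reps = 200, seed = m,
                       drop_inert_germaria = FALSE)
    if (ci$lower <= 527 && 527 <= ci$upper) covered <- covered + 1L
  }
  expect_gte(covered, 8L)
})
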