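snap_record <- function(gfp, rfp, edu = NA, dapi = TRUE) {
  tibble::tibble(cell_id = "c1", germarium_id = "g1", location = "1",
                 gfp = gfp, rfp = rfp, edu = edu, dapi = dapi,
                 genotype = "control")
}

test_that("reporter states map onto phases as a total function", {
  expect_identical(classify_phase(snap_record(TRUE, FALSE)), "G1")
  expect_identical(classify_phase(snap_record(TRUE, TRUE)), "G2/M")
  expect_identical(classify_phase(snap_record(FALSE, TRUE)), "S")
  expect_identical(classify_phase(snap_record(FALSE, FALSE, edu = TRUE)), "S")
  expect_identical(classify_phase(snap_record(FALSE, FALSE)), "S")
})

test_that("fraction tables carry proportions with binomial SEs", {
  snap <- simulate_snapshot(wt_durations(), 4000, seed = 33)
  tab <- fraction_table(snap)
  expect_equal(tab$fraction_g1 + tab$fraction_s + tab$fraction_g2m, 1)
  p <- 527 / 943  # G2 occupancy; M adds ~2% to the G2/M bin
  expect_lt(abs(tab$fraction_g2m - (527 + 17) / 943),
            3 * sqrt(p * (1 - p) / 4000))
  expect_equal(tab$se_g1, sqrt(tab$fraction_g1 * (1 - tab$fraction_g1) / 4000))
})

test_that("a single-cell group has degenerate fractions and zero SE", {
  tab <- fraction_table(snap_record(TRUE, FALSE))
  expect_equal(tab$fraction_g1, 1)
  expect_equal(tab$fraction_s, 0)
  expect_equal(tab$se_g1, 0)
})

test_that("layer-1 control counts reproduce the G1-poor, G2-rich pattern", {
  # synthetic fixture built from the published layer-1 percentages
  # (8% G1, 33% S, 59% G2/M) at n = 100
  counts <- c(G1 = 8, S = 33, G2M = 59)
  rec <- tibble::tibble(
    cell_id = sprintf("c%03d", 1:100), germarium_id = "g1", location = "1",
    gfp = rep(c(TRUE, FALSE, TRUE), counts),
    rfp = rep(c(FALSE, FALSE, TRUE), counts),
    edu = NA, dapi = TRUE, genotype = "control"
  )
  tab <- fraction_table(rec)
  expect_equal(round(100 * tab$fraction_g1), 8)
  expect_equal(round(100 * tab$fraction_g2m), 59)
})

test_that("the N-1 chi-squared is the classical statistic scaled by (N-1)/N", {
  res <- n1_chisq(5, 10, 9, 10)
  classical <- suppressWarnings(
    stats::chisq.test(matrix(c(5, 5, 9, 1), 2, byrow = TRUE),
                      correct = FALSE)$statistic
  )
  expect_equal(res$statistic, unname(classical) * 19 / 20)
  expect_lt(res$p_value, 0.2)
})

test_that("identical proportions give a zero statistic and p = 1", {
  res <- n1_chisq(4, 10, 8, 20)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(n1_chisq(0, 5, 0, 7)$statistic, 0)
  expect_equal(n1_chisq(5, 5, 7, 7)$statistic, 0)
})

test_that("the N-1 statistic is symmetric in group order", {
  a <- n1_chisq(3, 12, 9, 15)
  b <- n1_chisq(9, 15, 3, 12)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$z, -b$z)
})

test_that("EdU normalization rescales FSC layers by the control ratio", {
  tab <- tibble::tibble(location = c("1", "2", "3", "r2a"),
                        edu_index = c(0.30, 0.20, 0.10, 0.05),
                        n_cells = 50)
  out <- normalize_edu(tab, global_control_layer1 = 0.33,
                       experiment_control_layer1 = 0.30)
  expect_equal(out$edu_index[1:3], c(0.33, 0.22, 0.11))
  expect_equal(out$edu_index[4], 0.05)  # EC indices never normalized
  same <- normalize_edu(tab, 0.30, 0.30)
  expect_equal(same$edu_index, tab$edu_index)
})

test_that("expected EdU pattern preserves the weighted mean and detects deviation", {
  w <- c(0.50, 0.37, 0.13)       # normal FSC distribution among layers
  ctrl <- c(0.33, 0.20, 0.07)    # control per-layer indices
  same <- expected_edu_distribution(ctrl, ctrl, w)
  expect_equal(same$expected, ctrl)
  expect_equal(same$statistic, 0)

  flat <- c(0.25, 0.25, 0.25)
  res <- expected_edu_distribution(flat, ctrl, w)
  # hand computation: m = 0.25; scale = m / sum(w * ctrl)
  scale <- 0.25 / sum(w * ctrl)
  expect_equal(res$expected, ctrl * scale)
  expect_equal(sum(w * res$expected), 0.25)
  expect_gt(res$statistic, 0)

  # expected pattern shape is invariant to rescaling the control indices
  res2 <- expected_edu_distribution(flat, 2 * ctrl, w)
  expect_equal(res2$expected, res$expected)

  literal <- expected_edu_distribution(flat, ctrl, w, preserve_mean = FALSE)
  expect_equal(literal$expected, 0.25 * ctrl)
})
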