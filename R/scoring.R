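# Fixed-snapshot scoring: phase classification from FUCCI/EdU/DAPI states,
# per-location fraction tables, the N-1 chi-squared two-proportion test, and
# EdU-index normalization and expected-pattern comparison.

#' Classify snapshot cells into cycle phases
#'
#' GFP-only cells are in G1; GFP+RFP cells are in G2 or M ("G2/M"); cells
#' lacking GFP are in S-phase, whether RFP-only (late S) or colorless (early
#' S, countable via DAPI or EdU). The mapping is a total function on the
#' reporter-state vocabulary.
#'
#' @param records Snapshot records ([as_snapshot_records()] schema).
#' @return A character vector of `"G1"`, `"S"`, `"G2/M"` per record.
#' @export
classify_phase <- function(records) {
  records <- as_snapshot_records(records)
  dplyr::case_when(
    records$gfp & !records$rfp ~ "G1",
    records$gfp & records$rfp ~ "G2/M",
    .default = "S"
  )
}

#' Phase-fraction table with standard errors
#'
#' Per group (by default location and genotype): cell count, the fractions of
#' cells in G1, S and G2/M, and the standard error of each proportion,
#' `sqrt(p * (1 - p) / n)`. Fractions sum to 1 within each group.
#'
#' @param records Snapshot records.
#' @param group Character vector of grouping columns.
#' @return A tibble with `n_cells`, `fraction_g1`, `fraction_s`,
#'   `fraction_g2m` and `se_g1`, `se_s`, `se_g2m` per group.
#' @export
fraction_table <- function(records, group = c("location", "genotype")) {
  records <- as_snapshot_records(records)
  records$phase <- classify_phase(records)
  se_p <- function(p, n) sqrt(p * (1 - p) / n)
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      fraction_g1 = mean(.data$phase == "G1"),
      fraction_s = mean(.data$phase == "S"),
      fraction_g2m = mean(.data$phase == "G2/M"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      se_g1 = se_p(.data$fraction_g1, .data$n_cells),
      se_s = se_p(.data$fraction_s, .data$n_cells),
      se_g2m = se_p(.data$fraction_g2m, .data$n_cells)
    )
}

#' EdU index table
#'
#' Fraction of EdU-positive cells per group, among cells with a scored EdU
#' channel.
#'
#' @inheritParams fraction_table
#' @return A tibble with `n_cells` (EdU-scored cells) and `edu_index`.
#' @export
edu_table <- function(records, group = c("location", "genotype")) {
  records <- as_snapshot_records(records)
  records <- records[!is.na(records$edu), , drop = FALSE]
  if (nrow(records) == 0L) stop_invalid("no records with a scored EdU channel")
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      edu_index = mean(.data$edu),
      .groups = "drop"
    )
}

#' "N-1" chi-squared test for two proportions
#'
#' The classical 2x2 Pearson chi-squared statistic scaled by `(N - 1) / N`,
#' where `N = n1 + n2`, with the p-value from the chi-squared distribution
#' with one degree of freedom. The statistic is symmetric in group order and
#' zero for identical proportions.
#'
#' @param successes1,n1 Successes and total in group 1.
#' @param successes2,n2 Successes and total in group 2.
#' @return A list with `statistic`, `p_value`, `z` (signed square root,
#'   positive when group 1 has the higher proportion) and `n`.
#' @examples
#' n1_chisq(5, 10, 9, 10)
#' @export
n1_chisq <- function(successes1, n1, successes2, n2) {
  check_scalar_number(n1, "n1", 1)
  check_scalar_number(n2, "n2", 1)
  check_scalar_number(successes1, "successes1", 0)
  check_scalar_number(successes2, "successes2", 0)
  if (successes1 > n1 || successes2 > n2) {
    stop_invalid("successes cannot exceed group totals")
  }
  a <- successes1; b <- n1 - successes1
  c_ <- successes2; d <- n2 - successes2
  n <- n1 + n2
  col1 <- a + c_; col2 <- b + d
  if (col1 == 0 || col2 == 0) {
    classical <- 0
  } else {
    classical <- n * (a * d - b * c_)^2 / (n1 * n2 * col1 * col2)
  }
  statistic <- classical * (n - 1) / n
  list(
    statistic = statistic,
    p_value = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
    z = sign(a / n1 - c_ / n2) * sqrt(statistic),
    n = n
  )
}

#' Normalize experimental EdU indices to the global control level
#'
#' EdU incorporation varies between experiments, so each layer's index for an
#' experimental genotype is multiplied by the ratio of the layer-1 index over
#' all controls to the layer-1 index of the control run in the same
#' experiment. Escort-cell (r2a, r1) indices are never normalized.
#'
#' @param experiment An EdU table (columns `location`, `edu_index`, ...).
#' @param global_control_layer1 Layer-1 EdU index averaged over all controls.
#' @param experiment_control_layer1 Layer-1 EdU index of this experiment's
#'   control (> 0).
#' @return The table with `edu_index` rescaled for FSC layers.
#' @examples
#' tab <- tibble::tibble(location = "2", edu_index = 0.20, n_cells = 50)
#' normalize_edu(tab, 0.33, 0.30)$edu_index  # 0.22
#' @export
normalize_edu <- function(experiment, global_control_layer1,
                          experiment_control_layer1) {
  require_columns(experiment, c("location", "edu_index"), "EdU table")
  check_scalar_number(global_control_layer1, "global_control_layer1", 0)
  check_scalar_number(experiment_control_layer1, "experiment_control_layer1",
                      0, strict_min = TRUE)
  ratio <- global_control_layer1 / experiment_control_layer1
  fsc <- experiment$location %in% c("1", "2", "3")
  experiment$edu_index[fsc] <- experiment$edu_index[fsc] * ratio
  experiment
}

#' Expected EdU-index pattern under the control layer distribution
#'
#' Tests whether a genotype's EdU indices are distributed across FSC layers
#' the way control indices are. The genotype's average index is first
#' computed with layers weighted by the normal distribution of FSCs among
#' layers; that average is then spread across layers in proportion to the
#' control per-layer pattern. With `preserve_mean = TRUE` (default) the
#' control pattern is rescaled so the expected indices have the same weighted
#' average as observed, making the two patterns directly comparable; with
#' `FALSE` the literal product `average x control index` is used. A
#' chi-squared statistic compares observed and expected per-layer indices.
#'
#' @param genotype_index,control_index Numeric vectors of per-layer EdU
#'   indices (same layer order).
#' @param weights Layer weights summing to 1 (normal FSC distribution among
#'   layers).
#' @param preserve_mean Use the weighted-mean-preserving redistribution
#'   (default) rather than the literal product.
#' @return A list with `expected`, `weighted_mean`, `statistic`, `df`,
#'   `p_value`.
#' @export
expected_edu_distribution <- function(genotype_index, control_index, weights,
                                      preserve_mean = TRUE) {
  k <- length(genotype_index)
  if (length(control_index) != k || length(weights) != k) {
    stop_invalid("`genotype_index`, `control_index` and `weights` must have equal length")
  }
  if (abs(sum(weights) - 1) > 1e-8) stop_invalid("`weights` must sum to 1")
  if (all(control_index == 0)) {
    stop_invalid("control indices are zero in every layer")
  }
  m <- sum(weights * genotype_index)
  expected <- if (preserve_mean) {
    m * control_index / sum(weights * control_index)
  } else {
    m * control_index
  }
  nonzero <- expected > 0
  statistic <- sum((genotype_index[nonzero] - expected[nonzero])^2 /
                     expected[nonzero])
  df <- k - 1L
  list(
    expected = expected,
    weighted_mean = m,
    statistic = statistic,
    df = df,
    p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE)
  )
}
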