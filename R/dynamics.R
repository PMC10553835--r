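# Tissue flux calculus: converting cell-cycle times into follicle-cell (FC)
# and escort-cell (EC) output per egg-chamber budding cycle, required cycle
# times for a given output, and the division/differentiation balance.

#' Cell production per budding period
#'
#' `n_cells * period / cycle_time`: the number of new cells produced by
#' `n_cells` stem cells per budding period (without depletion), e.g.
#' 8 layer-1 cells cycling every 943 min produce 6.1 cells per 720-min cycle.
#'
#' @param n_cells Number of stem cells in the layer.
#' @param cycle_time_min Average cell-cycle time, minutes.
#' @param period_min Budding period, minutes (default 720).
#' @return Cells per period (unrounded; report to one decimal).
#' @examples
#' round(production_rate(8, 943), 1)  # 6.1
#' @export
production_rate <- function(n_cells, cycle_time_min, period_min = 720) {
  check_scalar_number(n_cells, "n_cells", 0)
  check_scalar_number(cycle_time_min, "cycle_time_min", 0, strict_min = TRUE)
  check_scalar_number(period_min, "period_min", 0, strict_min = TRUE)
  n_cells * period_min / cycle_time_min
}

#' Cycle time required for a given output
#'
#' Exact inverse of [production_rate()]: `period * n_cells / output`, e.g.
#' producing 5.5 FCs per 720-min cycle from 8 layer-1 cells requires a
#' 1047-min cell cycle.
#'
#' @param n_cells Number of stem cells.
#' @param output_per_period Cells produced per period (> 0).
#' @param period_min Budding period, minutes.
#' @return Required average cycle time, minutes.
#' @examples
#' round(required_cycle_time(8, 5.5))  # 1047
#' @export
required_cycle_time <- function(n_cells, output_per_period, period_min = 720) {
  check_scalar_number(n_cells, "n_cells", 0)
  check_scalar_number(output_per_period, "output_per_period", 0,
                      strict_min = TRUE)
  check_scalar_number(period_min, "period_min", 0, strict_min = TRUE)
  period_min * n_cells / output_per_period
}

#' Required layer-2 : layer-1 cycle-time ratio
#'
#' For EC production at `ec_to_fc_ratio` times the FC rate to be sustained by
#' the layer-2 pool alone, layer-2 cells must cycle slower than layer-1 cells
#' by `(1 / ec_to_fc_ratio) * n_layer2 / n_layer1` — 3.0 at the defaults
#' (4 x 6 / 8). Live imaging deduced a measured ratio of 3.4.
#'
#' @param params A [tissue_params()].
#' @return The dimensionless required ratio.
#' @export
required_cycle_ratio <- function(params = tissue_params()) {
  if (!inherits(params, "tissue_params")) {
    stop_invalid("`params` must be a `tissue_params` object")
  }
  (1 / params$ec_to_fc_ratio) *
    params$cells_per_layer[["2"]] / params$cells_per_layer[["1"]]
}

#' Differentiation loss per stem cell per budding cycle
#'
#' `F = f * p`: the probability that a marked stem cell is lost to follicle
#' cell differentiation in one budding cycle, where `f` is the fraction of
#' marked stem cells in layer 1 and `p` the per-cycle probability that a
#' layer-1 cell becomes an FC. The wild-type baseline is
#' `F = 0.48 * 0.64 = 0.307`; `delta_F` is the deviation from that baseline.
#'
#' @param f Fraction of stem cells in layer 1, in `[0, 1]`.
#' @param p Per-cycle layer-1 to FC conversion probability, in `[0, 1]`.
#' @param baseline Wild-type `F` (overridable; default 0.307).
#' @return A list with `f`, `p`, `F`, `delta_F` and `percent_change` (of `F`
#'   relative to baseline).
#' @examples
#' conversion_loss(0.48, 0.64)$F  # 0.307
#' @export
conversion_loss <- function(f, p, baseline = 0.307) {
  check_scalar_number(f, "f", 0)
  check_scalar_number(p, "p", 0)
  if (f > 1 || p > 1) stop_invalid("`f` and `p` must be in [0, 1]")
  F_ <- f * p
  list(
    f = f, p = p, F = F_, delta_F = F_ - baseline,
    percent_change = 100 * (F_ - baseline) / baseline
  )
}

#' Per-layer production vs differentiation flux report
#'
#' Balances each layer's cell production (from its cycle time) against its
#' differentiation output: layer 1 feeds FC production (`fc_per_cycle`),
#' layers 2-3 jointly feed EC production at `ec_to_fc_ratio` times the FC
#' output. The residual per layer is the net anterior-posterior flux (positive
#' = surplus available to flow out or grow the pool). Layer-3 production is
#' reported but excluded from the layer-2 sufficiency balance, since layer-3
#' cells divide much more slowly. By construction production = consumption +
#' net flux in every row.
#'
#' @param cycle_times_min Named numeric vector of cycle times in minutes for
#'   layers `"1"`, `"2"` and optionally `"3"`, or a named list of
#'   [cell_cycle_estimate()] objects.
#' @param params A [tissue_params()].
#' @return An object of class `flux_report`: a tibble with `layer`,
#'   `n_cells`, `cycle_time_min`, `production`, `consumption`, `net_flux`
#'   (cells per budding period), with totals in attributes
#'   `total_production` and `total_consumption`.
#' @examples
#' flux_report(c("1" = 943, "2" = 3223))
#' @export
flux_report <- function(cycle_times_min, params = tissue_params()) {
  if (!inherits(params, "tissue_params")) {
    stop_invalid("`params` must be a `tissue_params` object")
  }
  if (is.list(cycle_times_min)) {
    cycle_times_min <- vapply(cycle_times_min, function(x) {
      if (inherits(x, "cell_cycle_estimate")) x$total_min else as.numeric(x)
    }, numeric(1))
  }
  layers <- names(cycle_times_min)
  if (is.null(layers) || !all(layers %in% c("1", "2", "3")) ||
      length(layers) < 2L) {
    stop_invalid("`cycle_times_min` must be named with >= 2 of layers \"1\", \"2\", \"3\"")
  }
  n_cells <- params$cells_per_layer[layers]
  production <- mapply(production_rate, n_cells, cycle_times_min,
                       MoreArgs = list(period_min = params$budding_period_min))
  ec_output <- params$ec_to_fc_ratio * params$fc_per_cycle
  consumption <- vapply(layers, function(l) {
    switch(l, "1" = params$fc_per_cycle, "2" = ec_output, "3" = 0)
  }, numeric(1))
  out <- tibble::tibble(
    layer = layers,
    n_cells = unname(n_cells),
    cycle_time_min = unname(cycle_times_min),
    production = unname(production),
    consumption = unname(consumption),
    net_flux = unname(production - consumption)
  )
  structure(out,
            class = c("flux_report", class(out)),
            total_production = sum(production),
            total_consumption = sum(consumption),
            period_min = params$budding_period_min)
}

#' @export
print.flux_report <- function(x, ...) {
  cat(sprintf("Flux balance per %g-min budding period (cells/period):\n",
              attr(x, "period_min")))
  df <- as.data.frame(x)
  df$production <- round(df$production, 1)
  df$consumption <- round(df$consumption, 1)
  df$net_flux <- round(df$net_flux, 1)
  print(df, row.names = FALSE)
  cat(sprintf("total production %.1f, total consumption %.1f\n",
              attr(x, "total_production"), attr(x, "total_consumption")))
  invisible(x)
}
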