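# Shared fixtures and independent oracles, all built in code.

wt_durations <- function(cv = 0) phase_durations(81, 318, 527, 17, cv = cv)

# Hand-build a single-cell frame table from state strings:
# "G1" = GFP-only, "S-" = colorless, "S+" = RFP-only, "G2" = GFP+RFP,
# "M" = GFP+RFP with the mitotic flag.
make_track <- function(states, cell_id = "c1", germarium_id = "g1",
                       layer = "1", dt = 20) {
  gfp <- states %in% c("G1", "G2", "M")
  rfp <- states %in% c("S+", "G2", "M")
  tibble::tibble(
    cell_id = cell_id, germarium_id = germarium_id, layer = layer,
    time_min = dt * (seq_along(states) - 1),
    gfp = gfp, rfp = rfp, mitotic = states == "M"
  )
}

# Independent frame-walking recount of dwell time and exits for one phase.
# Deliberately a naive per-frame loop, sharing no code with the package's
# interval aggregation.
naive_dwell <- function(tracks, phase) {
  nxt <- c(G1 = "S", S = "G2", G2 = "M", M = "G1")
  total <- 0
  exits <- 0L
  for (cid in unique(tracks$cell_id)) {
    tr <- tracks[tracks$cell_id == cid, ]
    tr <- tr[order(tr$time_min), ]
    lab <- ifelse(tr$mitotic, "M",
                  ifelse(tr$gfp & !tr$rfp, "G1",
                         ifelse(tr$gfp & tr$rfp, "G2", "S")))
    n <- nrow(tr)
    ok <- TRUE
    for (i in seq_len(max(0, n - 1))) {
      if (lab[i + 1] != lab[i] && nxt[[lab[i]]] != lab[i + 1]) ok <- FALSE
    }
    if (!ok) next
    since <- if (lab[1] == phase) tr$time_min[1] else NA_real_
    for (i in seq_len(max(0, n - 1))) {
      if (lab[i + 1] != lab[i]) {
        mid <- (tr$time_min[i] + tr$time_min[i + 1]) / 2
        if (lab[i] == phase) {
          total <- total + (mid - since)
          exits <- exits + 1L
          since <- NA_real_
        }
        if (lab[i + 1] == phase) since <- mid
      }
    }
    if (!is.na(since)) total <- total + tr$time_min[n] - since
  }
  list(total = total, exits = exits)
}
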