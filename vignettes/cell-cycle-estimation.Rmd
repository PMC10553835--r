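---
title: "Estimating cell-cycle phase durations from partial FUCCI tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-cycle phase durations from partial FUCCI tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germcycle)
```

## The problem

Follicle stem cells (FSCs) of the *Drosophila* germarium sit in three
anterior-posterior rings ("layers" 1-3) between escort cells (ECs) anteriorly
and follicle cells (FCs) posteriorly. How fast FSCs divide, and how division
rate is patterned across layers, determines whether stem-cell gains and
losses balance. S-phase labeling indices (EdU) cannot answer this on their
own: an EdU index is the product of entry frequency and S-phase *length*, and
nothing guarantees S-phase length is constant across locations or genotypes.

`germcycle` implements a pipeline for measuring absolute phase durations
with FUCCI cell-cycle reporters: a GFP fusion degraded in S phase and an RFP
fusion degraded at mitosis and through G1. The joint color state encodes
phase — GFP-only is G1, GFP+RFP is G2 (or M, recognized morphologically),
RFP-only is late S, and colorless cells are early S, countable by DAPI or
EdU. Because germaria can only be imaged live for short windows (~2.5 h)
while cycles last ~16-54 h, no cell is ever observed through a full cycle;
the estimator must work from partial observations.

## The dwell/exit estimator

A cell observed at the start of an imaging window was captured at an
arbitrary time within its current phase. For an asynchronous population in
steady state, the mean duration of a phase can be estimated by

\[
\hat{T}_{\text{phase}} \;=\;
\frac{\sum_{\text{cells}} \text{observed minutes in phase}}
     {\#\{\text{observed transitions out of the phase}\}} .
\]

This is an occupancy / exit-rate identity (Little's law for the renewal
process of cycling cells): with observation time \(W\) per cell, the expected
total dwell time is (occupancy) \(\times W\) and the expected number of exits
is (flux) \(\times W\); their ratio is the mean dwell time. Three kinds of
interval all contribute time:

* cells already in the phase at the window start (censored entry);
* cells entering the phase during the window (observed entry);
* intervals cut short by the window end or by a cell leaving the imaged
  z-range (censored exit — time counted, no exit counted).

Dropping the *entering* cells is the classic mistake: their mostly censored
dwell time is discarded while early exits are kept, and the estimate
collapses toward the mean *residual* time (about half the true duration for
a short phase). `summarize_tracks(include_entering = FALSE)` exists only to
demonstrate this bias, and the test suite asserts it.

S-phase entries and exits are rarely observable (most S-phase cells are
colorless), so S is inferred from the fixed-snapshot S fraction \(f_S\):

\[
T_S = (T_{G1} + T_{G2} + T_M)\,\frac{f_S}{1 - f_S},
\]

with \(f_S\) pooled across germaria weighted by cell counts.

```{r}
g2 <- estimate_phase_duration(phase_dwell_summary("G2", 8432, 16, 92))
g1 <- estimate_phase_duration(phase_dwell_summary("G1", 1621, 20, 92))
g2
infer_s_duration(81, 527, 17, s_fraction = 0.337)
```

## Interval construction from frames

`classify_track()` labels each frame (mitotic flag beats colors, otherwise
GFP-only → G1, GFP+RFP → G2, anything GFP-negative → S) and places each
transition at the midpoint between the two bounding frames — unbiased when
the true transition time is uniform within a frame gap, which holds for
sampling unsynchronized with the cycle. First and last frames bound censored
intervals. Label sequences violating the cyclic order G1→S→G2→M→G1 mark the
track ambiguous, and ambiguous tracks are excluded with a logged reason; a
track starting colorless is taken to be in S (the dominant case) and
flagged. Whether dwell time should run to the transition frame instead of
the midpoint is not observable from the data; the midpoint is the default
because it is the unbiased choice, and published pooled totals enter the
estimator directly through `phase_dwell_summary()` regardless of convention.

Two filters deserve note:

* **Inert germaria.** `summarize_tracks()` by default drops germaria with no
  observed G1 or G2 exits, mirroring live-imaging practice where such
  germaria also show minimal cell movement and are judged unhealthy. This is
  a *data-quality* exclusion, and it selects toward active germaria: applied
  to small, perfectly healthy simulated germaria (~6 cells) it removes
  exactly those whose cells happened to dwell without exiting and biases G2
  down by ~25%. The estimator-consistency tests therefore disable it —
  simulated germaria are all healthy — while real-data analyses keep it on.
* **Ambiguous tracks** are excluded whole rather than salvaged piecewise, to
  keep the accounting auditable.

## The synthetic-data generator

Because the raw microscopy is not redistributable, every stage is exercised
against a seeded simulator:

* `simulate_population()` draws the length-biased steady state: each cell's
  phase with probability proportional to its phase duration, and elapsed
  time within the phase uniform. Per-cell variability is modeled as
  independent gamma draws per phase with a shared coefficient of variation
  (`cv`; default 0 reproduces deterministic worked examples — no dispersion
  estimate exists to calibrate against, so `cv` is a simulation knob, not a
  fitted quantity).
* `simulate_imaging()` samples frames on a fixed grid (defaults: 150-min
  window, 20-min interval, matching the live protocol's averages of 148 and
  ~20 min), applies reporter lags (RFP detectable only 114 min after S
  entry, the observed average colorless period; GFP immediately at S exit),
  flags mitosis in a single frame as morphology does, and right-censors
  tracks by permanent dropout.
* Divisions produce two G1 daughters. The imaged lineage continues under the
  parent `cell_id` through mitosis, and the second daughter starts a new
  track *at the shared mitotic frame*. Anchoring both daughters at the
  observed mitosis matters: starting daughter tracks at the next grid frame
  silently discards ~half a frame interval of G1 per daughter (~10 of 81
  min) and biases G1 low.
* `daughter_retention_prob` (default 0.5) is the probability that each
  daughter stays in the monitored pool. The default encodes homeostasis:
  differentiation consumes on average one daughter per division, keeping the
  imaged population stationary. With both daughters always retained the pool
  grows ~11% per 150-min window, G1 occupancy transiently doubles its
  inflow, and the G1 estimate converges to ~96 min instead of 81 — a
  property of the *population dynamics*, not an estimator defect. Set the
  parameter to 1 to reproduce watching both daughters of a division.
* `simulate_snapshot()` fixes the population after a 1-h EdU pulse; a cell
  is EdU-positive iff the pulse overlapped S-phase, including S time in the
  previous cycle for recently divided cells. This makes the EdU index
  systematically exceed the instantaneous S fraction by ~pulse/cycle, which
  is exactly why the package reports both.
* `simulate_dilution()` halves a stable H2B-RFP label per division with
  optional lognormal noise (mean 1).

One RNG stream is derived per germarium, so enlarging an experiment never
perturbs germaria already generated. What the simulator does *not* emulate:
spatial geometry, layer exchange during imaging, segmentation error, or
signaling mechanisms — passing tests show the statistics are right under the
generative assumptions, not that image analysis upstream is error-free.

## Problem sizes and numerical choices

The consistency checks run 10,000 cells through 150-min windows (~1,450 G2
exits, giving ~2.5% standard error against a 10% acceptance band); oracle
and coverage tests use 150-600 cells. Bootstrap intervals resample germaria
(the independent unit) with replacement; resamples with zero exits are
recorded and skipped. Degenerate inputs fail loudly: zero exits, non-cyclic
label sequences, fractions outside \([0,1)\), germaria without layer-3
reference cells, and schema violations all raise errors or logged
exclusions rather than silent coercion.

Reporting conventions follow the source style — durations to the nearest
minute, ratios to one decimal, percentages to the integer — while unrounded
values are always retained in results JSON (`write_results()`).

## Snapshot scoring and statistics

`fraction_table()` gives per-location phase fractions with binomial standard
errors. Two-proportion comparisons use the "N-1" chi-squared test
(`n1_chisq()`): the classical Pearson statistic scaled by \((N-1)/N\),
recommended for small samples. EdU indices are normalized between
experiments by the layer-1 control ratio (`normalize_edu()`; EC indices are
never normalized). `expected_edu_distribution()` redistributes a genotype's
weighted-average index across layers in proportion to the control pattern;
the published description of this construction is ambiguous about scaling,
so both readings are implemented — the default rescales so the weighted mean
is preserved, the only reading in which a genotype identical to control
yields expected = observed and \(\chi^2 = 0\).

## Tissue calculus and dilution

`production_rate()` (cells × period / cycle time), `required_cycle_time()`
(its exact inverse), `required_cycle_ratio()`, `conversion_loss()`
(\(F = f \times p\), wild-type baseline 0.307) and `flux_report()` connect
cycle times to FC/EC output per 720-min budding cycle. Layer-3 production is
reported separately and excluded from the layer-2 sufficiency balance, since
layer-3 cells divide much more slowly.

```{r}
flux_report(c("1" = 943, "2" = 3223))
```

H2B-RFP dilution is normalized per germarium to layer-3 cells
(`normalize_to_layer3()`, idempotent), classified against per-layer
pre-chase baselines at a four-fold threshold (`fraction_below_threshold()`;
the published counts imply layer-specific starting points, so per-layer
baselines are the default with a global baseline available), and converted
to approximate division counts via `divisions_from_dilution()` =
log2(baseline/observed), clipped at zero. Division counts are labeled
approximate throughout: heterogeneous initial labeling systematically limits
quantitative inference from dilution.

## Known limitations

* The estimator is population-level by design; it does not fit per-cell
  cycle-length distributions.
* M-phase duration is near the frame interval, so its estimate is dominated
  by the midpoint convention (observed ~17 min at 20-min frames).
* The S inference assumes the snapshot and live cohorts share one \(f_S\).
* The inert-germarium filter and ambiguous-track exclusion both select
  toward active, cleanly labeled cells; their counts are logged so the
  selection is visible.
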