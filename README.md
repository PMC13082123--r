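# gliowave

Calcium co-activity network inference for glioma cell networks.

Glioma cells wire themselves into multicellular networks through tumour
microtubes and communicate across them with intercellular Ca²⁺ waves. Given
single-cell fluorescence traces (frames × cells, with a sampling rate) and a
table of ROI centroids (µm), `gliowave` reconstructs the functional
communication graph and the summary statistics used to compare conditions
(e.g. control vs gene-knockdown cultures): the percentage of communicating
cells, degree hubs, periodic (rhythmic) cells, and population calcium event
rates. A plate-scoring module covers triple-readout RNAi screens and simple
morphometric gates, and a synthetic-recording generator with known
ground-truth connectivity makes the whole pipeline testable end to end.

## The method in brief

For each cell, raw fluorescence is normalized to ΔF/F = (F − F₀)/F₀ with F₀
a 20th-percentile baseline, and calcium peaks are detected as
prominence-gated local maxima (≥ 3σ̂ of the frame noise, ≥ 1 s apart). Cells
with ≥ 4 peaks are *active*. For every pair of active cells the
connectivity strength is the maximum time-lagged Pearson correlation

  r = max over τ of corr(x(t), y(t + τ)),  τ ∈ [−25 s, +25 s],

computed on overlap segments per lag; the implied propagation speed is the
centroid distance divided by |τ*| at the maximum. Pairs are excluded when
d > 100 µm, when the speed falls outside 4–25 µm/s, or when either cell is
insufficiently active (< 4 peaks). Significance is assessed against a
linear-shift null: one trace of each pair is circularly time-shifted by a
random ΔT > 5 min, the lagged maximum recomputed, and all surrogate values
pooled; the 95th percentile of the pooled null is the edge threshold r₀.
Nodes are active cells, edges are significant passing pairs, communicating
cells have degree ≥ 1, hubs occupy the top 5% of the degree distribution,
and periodic cells have ≥ 4 peaks with inter-peak-interval CV ≤ 0.3.

See `vignettes/coactivity-networks.Rmd` for the full account, including the
null-model design, numerical conventions, the simulator's architecture and
its limitations.

## Worked example

Simulate a 10-min, 30-cell recording with 5 rhythmic pacemaker cells
driving 5 couplings, run the full analysis, and compare against the same
field with the pacemakers ablated:

```r
library(gliowave)

cfg <- sim_config(n_cells = 30, field_um = 300, n_sources = 5, n_edges = 5,
                  seed = 7)
field <- simulate_field(cfg)
report <- run_analyze(field$traces, field$rois, seed = 7,
                      truth = field$truth)
report
#> <run_report> 30 cells (15 active); 105 pairs (22 pass); r0 = 0.146; 5 edges; 66.7% communicating
report$truth_scoring$f1
#> [1] 1

ablated <- render_fluorescence(remove_sources(field$truth), cfg)
report0 <- run_analyze(ablated$traces, field$rois, seed = 7)
run_compare(report, report0)
#>                       metric    value_a     value_b        delta
#> 1          communicating_pct 66.6666667 40.00000000 -26.66666667
#> 2                     n_hubs 10.0000000  2.00000000  -8.00000000
#> 3                 n_periodic  7.0000000  0.00000000  -7.00000000
#> 4 event_rate_per_min_per_100 80.6666667 16.33333333 -64.33333333
#> 5                    n_edges  5.0000000  1.00000000  -4.00000000
#> 6               threshold_r0  0.1459507  0.06399004  -0.08196071
```

Reading the numbers: 15 of 30 cells pass the 4-peak activity gate; of their
105 pairs, 22 survive the distance/speed/activity gates; the pooled
surrogate null puts the significance threshold at r₀ = 0.146, and the 5
resulting edges recover the simulated coupling graph exactly (F1 = 1).
Deleting the rhythmic sources collapses communication: the communicating
percentage drops by 27 points, and hubs and periodic cells disappear —
the computational signature of removing the pacemaker subpopulation.

`run_analyze(..., out_dir = "out")` additionally writes every intermediate
table (`activity.csv`, `peaks.csv`, `pairs.csv`, `null.json`, `edges.csv`,
`nodes.csv`, `report.json`); identical inputs and seed reproduce the files
byte for byte.

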