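---
title: "Inferring glioma communication networks from calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring glioma communication networks from calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliowave)
```

## The problem

Glioma cells connect to one another (and to neurons) through tumour
microtubes — ultralong, neurite-like protrusions — and communicate across
those connections with intercellular Ca²⁺ waves. In a calcium-imaging
recording of such a culture or slice, that communication is visible as
co-activity: when one cell fires, coupled neighbours fire a short,
distance-dependent delay later. `gliowave` turns a frames × cells
fluorescence matrix plus a table of cell centroids into an undirected
*functional network* whose edges are statistically significant, physiologically
plausible co-activations, and summarizes that network with the metrics used
to compare conditions: the percentage of communicating cells, degree hubs,
and periodic (rhythmic) cells.

## The statistical procedure

**Normalization.** Each cell's raw trace is converted to
$\Delta F/F = (F - F_0)/F_0$. The basal fluorescence $F_0$ is the 20th
percentile of the trace (a rolling 30 s percentile is available for
drifting baselines). The percentile is evaluated on a running-median
smoothed copy of the trace (1 s window): a low percentile of an
*unsmoothed* noisy baseline is systematically biased low by frame noise,
which would inflate every subsequent amplitude by the same factor.
$\Delta F/F$ itself is always computed from the unsmoothed trace. Cells
with non-positive $F_0$ (dead pixels, empty ROIs) are flagged invalid and
excluded.

**Events and the activity gate.** Calcium peaks are prominence-gated local
maxima of $\Delta F/F$: a peak must rise at least $k\hat\sigma$ (default
$k = 3$) above its surrounding valleys, with
$\hat\sigma = 1.4826\,\mathrm{MAD}(\mathrm{diff}(\Delta F/F))/\sqrt{2}$ —
a robust estimate of the frame-noise scale that slow transients do not
contaminate. Maxima are located on a lightly smoothed copy (0.25 s moving
average, shorter than a transient); without this, the extremes of tens of
thousands of noise frames reliably masquerade as events no matter how the
threshold is phrased in $\hat\sigma$ units. Peaks closer than 1 s are
merged (most prominent kept). Cells with **at least four peaks** per
recording are *active*; only active cells enter the network analysis.

**Connectivity strength.** For every unordered pair of active cells the
package computes the time-lagged Pearson correlation
$r_{xy}(\tau)$ for every integer frame lag $\tau \in [-\tau_{max},
+\tau_{max}]$, using only the overlapping samples at each lag, each lag
normalized by its own overlap means and variances (zero-padding would bias
$r$ toward zero at long lags). The pair's connectivity strength is
$r = \max_\tau r_{xy}(\tau)$ and $\tau^*$ is the lag at the maximum; exact
ties go to the smallest $|\tau|$, then to the negative lag. The default lag
window is derived from the physiological gates below:
$\tau_{max} = d_{max}/v_{min} = 25$ s, the smallest window that cannot miss
an admissible propagation delay.

**Physiological gating.** Pairs are excluded, in this order, when

1. *distance*: centroid distance $d > 100$ µm;
2. *speed*: the implied propagation velocity $v = d/|\tau^*|$ lies outside
   the closed window $[4, 25]$ µm/s. A zero-lag pair has no finite
   velocity; it is treated as "faster than measurable" and excluded unless
   the window is unbounded above (see the synchrony preset below);
3. *inactivity*: either cell has fewer than four peaks. (Pairs whose
   correlation is undefined at every lag — constant traces — are also
   classed here: no lag or speed exists for them.)

**Significance.** The null model preserves each trace's autocorrelation
while destroying coupling: one trace of each gate-passing pair is
time-shifted by a random offset $\Delta T$ drawn uniformly above 5 min
(per pair, per surrogate), the lagged maximum is recomputed on the same lag
grid, and all surrogate $r$ values are pooled. The significance threshold
$r_0$ is the 95th percentile of this pooled null; an edge requires
$r \ge r_0$. The shift wraps circularly. A strictly non-wrapping shift with
a ≥ 5 min offset would discard more than half of a 10-min recording, and
rotation is the standard surrogate that preserves the autocorrelation
structure exactly (a truncating variant is available via
`shift_mode = "truncate"` for comparison). On synthetic recordings matched
to typical cultured-GSC signal-to-noise, $r_0$ lands in the 0.1–0.2 range;
it is a data-dependent quantity, not a constant of the method.

**Network metrics.** Nodes are all active cells (isolates included); edges
are significant gate-passing pairs. *Communicating cells* have degree ≥ 1,
reported as a percentage of active cells. *Hubs* are nodes in the top 5% of
the degree distribution (interpolated percentile, ties at the cutoff
included, isolates never hubs — note that in a sparse graph with many tied
degrees the hub set can exceed 5% of nodes; that is a property of the
rule, reported as-is). *Periodic cells* have ≥ 4 peaks and an
inter-peak-interval coefficient of variation ≤ 0.3. The CV uses the
population (n) standard deviation — with, say, intervals of 5, 50, 5, 50 s
this gives CV ≈ 0.82, clearly arrhythmic, and makes the small-sample CV
less noisy than the n−1 convention. An autocorrelation-based rhythmicity
test was considered and rejected: it needs a dominant-period estimate and
behaves erratically for trains of 4–6 events, exactly the regime the
4-peak gate admits.

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `baseline_q` | 0.2 | — | percentile defining $F_0$ |
| `peak_k` | 3 | × $\hat\sigma$ | peak prominence threshold |
| `peak_min_separation_s` | 1 | s | event refractory interval |
| `active_min_peaks` | 4 | peaks | activity gate |
| `d_max_um` | 100 | µm | pair distance gate |
| `v_min_um_s`, `v_max_um_s` | 4, 25 | µm/s | propagation-speed window |
| `max_lag_s` | derived | s | lag window ($d_{max}/v_{min}$) |
| `dt_min_s` | 300 | s | minimum surrogate shift |
| `n_surrogates` | 20 | per pair | null-model draws |
| `percentile` | 95 | — | null percentile for $r_0$ |
| `hub_top_frac` | 0.05 | — | hub degree fraction |
| `periodic_cv_max` | 0.3 | — | rhythmicity CV bound |

An alternative edge definition treats events co-occurring within 1 s as
connected, without a velocity window. This conflicts with the velocity
gating above (at 100 µm, 4–25 µm/s implies 4–25 s delays, not ≤ 1 s), so it
is exposed explicitly as `analysis_config(preset = "synchrony_1s")` — which
sets `max_lag_s = 1` and removes the speed bounds — rather than silently
merged with the velocity rule.

## The synthetic recording generator

Because raw recordings of this kind are rarely shareable, every stage is
validated against `simulate_field()`, which emulates the target recording
geometry: 10 min at 40 Hz, ~50 cells with ≥ 10 µm centroid separation in a
400 µm field. Its architecture mirrors the hierarchy the analysis is
designed to detect:

* **sources** — `n_sources` pacemaker cells with quasi-periodic trains
  (nominal period 30 s; each source draws its intrinsic period within
  ±20% of nominal so unrelated pacemakers are not artificially
  phase-locked; inter-event jitter 5% of the period, which places the CV
  rule near its decision boundary);
* **couplings** — `n_edges` source→follower edges wired round-robin across
  sources among pairs ≤ 100 µm apart (each pacemaker acquires its own
  follower before any acquires a second — a hub-and-spoke motif that also
  keeps follower trains conditionally independent), each with a propagation
  speed drawn in `[4, 25]` µm/s and delay = distance/speed; source events
  cross an edge with probability `edge_fidelity` (default 0.9, near-reliable
  propagation with occasional failure);
* **background** — every non-source cell receives an independent Poisson
  train at 0.2 events/min, so genuinely inactive cells (< 4 peaks in
  10 min) occur;
* **rendering** — each event adds a difference-of-exponentials transient
  (rise 0.05 s, decay 0.5 s, unit $\Delta F/F$ amplitude — fast-GCaMP-like
  kinetics) evaluated in continuous time on the frame grid; raw
  fluorescence is $F_0(1 + \Delta F/F)$ plus Gaussian frame noise of s.d.
  0.1 $F_0$ (SNR 10 for a unit transient) and an optional linear bleach.

`remove_sources()` deletes the pacemaker trains and everything they
propagate, leaving only background — the computational analogue of ablating
the rhythmic-hub subpopulation. Communication collapses: across seeds the
communicating-cell percentage falls from ~75–85% to ~0%.

The generator is deliberately idealized. It does **not** emulate motion
artifacts, bleaching nonlinearity, overlapping ROIs, bursting or
facilitation, inhibitory interactions, or non-Gaussian noise. Passing
tests therefore demonstrate that the *statistics* behave as specified under
controlled conditions, not that any particular biological recording will be
segmented or normalized perfectly.

## Numerical choices

* Every percentile in the package (baseline, null threshold, hub cutoff)
  uses the same linear-interpolation definition (R's type 7).
* The per-lag correlations are computed via FFT cross-products plus prefix
  sums, algebraically identical to a per-lag Pearson loop over overlap
  segments; tests pin agreement with a naive `cor()` loop to 10⁻¹⁰ at full
  recording scale (24 000 frames, ±1000 lags).
* A lag whose overlap segment has (numerically) zero variance is undefined
  and skipped; a pair undefined at every lag is excluded as inactive.
* Shifting both traces of a pair by the same offset leaves the correlation
  *exactly* unchanged at lag 0 (the same sample pairs, reordered); at lag
  $\tau$, the $\le|\tau|$ pairs straddling the wrap point change, an
  $O(\tau_{max}/n)$ perturbation — negligible at 24 000 frames.
* With only ~20 surrogates per pair, a *per-pair* 95th percentile is noisy;
  the pipeline therefore pools surrogates across pairs into one global
  threshold (a per-pair threshold remains possible by thresholding each
  pair against its own draws). Pooled over ≥ 400 pair-tests, the realized
  false-positive edge rate sits at 5% ± 2 points.
* All randomness flows from one integer seed through named per-stage
  sub-seeds (`derive_seeds()`), so changing the number of surrogate draws
  never perturbs the simulator's stream; identical configuration + seed
  reproduces every output file byte for byte.
* Validation problem sizes: the oracle-equivalence check runs 100 pairs at
  full recording scale; null calibration pools 20 fields of 30 cells;
  network recovery uses 20 fields of 50 cells with 10 true couplings
  (median F1 ≥ 0.9, delays recovered to one frame on noiseless renders);
  the ablation contrast uses 10 paired fields of 40 cells.

## Screen scoring

The screen module scores triple-readout RNAi plates (nascent-protein
puncta, ATP intensity, tumour-microtube length) with
$z = (X - \mu)/\mathrm{s.d.}$, where $\mu$ is the mean of the
negative-control wells and s.d. is the sample (n−1) standard deviation of
the *whole plate population*, per plate and readout. Although such scores
are often called "robust Z-scores", this mean/sd form is the convention
implemented by default (`formula = "paper"`); a fully robust variant
(median of controls, MAD of population) is available as
`formula = "mad"`. Hits are ranked by the mean of the per-readout scores
(sign-aligned so loss-of-function is negative), ties broken by condition
name. The morphometric gate classifies a protrusion as a tumour microtube
iff length > 10 µm (strict) and calibre ∈ [0.5, 2.5] µm (closed); the EdU
proliferation index is 100 · EdU⁺/DAPI.

## Known limitations

* The linear-shift null is *conservative for strongly rhythmic pairs*: a
  rotation of a periodic trace resembles a phase shift, so surrogate
  maxima over a lag window spanning a full period stay elevated and the
  pooled threshold rises. This is intrinsic to the surrogate, not to the
  implementation; with heterogeneous source periods and 5% jitter the
  method still separates true couplings cleanly (observed edge r ≈ 0.8–1.0
  vs thresholds ≈ 0.15).
* Correlations are computed on $\Delta F/F$, not on deconvolved spike
  trains; there is no spike inference, and none is attempted.
* Velocity gating assigns each pair a single delay; a pair connected by
  multiple routes with different delays is summarized by its strongest lag
  only.
* Zero-lag synchrony is excluded by the velocity gate under the default
  preset (no finite speed exists for it); use `preset = "synchrony_1s"`
  when near-synchronous co-activation is the phenomenon of interest.
* Hub flags on sparse, heavily tied degree sequences can cover far more
  than 5% of nodes (ties at the cutoff are included by definition).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_cells = 30, field_um = 300, n_sources = 5, n_edges = 5,
                  seed = 7)
field <- simulate_field(cfg)
report <- run_analyze(field$traces, field$rois, seed = 7,
                      truth = field$truth)
report
report$truth_scoring$f1

ablated <- render_fluorescence(remove_sources(field$truth), cfg)
report0 <- run_analyze(ablated$traces, field$rois, seed = 7)
run_compare(report, report0)
```
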