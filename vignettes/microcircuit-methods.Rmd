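---
title: "Methods: microcircuit analysis of epileptiform MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microcircuit analysis of epileptiform MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meacircuit)
```

## The scientific problem

High-density CMOS microelectrode arrays record extracellular voltage from
hundreds of spike-sorted neurons and roughly a thousand electrodes at once.
In hippocampal slices that develop seizure-like activity under low-magnesium
media with kainic acid, the population shows a characteristic progression:
a quiet **baseline**, an **initiation** burst in which theta-band (4–8 Hz)
oscillations emerge and the granule cell layer splits into two alternating
activity modes, and a **seizure** stage of recurring bursts. `meacircuit`
implements the analysis chain that turns such a recording into a functional
microcircuit description: burst staging, theta-wave spatial dynamics,
spike–theta phase locking, spike time tiling coefficient (STTC) clustering,
and — the headline output — a directed pairwise-correlation circuit diagram
with a significance test of its geometry.

All analyses are exercised end-to-end on synthetic recordings with planted
ground truth, so every recovery claim in the test suite is checked against a
known construction rather than against the analyses themselves.

## The circuit-inference protocol

For a unit pair \((n_1, n_2)\), every spike of the reference unit is matched
to the nearest spike of the other unit by absolute time difference; signed
differences within \(\pm 30\) ms form the pair's **latency distribution**
(30 ms reflects polysynaptic transmission timescales, not monosynaptic
coupling). The screening and filtering chain is:

1. consider only pairs with STTC \(> 0.01\) (computation-saving screen);
2. discard distributions with fewer than 25 events or absolute mean latency
   below 1 ms;
3. two-tailed one-sample t-test of the mean latency against zero; keep
   pairs with \(p < 0.05\) (raw p-values by default; Benjamini–Hochberg is
   available behind `p_adjust = "BH"`).

A significant pair becomes a **propagation vector** from the earlier-firing
unit toward the later one, weighted by its event count; its angle is the
direction from source to target position (x rightward, y upward, radians
counterclockwise from +x). Latency distributions are computed once per
unordered pair with the lower unit id as reference; reversing the roles
flips every latency's sign and therefore the inferred direction, so the
procedure is order-invariant. Equidistant nearest spikes keep the negative
(earlier) latency, deterministically.

Per-source arrows are aggregated by the event-weighted circular mean, and
aggregates whose weighted circular standard deviation reaches 0.5 rad are
dropped — averaging opposed arrows would fabricate a direction representative
of neither. The propagation-angle histogram (24 bins of 15°, config-exposed)
is computed over **all** significant pairs, weighted by events. A report
classification operationalizes the qualitative circuit classes by mass in
the two dominant opposed 30° sectors: *bipolar* if both hold ≥ 25 % of the
mass with modes 180° ± 30° apart, *unimodal* if one holds ≥ 40 %, otherwise
*diffuse*. Fewer than 10 significant pairs is always *diffuse* ("no coherent
circuit"): a handful of arrows is not a circuit, whatever their angles.

### Geometry-bias test

To check that a bipolar angle histogram is not an artifact of where the
neurons sit, the cell layer is approximated by a degree-2 polynomial fitted
to all unit positions; each pair's **source** unit (config-exposed) is
projected to its nearest curve point and assigned a normalized arc-length
position in \([0, 1]\) (arc length rather than raw x, so strongly curved
layers are handled). Pairs split by the sign of their propagation angle,
and the two groups' positions are compared with a two-tailed two-sample
t-test. A genuinely reciprocal circuit gives a vastly smaller p-value than
layouts where position does not determine direction.

One caveat discovered while calibrating the test: on a fully two-dimensional
null layout (units uniform on a disk), deriving each pair's direction from
the pair chord is **not** a clean null — the chord's vertical component
correlates with the source's position after curve projection, inflating the
type-I error to ~0.10–0.13. The test's null calibration
(`geometry_null_calibration()`) therefore assigns propagation angles
uniformly at random, independent of position, which is exactly the
hypothesis the test addresses; under that construction the empirical
rejection rate at \(\alpha = 0.05\) is ~0.05. The practical reading: the
test presumes a quasi-one-dimensional cell layer (as in hippocampal slices),
and its p-values on genuinely 2-D layouts should be interpreted cautiously.

## STTC and its clustering

The spike time tiling coefficient for trains A and B is
\[
\mathrm{STTC} = \tfrac12\!\left(\frac{P_A - T_B}{1 - P_A T_B} +
\frac{P_B - T_A}{1 - P_B T_A}\right),
\]
with \(T_A\) the fraction of the recording covered by the merged
\(\pm\Delta t\) windows around A's spikes and \(P_A\) the fraction of A's
spikes with a B spike in their window. \(\Delta t\) is not part of the
measure's definition; the default is 20 ms (common practice, and matching
the ±30 ms latency scale), always reported alongside results. Empty trains
return 0 with a flag; a degenerate denominator (\(PT = 1\)) contributes 0.
The implementation is verified against an independent brute-force
window-merge evaluator to \(10^{-12}\) on hundreds of random train pairs.

For clustering, off-diagonal values are capped at 0.3 (the measure's heavy
right tail otherwise dominates the distances; a percentile-based cap is
available via `cap_quantile`), Euclidean distances between matrix rows feed
average-linkage agglomerative clustering (linkage config-exposed), the tree
is reordered by an exact Bar-Joseph optimal-leaf-ordering dynamic program
(verified against exhaustive enumeration of all \(2^{n-1}\)
dendrogram-consistent orderings at small n), and the tree is cut at k = 2.
A second, independent view is the eigendecomposition of the (positive
semidefinite) STTC matrix: the top two eigenvectors are reported with a
deterministic sign fix, because whether the block-separating vector is the
first or the second depends on whether the leading one is a near-constant
Perron vector.

## Theta-band analyses

* **Filtering.** Fourth-order Butterworth band-passes are applied forward
  and backward (zero phase): wave-timing analyses cannot tolerate group
  delay. Raw 20 kHz traces are decimated to 1 kHz behind a 400 Hz low-pass.
* **Spectrogram.** Complex Morlet CWT (unit bandwidth/centre frequency) on
  60 log-spaced frequencies over 0.5–50 Hz (~10 voices/octave, covering the
  delta/theta/alpha/beta/gamma sub-bands), power = squared magnitude,
  Gaussian-smoothed (σ = 2 bins). Wavelets are L2-normalized per scale so
  white noise is flat across frequency.
* **Theta frames.** Each electrode's theta-filtered trace is normalized to
  \([-1, 1]\) by its own maximum absolute value over the analysis window
  (all-zero electrodes stay zero), sampled every 5 ms. Normalization is per
  analysis window and exposed as an option, since whole-recording
  normalization is equally defensible.
* **Electrode lag clustering.** For each electrode pair the delay within
  ±40 ms that maximizes the cross-correlation (Pearson-style: globally
  mean-centred, variance-scaled, overlap-normalized — so amplitude
  differences don't dominate) defines a lag matrix; k-means with k = 2 and
  10 restarts on its rows clusters electrodes by wavefront timing.

Two deliberate choices here deserve emphasis. First, `lag_matrix()` offers
`method = "abs"` (maximize \(|r|\); the default) and `method = "signed"`.
For an exactly antiphase electrode pair — a standing wave's two halves —
\(|r|\) peaks at lag 0 just as it does for an in-phase pair, so under the
absolute rule the lag matrix of a standing wave is identically ~0 and
carries no spatial information. The stage-level wrapper
(`theta_lag_clusters()`) therefore maximizes the signed correlation, which
pushes antiphase pairs to the window edge and makes the two halves
separable; the absolute rule remains the default at the op level (it is the
natural choice for traveling delays, e.g. a 6 Hz sine delayed beyond the
window aliases to the −33 ms antiphase peak). Second,
`cluster_electrodes()` clusters on \(|{\rm lag}|\) rows by default: for
oscillatory signals the two window-edge maximizers are near-ties whose sign
is noise-dominated, while the magnitude carries the timing offset.

## Phase locking

The analytic signal of the theta-filtered reference trace (FFT Hilbert
transform) yields instantaneous phase and envelope. Spikes are kept only
while the envelope exceeds the RMS of the whole theta trace — i.e. during
genuine theta epochs. The Rayleigh statistic
\(R = \sqrt{(\sum\cos\sigma_i)^2 + (\sum\sin\sigma_i)^2}\) tests
non-uniformity with the standard approximation
\(p \approx \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))\), which agrees
with a direct Monte-Carlo null within ±0.01 across the sample sizes that
arise here. Each unit is referenced to its nearest electrode by default
(config-exposed; a fixed reference electrode is the alternative), and the
analysis is run separately per stage.

For the spatial map, the polar mode is the centre of the fullest 10° bin of
significant units' mean phases (bin width config-exposed); per-unit values
are wrapped absolute differences from the mode in \([0, \pi]\), gridded and
smoothed with σ = 70 µm. Units split at π/2 — the natural bipolar
separator — and the two clusters' phase distributions are compared with a
two-sample Kuiper test (asymptotic series with the Stephens correction on
the effective sample size; an exact permutation branch is used when the
smaller sample has ≤ 50 units).

## Spatial heatmaps and staging

Firing and phase heatmaps use a 30 × 30 grid anchored to the bounding box
of unit positions (~58 µm cells on a standard array), per-cell means, and
NA-aware Gaussian smoothing whose weights are renormalized over occupied
cells. A consequence worth knowing: an isolated occupied cell adopts the
value of its nearest occupied neighbour rather than decaying toward zero,
so smoothed maxima are pinned only to within about two smoothing SDs on
very sparse maps.

The population rate is spikes per 1 ms bin, Gaussian-smoothed (σ = 15 ms;
the conventional range is 10–20 ms), divided by the neuron count and scaled
to Hz. Burst detection — which the source protocol leaves qualitative — is
made explicit: a burst is a region where the rate exceeds mean + 2 SD of
the pre-burst segment, with the pre-burst segment and threshold found by
fixed-point iteration (the pre-segment never shrinks below 1 s so an early
noise excursion cannot collapse the noise estimate). Supra-threshold runs
shorter than 20 ms (the smoothing scale) are treated as noise; gaps up to
60 ms are absorbed, bridging the dips between theta-paced sub-bursts half a
period apart; and the duration criterion (≥ 200 ms) applies to
supra-threshold *occupancy*, not merged span, so strings of noise blips
cannot qualify. Baseline is everything before the first burst, initiation
is the first burst, seizure is everything after. Sub-bursts are local
extrema of the smoothed rate within initiation with prominence ≥ 25 % of
the initiation peak. The rate-based criterion stands in for the qualitative
"theta amplitude exceeds background" boundary and all of its constants are
config-exposed.

## The synthetic generator

`generate_recording()` builds recordings that emulate the epileptiform
phenotype with known ground truth:

* **Geometry.** ~80 units along a curved cell layer
  \(y = 5\times10^{-4}x^2 + 0.35x\) over 560 µm (a 32-electrode span at
  17.5 µm pitch), split into two groups on the two arc halves
  (`bipolar_arc`), one population with a left-to-right activation sweep
  (`unimodal_arc`), or a structureless uniform disk (the null). The sloped
  arc matters for the geometry test: rightward propagation has positive
  angles and leftward propagation negative ones, as in a curved granule
  cell layer.
* **Spiking.** 2 Hz Poisson background (paused inside burst epochs, where
  the sub-burst process drives the population); eight ~1.3 s bursts, each a
  train of 16 sub-bursts at 6 Hz in which the two groups alternate Gaussian
  rate bumps (σ = 15 ms) half a theta period apart — 8 bumps per group per
  burst, consistent with the 6–8 within-epoch bursts seen in epileptiform
  slices. A unit fires at most once per own-group bump (participation 0.9):
  granule cells at theta pace rarely spike twice within one 15 ms bump, and
  multi-spike bumps would blur the planted pair latency through cross-unit
  nearest-neighbour capture.
* **Planted circuit.** Units are paired across groups (mirror partners)
  with a fixed per-pair direction, half A→B and half B→A; the follower
  echoes each leader bump spike with probability 0.45 at
  +10 ms ± 2 ms jitter. This plants a recoverable ~10 ms directed latency
  per pair (the pooled within-burst nearest-spike latency mean lands within
  1 ms of the planted value) while keeping cross-group STTC low enough that
  group structure, not partner structure, dominates the clustering. The
  half-period group alternation produces the alternating two-mode sub-burst
  heatmaps; the echoes produce the reciprocal bipolar circuit.
* **LFP.** Electrode grid at 17.5 µm pitch clipped to the arc's bounding
  box (an optional stride trims it), synthesized at 1 kHz: a theta carrier
  whose envelope follows the burst schedule, with a phase gradient spanning
  2π along the arc (traveling mode) or a sign flip at the arc midpoint
  (standing mode), plus white noise. Phase-locked spike trains are drawn by
  thinning an inhomogeneous Poisson process whose intensity is a von Mises
  density of the instantaneous theta phase.

What the generator does *not* emulate: spike-sorting artifacts (bursty
false positives, waveform drift, split/merged units), realistic 1/f LFP
background, conduction-direction heterogeneity, or slice-to-slice
variability in layer shape. Passing the recovery tests therefore shows the
analysis chain is correct and well-calibrated under its stated model — not
that it is robust to the full messiness of patient tissue recordings.

## The dentate gyrus simulation

A deliberately minimal network probes the qualitative claim that increasing
granule-cell (GC) interconnectivity produces seizure-like bursting. Neurons
are adaptive leaky integrate-and-fire — the simplest model whose bursts
self-terminate through spike-triggered adaptation — with current-based
exponential synapses, 1–3 ms delays, Euler integration at 1 ms, and
independent Poisson drive per GC. GC→GC connections are drawn uniformly at
random over ordered pairs at the configured fraction; 40 inhibitory cells
receive GC input (p = 0.2) and inhibit all GCs. The default weights
(w_ee = 0.2, w_ei = 0.6, w_ie = 0.1 mV; adaptation b = 0.06 with
τ_w = 400 ms) were calibrated once so that the unconnected network fires
asynchronously (synchrony index < 0.05) while the half-connected network
produces recurring population bursts; the sweep over fractions
0–0.5 (5 seeds each, 15 s per run) yields a Spearman ρ(fraction, mean
synchrony) above 0.9. The synchrony index is the fraction of time the
smoothed GC population rate exceeds 3× its median; bursts are
supra-threshold runs ≥ 100 ms. A hard divergence guard aborts with a
diagnostic if the running mean rate passes 200 Hz. No attempt is made to
reproduce specific cell counts, conductances or topographic connectivity of
detailed dentate models — only the dose–response claim is in scope.

## Numerical and design notes

* Gaussian smoothing renormalizes kernels at edges (a constant series is a
  fixed point); 2-D smoothing is NA-aware as described above.
* Circular means with a numerically zero resultant are reported as an
  explicit undefined marker, never as an arbitrary angle.
* K-means and every other stochastic step take explicit seeds; the pipeline
  derives per-stage seeds from one master seed, and a rerun with identical
  configuration is byte-identical (outputs contain no timestamps).
* Footprint channels are ranked by peak-to-peak of the mean spike-aligned
  waveform ("maximum amplitude" made precise); 12 channels or all, if the
  array has fewer.
* The NWB/HDF5 readers go through a small bundled h5py bridge and read the
  plain HDF5 layout (units table with its ragged index, electrode table,
  first `ElectricalSeries`); electrode selection ("activity scan") is
  treated as given by the input file.
* Problem sizes in the test-suite and acceptance script (e.g. 120 s
  bipolar recordings with 2 × 40 units, 14 s LFP segments, 15 s simulation
  runs, 200-seed calibrations) were chosen as the smallest sizes at which
  the statistical contracts hold with comfortable margins.

## Known limitations

* The burst-staging criterion is a rate-based stand-in for a qualitative
  boundary; on recordings whose initiation has no rate signature it will
  disagree with expert labels.
* The geometry test's calibration presumes a quasi-1-D layer (see above).
* Latency-based direction is a functional statement, not a claim of
  monosynaptic connection; no cross-correlogram deconvolution is attempted.
* The Rayleigh p approximation is slightly anti-conservative for very small
  n; for n < 10 treat marginal significance with care.
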