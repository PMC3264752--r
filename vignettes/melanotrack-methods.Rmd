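---
title: "Methods: correlating organelle motility with membrane protein recruitment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating organelle motility with membrane protein recruitment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Peripheral membrane proteins such as Rab GTPases and their effectors are
recruited to organelle membranes and are thought to switch the organelle's
transport behaviour — for example from fast microtubule-dependent movement
to actin-dependent tethering. Testing that idea requires more than comparing
organelle speeds between mutant and wild-type cells: it requires measuring,
*within the same cell*, how much of the protein each organelle carries and
how that organelle moves, over thousands of movement episodes.

melanotrack implements that measurement pipeline for pigmented organelles
(melanosomes), which appear as dark particles in transmitted-light images
while the protein of interest is imaged in one or two fluorescence channels.
The pipeline's unit of analysis is the **movement event**: one frame-to-frame
displacement of one tracked organelle, carrying

* a speed $s_i = \lVert x_{t+1} - x_t \rVert / \Delta t$ (µm/s),
* a mean organelle-associated fluorescence intensity (**MMFI**) per channel,
* the organelle's apparent size (µm²), and
* optionally the MMFI ratio of two channels.

## Pipeline stages and their contracts

### Detection

Particles are defined on the transmitted channel by an intensity threshold
(dark-on-bright polarity by default; Otsu's method picks the threshold when
none is given) followed by a size/area filter on 8-connected components
(default 0.05–2 µm²). The centroid is the unweighted mask centroid, reported
in µm with the origin at the center of the top-left pixel. MMFI is measured
over the particle's own transmitted-light mask — no dilation — as the mask
mean minus the frame's background estimate (median intensity outside all
retained masks; the correction can be disabled for recordings selected for
high organelle-to-cytosol signal ratios). Touching particles that merge into
one component are deliberately reported as one particle; no watershed
splitting is attempted, mirroring the fact that clustered organelles cannot
be tracked reliably anyway.

### Linking

Consecutive frames are linked by **gated globally optimal assignment**:
among all one-to-one partial matchings whose pairs lie within the gating
distance (default 1.2 µm), the matching with maximal cardinality and, among
those, minimal total squared displacement is selected. The solver is a
Jonker–Volgenant shortest-augmenting-path implementation on a padded square
cost matrix; non-matching carries a dummy cost high enough that larger
matchings are always preferred, and gated-out pairs are blocked entirely.
Equal-cost ties are broken towards lexicographically smaller index pairs via
an infinitesimal rank perturbation (≈ gate² · 10⁻¹⁰), far below any
physically meaningful cost difference. Unmatched detections start new
tracks; unmatched track ends terminate — there is no gap closing and no
merge/split handling. Tracks shorter than 10 frames (configurable) are
discarded and counted; the census report (track count, frame-to-frame point
count, length histogram) replaces the visual QC step of interactive
software with auditable numbers.

### Events and derived quantities

Each consecutive observation pair of a track yields one event. The event's
MMFI is the arithmetic mean of the two bounding observations' MFIs: the
field's convention for which frame's intensity accompanies a displacement is
genuinely ambiguous (frame t, frame t+1, or both), and the symmetric mean is
stable under time reversal — this is this package's choice, made once. The
same averaging gives the event size. The two-channel ratio divides one
channel's MMFI by the other's, guarded by a denominator threshold ε (events
failing the guard are excluded from ratio analyses and counted, never
silently dropped). Channel normalization divides by the per-cell median of
the channel — a robust, scale-free choice for comparing recruitment across
bins when the original normalization method is unspecified.

### Static/motile classification

A fixed (chemically immobilized) sample contains no genuine motion, so the
maximum event speed observed in it bounds what detection and localization
noise can fabricate. That maximum is the **static threshold**; with no
calibration recording available the conventional 0.05 µm/s default is used.
Classification is *inclusive* (static ⟺ speed ≤ threshold): only the
inclusive comparison makes "100% of the fixed sample is static" a theorem
rather than an aspiration, since the calibrating maximum itself must
classify as static.

### Binning and aggregation

Events are binned **per cell** into deciles (10 equal-occupancy groups) of
the binning variable: after a stable ascending sort, the event of 0-based
rank $r$ among $N$ goes to bin $\lfloor r \cdot 10 / N \rfloor$, so bin
sizes differ by at most one and sum to $N$. Per-cell binning compensates for
expression-level differences between cells. Three distinct layers are kept
separate because analyses use all three:

1. per-cell, per-bin summaries (median speed, % static, motile-only median);
2. cross-cell aggregates (mean ± SEM of the per-cell bin medians);
3. events pooled across cells by bin index, which feed the hypothesis tests.

Every reported value is labeled with its provenance (pooled events vs
per-cell aggregation).

### Statistics

* **Kruskal–Wallis** (tie-corrected H, χ² p on k−1 df) across bins, with an
  exact permutation p by full enumeration for pooled n ≤ 10.
* **Dunn's post test**: pairwise z on mean pooled ranks with the
  tie-corrected variance, two-sided normal p, Bonferroni adjustment over all
  pairs (the conventional "Dunn's post test"); the adjustment method is
  recorded in the report.
* **Mann–Whitney** for pairwise comparisons of full data sets (exact for
  small tie-free samples, normal approximation with tie/continuity
  correction otherwise).
* **Spearman rank correlation** with midranks for ties; two-sided p from the
  t approximation; 95% CI from the Fisher z transform with variance
  1.06/(n−3). That variance choice reproduces published confidence intervals
  for this analysis style at n in the thousands.
* **Five-number speed summaries** use the linear-interpolation percentile
  definition (R quantile type 7), recorded in the output because box-plot
  percentile conventions vary.

## The synthetic-movie generator

Because no raw recordings are deposited for this kind of experiment, every
stage is validated on synthetic movies with known ground truth.

The generator emulates: a 20 × 20 µm field at 16 px/µm recorded at 1 frame/s
for 100 frames; ~50 dark particles of 0.15–0.25 µm radius on a bright
background; one or two fluorescence channels rendering a Gaussian spot
(σ = particle radius) scaled by the particle's label level over a uniform
cytosolic background; additive Gaussian camera noise. Motion is a
per-particle two-state Markov switch with geometric dwell times (mean motile
dwell 10 frames): static particles jitter (σ = 0.008 µm per axis per frame,
chosen to give a fixed-sample median event speed near 0.013 µm/s), motile
particles run at a per-run speed drawn from 0.05–0.8 µm/s with a slowly
diffusing heading (σ = 0.2 rad/frame). The baseline motile occupancy is
0.35, matching live-cell observations that roughly two-thirds of events are
static. Boundaries reflect, keeping tracks in the field for the whole movie.
The observed-regime parameters above are treated as the study conditions;
none of them is a tuning knob.

Label→motility coupling acts on **state occupancy**, not on speed within the
motile state: with negative coupling of strength c, a particle whose label
level sits at quantile u of the configured label range has motile occupancy
0.35 · (1 − c·u). This reproduces the key observable structure (more static
events at high MMFI) with a single knob. Initial positions are
non-overlapping; overlap during the movie is allowed and mirrors crowded
cytoplasm.

The generator does **not** model: optical point-spread functions, evanescent
TIRF illumination depth, photobleaching, Poisson (shot) noise, organelle
birth/death, or z-motion. Tests passing on synthetic movies therefore
demonstrate the correctness of the measurement and statistics chain under a
known generative model — not robustness to every optical artifact of real
microscopy.

## Validation choices worth knowing about

* **Link recovery** is measured as coverage: a ground-truth link (particle
  p, frames t→t+1) is recovered iff some track has consecutive observations
  within 0.3 µm of p at both frames. A merged component may cover both of
  two touching particles — charging the linker for the detector's deliberate
  merge policy would conflate the two stages. Recovery is assessed on
  unfiltered tracks (minimum length 2), because the 10-frame filter is a
  downstream QC step that discards fragments wholesale. On default movies
  the linker recovers 96–97% of the 4 950 true links.
* **Kruskal–Wallis null calibration** uses two-frame movies (one event per
  particle, 100 particles per dataset, 200 datasets). Longer movies give
  events that are serially dependent within particles — a particle's label
  is constant and its motion state persists for ~10 frames — so pooled
  events violate the exchangeability unit of the test and no implementation
  could achieve the nominal 5% rate on them. One-event-per-particle
  datasets are the generator's honest iid regime; the observed rejection
  rate is checked against the binomial 95% band around 5%.
* **Coupling recovery** is assessed on four simulated cells aggregated as a
  session would be (per-cell binning, cross-cell mean of per-cell
  percent-static): the per-decile sampling unit is the particle (~5 per
  decile in a single 50-particle cell), so single-cell profiles are too
  noisy to judge monotonicity.
* **Problem sizes** used by the test-suite: default-scale movies (50
  particles × 100 frames) for recovery and coupling runs, 15–25 particle
  movies for interface round-trips, and n ≤ 9 fixtures wherever a
  brute-force enumeration oracle is the comparator. These sizes were chosen
  so each property is measured at the scale where its oracle is exact or
  its sampling noise is quantifiable.

## Numerical and degenerate-input behaviour

* All-equal samples: Kruskal–Wallis returns H = 0, p = 1; Dunn flags no
  pairs.
* Zero-variance variables: Spearman r is flagged undefined rather than
  returning NaN.
* Bins with no motile event: the motile-only median carries an explicit
  undefined flag; nothing divides by zero.
* Single-cell aggregates: means are returned, SEMs are flagged undefined.
* Empty detection results, empty matchings and empty calibration sets are
  either valid empty results (logged) or errors naming the offending input,
  as documented per function.
* TIFF round-trips quantize to 16 bits against a recorded intensity scale;
  all pipelines are byte-reproducible under a fixed seed.

## Known limitations

* The linker optimizes frame pairs, not whole trajectories; crossing
  particles at high speed can swap identities (rare at the default density
  and gate).
* Merged (touching) particles are a single observation by design; their
  MMFI mixes both particles' labels.
* No sub-pixel localization: centroid accuracy is limited by mask
  quantization (well under a pixel in practice).
* The SEM-of-per-cell-medians aggregation treats cells as exchangeable
  replicates; no mixed-effects modelling of within-cell clustering is
  attempted beyond it.
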