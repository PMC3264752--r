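# melanotrack

Semi-automated correlation of **organelle movement** with **membrane-bound
fluorescent protein content** in multi-channel time-lapse microscopy.

Pigmented organelles (melanosomes) are visible as dark particles in
transmitted-light images, while a tagged peripheral membrane protein — a Rab
GTPase or one of its effectors — is recorded in one or two fluorescence
channels. melanotrack detects the particles with intensity and size/area
filters, links them across frames by gated globally optimal assignment,
and reduces every track to its **frame-to-frame movement events**: for the
displacement from frame *t* to *t+1* it records the speed
*s = ‖x(t+1) − x(t)‖ / Δt*, the mean organelle-associated fluorescence
intensity (MMFI, mask mean minus frame background, averaged over the two
bounding frames), the apparent organelle size, and optionally the MMFI
ratio of two channels.

Downstream, the package implements the standard analysis battery for this
kind of data:

* **static/motile classification** against a speed threshold calibrated as
  the *maximum* event speed of a fixed (immobilized) sample — inclusive
  comparison, so the fixed sample is 100% static by construction (default
  threshold 0.05 µm/s when no calibration recording exists);
* **per-cell decile binning** by MMFI (or MMFI ratio, or size): stable sort,
  rank *r* of *N* → bin ⌊10·r/N⌋, compensating for expression-level
  differences between cells;
* per-bin summaries (median speed, % static, motile-only median), cross-cell
  aggregation (mean ± SEM of per-cell medians), and the test battery:
  Kruskal–Wallis with tie correction + Dunn's post test (Bonferroni),
  Mann–Whitney, and Spearman rank correlation with a Fisher-z 95% CI
  (variance 1.06/(n−3));
* a **synthetic-movie generator** with ground truth — a two-state
  static/motile Markov motion model whose state occupancy can be coupled
  (negatively, positively, or not at all) to each particle's label level —
  so the entire pipeline is testable against known trajectories and known
  coupling.

Intended users: cell biologists quantifying organelle transport regulation,
and anyone needing a transparent, fully testable reimplementation of the
"track in transmitted light, measure fluorescence per organelle, bin by
recruitment, compare speed distributions" workflow.

## Worked example

Calibrate a threshold on a simulated fixed sample, then analyse a live-cell
movie whose label level is negatively coupled to motility:

```r
library(melanotrack)

# fixed sample -> static threshold
fixed <- simulate_fixed_sample(simulation_config(
  n_particles = 30, n_frames = 50, field_size = c(15, 15), seed = 2))
fx_events <- compute_events(
  build_tracks(detect_movie(fixed$stack), max_displacement = 1.2,
               frame_interval = 1), frame_interval = 1)
threshold <- calibrate_static_threshold(fx_events)
threshold
#> static threshold: 0.05114 um/s (source: fixed_calibration, n = 1470)

# live cell, high-label particles dock more often
live <- simulate_movie(simulation_config(
  coupling_sign = "negative", coupling_strength = 0.7, seed = 3))
tracks <- build_tracks(detect_movie(live$stack), max_displacement = 1.2,
                       frame_interval = 1)
#> build_tracks: 73 track(s) kept, 25 discarded (< 10 frames)
events <- compute_events(tracks, frame_interval = 1)

spearman_with_ci(events$mmfi_ch1, events$speed_um_s)
#> Spearman rank correlation
#>   r = -0.1150, 95% CI [-0.1439, -0.0860]
#>   p = 2.146e-15

binned <- bin_by_variable(events, "mmfi_ch1")
summ <- summarize_bins(binned, threshold)
summ[, c("bin", "percent_static")]
#>    bin percent_static   (rises from 66.2% in the lowest-MMFI decile
#>    ...                   to 87.3% in the highest)

kw <- kruskal_wallis_dunn(split(binned$speed_um_s, binned$bin))
#> KW H = 92.4, p = 5.29e-16; 16 of 45 Dunn pairs significant
```

The Spearman r < 0, the rising per-decile percent-static profile and the
significant Kruskal–Wallis test together recover the programmed coupling:
organelles carrying more label move less — the signature of
recruitment-driven docking.

The same pipeline is scriptable from a shell via the thin dispatcher in
`inst/cli/melanotrack` (`simulate`, `track`, `analyze` subcommands; movies
as multi-page TIFF + JSON sidecar, tracks/events as CSV, reports as JSON
with full provenance).

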