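---
title: "Quantifying endothelial signaling during neutrophil transmigration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying endothelial signaling during neutrophil transmigration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(temsig)
```

## The biological problem

When neutrophils leave the blood stream they cross the endothelial
monolayer at preferred locations — transmigration hotspots — and a first
wave of adhering neutrophils appears to prime those locations for a second
wave. `temsig` implements the quantitative arms of that study design:

1. **KTR analysis** — kinase translocation reporters (KTRs) leave the
   nucleus when their kinase is active, so the cytoplasm/nucleus (C/N)
   intensity ratio of a cell reads out kinase activity. Two-channel
   time-lapses (nuclear marker + KTR) are segmented, tracked and reduced
   to per-cell C/N traces.
2. **Responder classification** — C/N traces are baseline-normalized to a
   relative kinase activity and cells are split into activated versus
   non-activated by unsupervised hierarchical clustering.
3. **Filopodia density** — apical ICAM-1-rich filopodia appear as
   diffraction-limited spots; their density per µm², excluding junctional
   ICAM-1, is the adhesion-priming readout.
4. **Two-wave spatial statistics** — signed nearest-neighbour distances of
   second-wave neutrophils to first-wave "surfaces", compared against a
   matched uniform random-dot null.
5. **Ratiometrics** — FRET (Venus/Cerulean3) traces, two-point FRAP
   normalization and fluorophore crosstalk matrices.

Because the study's raw microscopy is not deposited, every analysis ships
with a synthetic generator that produces ground-truth-annotated inputs
with the statistical structure the analysis assumes. The generators are
first-class, tested code: all quantitative claims in the test suite are
recoveries of planted truth.

## The KTR generative model

A cell's C/N trace is

$$
r_i(t) = b_i + a_i(t) + \varepsilon_{it}, \qquad
\varepsilon_{it} \sim \mathcal N(0, \sigma^2)
$$

with a per-cell baseline $b_i \sim U(0.9, 1.1)$ and a latent activity that
is zero for non-responders and, for responders,

$$
a_i(t) = A\,\bigl(1 - e^{-(t - t_s - d)/\tau}\bigr), \quad t \ge t_s + d
$$

where $t_s$ is the stimulus frame, $d = 1$ frame the translocation lag,
$\tau = 2$ frames the rise constant and $A = 0.4$ C/N units the plateau
amplitude. Defaults: 30 frames at 30 s (a 15-minute movie), stimulus at
frame 5 (2.5 min), noise $\sigma = 0.05$. The source experiments report no
translocation amplitudes or noise levels, so $A$, $\tau$, $d$ and
$\sigma$ are this package's choices — picked once so that the
classification task is non-trivial (single-frame SNR $A/\sigma = 8$, but
baseline jitter and the gradual rise leave room for error) — and all
remain configurable through `ktr_preset()`.

Two presets encode the study conditions: `control` with a 5% responder
rate and `neutrophil` with 50%. The responder count is always the exact
`round(rate * n)`, never a binomial draw, so that fraction-recovery
results are not confounded by sampling noise in the truth itself.

`gen_ktr_movie()` renders this model as a two-channel image stack: cells
are non-overlapping cytoplasm disks with concentric nucleus disks, and the
KTR channel distributes a constant per-cell total intensity between the
compartments so the mean-intensity ratio equals $r_i(t)$ exactly —
translocation conserves signal. Read noise and a smooth background
gradient are added with amplitudes proportional to the preset's noise, so
a zero-noise preset is an exact oracle: the rendered C/N equals the
analytic trace to machine precision, which the tests assert at `1e-6` and
the full pipeline at `1e-3`.

What the generator does **not** emulate: optics (no PSF blur on cell
edges), shot noise, cell shape irregularity, migration, division or death,
and neutrophils themselves are never rendered. Passing tests therefore
demonstrate the correctness of the measurement chain, not robustness to
every real-microscopy artifact; the segmentation parameters below are the
levers a user would retune on real data.

## The measurement chain

Per frame, `run_ktr_pipeline()` applies:

* `subtract_background()` — rolling-ball-style background removal,
  implemented as grayscale opening with a disc of radius 50 px (the exact
  rolling-ball variant is an implementation detail; a naive
  erode/dilate oracle pins the behaviour in the tests).
* `segment_nuclei()` — global threshold 0.1 on intensities in [0, 1]
  (the convention of the upstream tool family: raw integer images are
  divided by their dtype maximum), distance-transform watershed
  declumping, equivalent-diameter gate 30–100 px, border-touching nuclei
  dropped.
* `segment_cytoplasm()` — each cell is a ring of at most 10 px grown from
  its nucleus, restricted to KTR signal ≥ 0.08; collisions are resolved by
  the nearest-nucleus rule (seeded propagation with a large regularization
  constant, checked against a brute-force nearest-nucleus oracle);
  cytoplasm = cell − nucleus.
* `measure_cn()` — compartment means and their ratio; a compartment with
  fewer than 20 px (or a zero nuclear mean) yields a missing value, never
  a zero. The 20 px guard is this package's addition against tiny-region
  ratio noise.
* `track_overlap()` — objects link across consecutive frames when masks
  overlap **and** centroids moved ≤ 3 px; the stated "maximum pixel
  distance" is read as a centroid-displacement gate on top of overlap,
  with a pure-distance fallback (`require_overlap = FALSE`) for sparse
  scenes. Largest overlap wins, ties break by smaller displacement then
  lower label id; tracks never merge.

Coordinates are 0-based (row, col) pixels with the origin at the top-left;
frames are 0-based; physical units ride along via `pixel_size_um` and
`frame_interval_s`.

## Activity normalization and responder clustering

`normalize_baseline()` subtracts from each cell the mean of its frames
before the stimulus ("normalized to all frames before addition" — the
mean over the whole baseline window, not the last baseline frame). Cells
first detected after the stimulus have no baseline and are dropped with a
count. The operation is idempotent.

`cluster_responders()` reproduces the published recipe exactly: only
post-stimulus frames enter; frames are binned in pairs (trailing odd frame
dropped — the source is silent, and dropping keeps all bins equal-width);
remaining missing values are imputed by within-row linear interpolation;
cells from both conditions are clustered **jointly** with Manhattan (L1)
distance and Ward.D2 linkage, cut at $k = 2$. Ward's criterion formally
assumes squared Euclidean distances; applying the Ward.D2 update to L1
distances is mathematically unconventional but is precisely what the
source analysis did, so it is implemented as such — via
`stats::hclust(method = "ward.D2")`, which is the very routine the
original R-based app called — and verified merge-by-merge against an
independent brute-force Lance–Williams implementation in the tests.

The original analysis labelled the activated cluster by inspection; here
the cluster with the higher mean post-stimulus activity is `activated`.
If all cells are numerically identical there is no data-driven split and
the function returns everyone non-activated with a warning rather than an
arbitrary partition. Statistical testing on replicate medians is left to
stock routines (`t.test`, `aov`); the package only exports the tables.

The 95% ribbons of `summarize_timeseries()` use the normal approximation
(mean ± 1.96 SEM); the source does not state whether its ribbons were
normal or bootstrap, and the normal choice is the simpler, deterministic
one.

## Filopodia detection and morphometry

`detect_spots()` is a single-scale Laplacian-of-Gaussian detector at
$\sigma = D/(2\sqrt2)$ pixels for spot diameter $D$ = 0.6 µm (the scale at
which the LoG response of a Gaussian blob of that size peaks), with
sub-pixel maxima by quadratic interpolation. The commercial tool's
"quality" is proprietary; here quality is the detector response and the
published *manual* quality filtering is replaced by a numeric threshold on
`quality_rel` (response relative to the image's strongest response, which
makes the kept set invariant to intensity rescaling). The default
threshold 0.25 was chosen once on synthetic fields as the midpoint that
separates planted spots from membrane-texture maxima; it is a config
value, not a constant.

Junctional ICAM-1 is excluded by `junction_mask_from_channel()`
(threshold + 0.5 µm dilation) and `filter_spots()`, mirroring the negative
VE-cadherin filter; density is kept spots divided by imaged area, with an
optional GFP split for mosaic experiments (spots and area partitioned by
the GFP level at the spot centre).

`cell_morphometry()` renders the commercial "Cells" pipeline: nuclei
detected at a 5 µm scale and filtered at 173 px (the original filter is
stated in voxels; this 2D rendering treats it as pixels), cells grown from
nuclei by seeded propagation that cannot cross bright junction ridges
(ridge pixels are then split between adjacent cells so the boundary's area
share is not lost), cells under 10.62 µm equivalent diameter or touching
the border removed. The original "sphericity" from a 2.5D analysis is
rendered as 2D circularity $4\pi A/P^2$ — related but **not** identical,
and labelled as such.

## Two-wave spatial statistics

First-wave neutrophils are modelled as disks of radius 7.5 µm (≈ a
neutrophil radius) around their centroids — the stand-in for the rendered
surfaces of the original GUI analysis. `signed_nn_distance()` is the
distance to the nearest disk surface, negative inside, reproducing the
original sign convention. The null is `random_dot_null()`: uniform points
over the full field, matched in number to the second wave; no monolayer
mask is applied because the original generated its dots in the
phase-contrast channel without one, and whether first-wave-occupied area
was excluded is unstated — uniform-everywhere is the simpler null and is
what the calibration tests assume. `wave_comparison()` reports both
distance distributions, their medians/quartiles (per replicate when
given) and a KS comparison.

The generator `gen_wave_points()` plants the alternative: a stated
fraction of second-wave points lands within 5 µm of a first-wave point.
At attraction 0 the second wave is exactly the null (KS calibration); at
attraction 0.8 the wave-2 median is reliably below the random median —
the directional hotspot signature.

## Ratiometrics

`frap_normalize()` implements the two-point normalization — 100% at the
0 s pre-bleach anchor, 0% at the 15 s post-bleach anchor, anchors taken at
the nearest sampled frames. The source's methods text mentions a
first-frame-only normalization while its figure legend specifies the
two-point form; the legend's formula is the default and the single-anchor
variant sits behind `anchor = "first_frame"`. The normalization is
invariant to affine rescaling of the raw trace.

`fret_ratio_trace()` is the mean-acceptor over mean-donor ratio per frame
within each ROI mask, supporting the paired whole-cell versus
under-the-neutrophil comparison on the same time point.
`crosstalk_matrix()` picks, per fluorophore, the brightest cell on its own
channel (connected component above Otsu with the highest mean — the
operational rendering of "the brightest cell, using the same ROI for each
image"), reuses that ROI across channels and normalizes row-wise to the
own-channel signal, so the diagonal is exactly 1. No background
subtraction is applied before ratios by default (the source is silent);
both FRET stacks and crosstalk inputs accept pre-subtracted images.

## Numerical choices and degenerate inputs

* Thresholds (0.1 nuclei, 0.08 cytoplasm) assume intensities scaled to
  [0, 1]; callers of the low-level functions own that scaling.
* Watershed declumping uses tolerance 1 on the distance map; perfect
  disks yield one label each (asserted on planted scenes).
* All-missing pair bins stay missing; half-missing pairs keep the
  surviving value.
* Empty second waves, zero-spot fields, blank frames, single-frame movies
  and flat traces all return well-formed empty/degenerate results or
  explicit errors — each case is pinned in the tests.
* Generators fail loudly (naming the density limit) when asked to place
  more cells or spots than the field can hold at the required separations.

## Problem sizes

The test suite and the reproduction script run at the study's stated
conditions where those are known: 200 cells per condition, 30 frames,
stimulus frame 5, 20 repeat seeds for fraction recovery; one full-size
512×512, 30-frame, 20-cell noise-free movie for the end-to-end oracle;
200×200 µm fields at planted densities 0.001–0.02 µm⁻² (10 seeds each)
for filopodia recovery; 150-point waves over a 400×400 µm field (20
seeds) for the spatial calibration. Unit tests use smaller scenes chosen
to exercise the same code paths.

## Known limitations

* Segmentation and tracking are validated on rendered disks; real
  endothelial shapes, mitosis and cell death will stress the declumping
  and the 3 px gate in ways the synthetic movies cannot.
* The filopodia detector is single-scale; spots far from 0.6 µm would
  need a scale sweep.
* 2D circularity is not the original sphericity; compare only within this
  package's outputs.
* Ward.D2-on-L1 inherits whatever statistical quirks the original choice
  has; the package reproduces, not endorses, it.
* The FRAP module normalizes; it deliberately does not fit diffusion
  models.
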