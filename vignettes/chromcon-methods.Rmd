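---
title: "Quantifying chromatin condensation with pooled global thresholds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin condensation with pooled global thresholds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

Condensed chromatin (heterochromatin) appears in DAPI-stained nuclei as
bright, sharply bounded foci on a dimmer euchromatic background. Because the
foci are sharply bounded, their boundaries carry strong intensity gradients,
and the amount of gradient structure inside a nucleus tracks how compact its
chromatin is. `chromcon` turns that observation into a per-nucleus number,
the **condensation index**:

$$\mathrm{CI} = \frac{\#\{\text{interior pixels with } \lVert\nabla I\rVert > \tau_e\}}{\#\{\text{interior pixels}\}} \in [0, 1],$$

the fraction of interior nuclear pixels flagged as edges of condensed
domains by a thresholded Sobel gradient magnitude. Per z-stack the aggregate
index is the ratio of sums across planes, $\sum \mathrm{edge}_z / \sum
\mathrm{area}_z$, which down-weights planes where the nucleus is barely
present; the mean of per-plane ratios is also written to the CSV for
transparency.

## Pooled thresholding: one dataset, one threshold

The defining design choice is that thresholds are **never** chosen per
image. For comparative studies of heterogeneous tissue, per-image
thresholding biases exactly the quantity being compared: a dim nucleus gets
a lenient threshold, a bright one a strict threshold, and group differences
evaporate or invert. Instead the pipeline:

1. pools every **non-zero** pixel of every plane of every stack of the
   dataset into one histogram (zero is the black background created by
   cropping and extraction and carries no signal);
2. computes a single segmentation threshold on that pooled histogram by
   Otsu's method — the gray level maximizing the between-class variance
   $\omega_0\omega_1(\mu_0-\mu_1)^2$, found in one pass over cumulative
   moments, with the lowest level winning ties;
3. applies that one threshold to all images equally.

Otsu's criterion needs no peak detection and therefore cannot fail on a
non-empty histogram; a histogram with a single occupied gray level is
handled by returning that level flagged `degenerate` (with a warning) so a
batch run survives pathological crops. 16-bit histograms use all 65,536
levels — the analysis is loss-less and never rebins or compresses the data.

The same pooling logic is applied a second time to the *gradient*: the Sobel
magnitudes of all masked, blurred planes are pooled into a 65,536-bin
histogram on $[0, g_{\max}]$ and Otsu picks the edge threshold $\tau_e$ (the
upper edge of the selected bin). The original description names a single
"thresholding level" and leaves the binarization of the edge image
unspecified; using a second pooled Otsu keeps the edge decision as
dataset-global as the segmentation decision. This is the package's main
interpretive choice, and `analysis_params(edge_threshold_mode = "fixed",
fixed_edge_threshold = ...)` exists so users can bypass it.

A direct consequence, worth knowing when designing experiments: indices are
comparable **within** one analyzed dataset, and groups to be compared must
be analyzed jointly. Splitting a dataset in two and analyzing the halves
separately generally changes the numbers (each half gets its own threshold
pair); the package's tests assert that a joint run applies the identical
threshold pair to every stack. Equally, because the gradient threshold
adapts to the dataset's own gradient range, globally rescaling the contrast
of an *entire* dataset cancels out — an 8-bit dataset and its exact 257-fold
16-bit embedding yield identical masks, edge counts, and indices.

## The per-plane pipeline

For each plane, with the pooled threshold pair $(\tau_i, \tau_e)$ fixed:

1. **Segment**: pixels $> \tau_i$ form the nuclear mask.
2. **Fill holes**: background regions not 4-connected to the image border
   become foreground (condensed nucleoli and dim interior pockets belong to
   the nucleus). Foreground components use 8-connectivity, background
   4-connectivity — the standard duality.
3. **Keep the largest component** (default): one nucleus per image is
   assumed; ties break toward the component containing the lowest row-major
   pixel, so results are deterministic.
4. **Extract to black**: pixels outside the mask are set to 0.
5. **Blur**: Gaussian, $\sigma = 1$ px by default, kernel truncated at
   $4\sigma$, symmetric (edge-duplicating) borders, output kept in real
   precision. The blur suppresses the high-frequency camera noise that Sobel
   would otherwise amplify, while preserving the strong focal edges.
6. **Sobel**: gradient magnitude $\sqrt{G_x^2 + G_y^2}$ with the standard
   3×3 kernels.
7. **Erode and count**: the mask is eroded by `boundary_erosion_px` (default
   1, 3×3 box, border pixels treated as replicated) and edges are counted
   only in this interior, because extraction to black manufactures a huge
   artificial gradient at the nucleus/background rim that has nothing to do
   with chromatin. The reported `nuclear_area_px` is this interior area.

An empty interior (no pixels above threshold, or erosion consumed the mask)
flags the plane `empty`; it contributes nothing to the aggregate and its CSV
row carries an empty index field.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `gaussian_sigma` | 1 | px | noise suppression before Sobel; the original description names the blur but not its width, so the default is a deliberate choice: 1 px kills single-pixel shot noise while leaving multi-pixel foci boundaries intact |
| `boundary_erosion_px` | 1 | px | rim exclusion; 0 disables (sensitivity analysis) |
| `keep_largest_component` | TRUE | — | one-nucleus-per-image assumption |
| `edge_threshold_mode` | pooled Otsu on gradient | — | see above; `"fixed"` bypasses |

The blur and the erosion interact: the blur spreads the rim gradient about
$\lceil 4\sigma \rceil + 1$ pixels inward, so with the defaults a thin band
inside the rim still carries some bleed gradient, and it is the adaptive
edge threshold (calibrated on the same blurred data) that keeps it from
dominating. Only an erosion of at least $\lceil 4\sigma\rceil + 1$ px makes
the interior gradient of a uniform nucleus *exactly* zero — the package's
tests use that configuration when asserting the analytic zero bound.

## The legacy comparator

The antecedent method is included as `legacy_recursive_threshold()`: find
exactly two strict local maxima in the histogram, threshold at the minimum
between them; if the peak count differs from two, smooth (3-bin moving
average, ends averaged over available neighbours) and retry, up to 10,000
rounds. A *strict* maximum requires `counts[g-1] < counts[g] > counts[g+1]`,
so peaks widened beyond one bin — which smoothing itself produces — stop
being detected; constant and unimodal histograms can never yield two peaks
and fail by construction. That failure mode is the motivation for the Otsu
redesign, and the package reproduces it as a testable property rather than
inheriting it. The original code's exact smoothing kernel and peak
definition are not published; this comparator is faithful to their textual
description only, and its robustness numbers are reported, not asserted.
`legacy_bin2()` provides the 2×2 block-mean binning the legacy pipeline
applied (analyzing an image four times smaller), used only by the benchmark
grid so compressed and uncompressed inputs can be compared. A smoothing
round that leaves the histogram bit-identical is a fixed point and
short-circuits to failure — the outcome after 10,000 futile rounds, without
spinning them.

## What the synthetic generator emulates — and what it does not

No real tissue data ship with the method, so `nucleus_model()` +
`make_stack()` render what the pipeline needs to be testable end to end: an
elliptical nucleus (geometric-mean radius 18 px, axis ratio 1.2 at the
default 64×64 frame) at 35 % of dynamic range on a zero background,
Gaussian-profile foci (sd = half the focus radius, peak = base ×
`focus_gain`) placed uniformly inside the nucleus with a one-focus-radius
margin, Poisson shot noise, then 2 % Gaussian read noise, quantized to 8 or
16 bits. A spherical-cap z-profile scales radius and brightness so the
nucleus appears, peaks mid-stack, and disappears. Everything derives
deterministically from the seed (per-plane seeds are `seed XOR
hash(plane_index)` with a Knuth multiplicative hash, so an external replay
oracle can reproduce them), and `ground_truth.csv` sidecars regenerate any
written dataset bit-identically.

Condensation ground truth is carried by `n_foci` and `focus_gain`. The named
presets encode the two biological gradients the method was built to
quantify, as foci-count/gain pairs chosen once to span weak to strong
condensation: spermatogonia (2, 1.8) < spermatocyte (6, 2.2) < spermatid
(12, 2.8) for the spermatogenesis series, and blastema (2, 1.6) vs dermal
(10, 2.6) for regenerating vs mature limb tissue.

What the generator does **not** model: optics (no point-spread function),
crowded fields (one nucleus per frame), intra-nuclear texture other than
foci, bleaching, or z-correlated foci (each plane samples foci
independently). Passing tests therefore demonstrate that the pipeline
measures what it claims on images whose ground truth is known — not that
the presets reproduce any real tissue's absolute index values, which were
never published as numbers.

One interaction deserves emphasis. The pooled histogram *excludes zeros*,
so it only "sees" a background population if the background is not exactly
zero. With the generator's read noise on (the default), roughly half the
background pixels are positive and Otsu separates background from nucleus
as intended. With all noise off and a mathematically zero background, the
pooled histogram contains nucleus pixels only and Otsu instead separates
base intensity from foci — segmentation degenerates to the foci. That is a
faithful consequence of the pooling design, not a bug; the generator's
`background_level` option (e.g. 0.03 for residual mounting-medium
fluorescence) exists to stress-test exactly this assumption, and the
noise-robustness tests use it so that their baseline is a sanely segmented
dataset.

## Numerical choices and degenerate inputs

- Otsu ties: lowest maximizing level, so results are exactly reproducible.
- Between-class variance is computed as
  $(\mu_T\omega_0 - \mu_0^{cum})^2 / (\omega_0\omega_1)$ over cumulative
  moments; the tests verify exact argmax agreement with a literal
  exhaustive scan on 1000 random histograms per bit depth.
- All-zero dataset: `analyze_dataset()` aborts naming the dataset root.
- All-gradient-zero dataset (uniform nuclei): edge threshold 0, all indices
  0, no division by zero.
- Single-occupied-level histogram: degenerate success with a warning.
- CSV numbers: 8 significant digits; reruns under the same seed are
  byte-identical.
- Benchmark and test problem sizes: the test suite runs its grids at
  reduced sizes (32–128 px, 2–5 images per cell) and the full 128–2048
  robustness grid at n = 15 per condition, the acceptance script's own
  problem size.

## Known limitations

- Edge density is a proxy: two tissues can in principle differ in focal
  *size* at equal focal *count*; the index responds to boundary length, not
  volume, of condensed domains.
- Indices are only comparable within one jointly analyzed dataset (by
  design).
- 2-D per-plane analysis: hole filling and edges are computed per optical
  section, not volumetrically.
- Touching or overlapping nuclei are not resolved; the largest-component
  rule assumes the crop isolates one nucleus.
- The gradient-threshold interpretation (second pooled Otsu) is this
  package's resolution of an underspecified step; `fixed_edge_threshold`
  lets users substitute their own calibration.
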