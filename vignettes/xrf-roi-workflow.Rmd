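---
title: "Finding and recommending cells in coarse XRF scans: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and recommending cells in coarse XRF scans: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xrfroi)
```

## The problem

Synchrotron X-ray fluorescence (XRF) microscopy raster-scans a focused
X-ray probe over a cryo-preserved sample and records, for every pixel, the
fitted fluorescence counts of each chemical element — one 2D map per
element. Fine-resolution scans are slow (dwell times of tens of
milliseconds per pixel over hundreds of thousands of pixels), so beam time
is spent in two stages: a fast coarse survey scan, then fine scans of a
few selected regions. Choosing those regions by eye is slow and
irreproducible. `xrfroi` automates the choice for single-cell studies of
bacteria: it detects candidate cells in the coarse maps, embeds each cell
in a low-dimensional feature space, groups cells by physiological state
(e.g. healthy versus membrane-poisoned), and emits ranked stage
coordinates for fine scanning.

The biological signal driving the grouping is inorganic: healthy cells
frozen in a live state retain high intracellular potassium, while cells
whose inner membrane has been disrupted (e.g. by ethanol) leak K and show
relatively elevated Ca, Zn and P. Morphology (area, elongation) adds a
second, weaker axis of variation.

## Pipeline and model

1. **Composite and segmentation.** The K, P, S and Ca channels are summed
   into one intensity image — the combination in which cells contrast
   best against the background. A 3×3 median filter suppresses single-pixel
   noise, then the image is binarized at **1.25×** the Otsu threshold of
   the filtered image. Connected components (8-connectivity) are extracted
   and every component of **8 pixels or fewer** is discarded as an
   image-processing artifact.
2. **Features.** Each kept region (ROI) yields a 7-vector
   \((a, e, K, P, Ca, Zn, Fe)\): pixel area, eccentricity of the
   moment-equivalent ellipse, and the per-element **maximum** fluorescence
   count over the ROI's pixels (the mean, or any user reduction, is
   available as an alternative; S is used only for segmentation, not as a
   feature).
3. **PCA.** The \(n \times f\) feature matrix is standardized
   (mean 0, sample sd 1, \(n-1\) denominator) and decomposed,
   \(X_s = USV^\top\). Eigenvalues of the covariance
   \(C = X_s^\top X_s/(n-1)\) are \(\lambda = s^2/(n-1)\); scores are
   \(X_s V\), loadings \(VS/(n-1)\), and the scree reports
   \(\lambda_i / \sum_j \lambda_j\). The first **2** components are the
   working space for everything downstream.
4. **Clustering.** Hard k-means (k = 2 by default) gives crisp labels;
   fuzzy k-means (fuzziness m = 2) gives per-cell membership weights
   \(w_{ij} \in [0,1]\), \(\sum_j w_{ij} = 1\), minimizing
   \(\sum_i \sum_j w_{ij}^m \lVert x_i - c_j\rVert^2\) with the classical
   alternating updates
   \(w_{ij} = 1/\sum_c (\lVert x_i - c_j\rVert/\lVert x_i - c_c\rVert)^{2/(m-1)}\)
   and \(c_j = \sum_i w_{ij}^m x_i / \sum_i w_{ij}^m\). A cell's
   **confidence** is its largest weight; cells **below 0.99** are flagged
   as borderline (outliers, dividing cells, scan artifacts). With two
   clusters, the cluster with higher mean K is labeled type A (healthy),
   the other type B (poisoned).
5. **Recommendation.** Either the nearest neighbor (Euclidean, in the 2-PC
   plane) of each user-selected cell, or the confidence-ranked members of
   a chosen cluster; both translate to stage coordinates
   \(x = x_0 + \mathrm{col}\cdot\Delta\), \(y = y_0 + \mathrm{row}\cdot\Delta\)
   with \(\Delta\) the pixel step in µm.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `segmentation_channels` | K, P, S, Ca | channels whose sum contrasts cells best |
| `otsu_multiplier` | 1.25 | pushes the threshold above the background shoulder; tightens cell boundaries |
| `min_pixels` | 8 (exclusive) | components ≤ 8 px are artifacts at a 0.25 µm step; a real cell (≈ 2 µm × 1 µm) covers ≥ ~15 px |
| `elements` | K, P, Ca, Zn, Fe | feature channels; Cu/Ni/Cl maps are typically too noisy |
| `aggregator` | `max` | maximum counts cluster at least as well as cell means here; both supported |
| `n_components` | 2 | enough to separate two treatment types while staying plottable |
| `k`, `m` | 2, 2 | two treatment groups; m = 2 is the standard fuzziness (m → 1 recovers hard k-means) |
| `confidence_threshold` | 0.99 | strict "below": cells at exactly 0.99 are kept |
| `seed` | 1 | all randomness (k-means starts, simulator) funnels through one seed |

## The synthetic-scan simulator

Real coarse scans from the reference study are not distributable, so the
package ships a generator whose defaults encode that study's conditions:

* **Geometry.** Cells are filled ellipses rasterized by centre-of-pixel
  inclusion — areas and eccentricities then track closed-form ellipse
  values. Semi-axes are drawn uniformly from 4–7 px (major) and
  1.4–2.2 px (minor): rod-shaped bacteria of 2–3.5 µm × 0.7–1.1 µm at a
  0.25 µm step. Cells are placed without overlap (2-px halo); placement
  failure after 200 retries is an error, not a silent overlap.
* **Intensity.** Expected counts per pixel at the reference dwell of
  100 ms: background 2 for every element; type A (healthy)
  K=60, P=40, S=30, Ca=8, Zn=6, Fe=5; type B (ethanol-poisoned)
  K=15, P=55, S=30, Ca=30, Zn=20, Fe=5; type C (azide/Cu-treated)
  K=90, P=40, S=30, Ca=10, Zn=8, Fe=5. The magnitudes are invented — no
  absolute count scale exists for the real system — but they encode the
  qualitative ordering that matters: A ≫ B in K (membrane leakage), B
  elevated in Ca/Zn/P, C highest in K. All are configurable.
* **Noise.** Every pixel of every channel is an independent Poisson draw
  with mean `rate × dwell / 100 ms`, so halving the dwell time halves the
  expected counts and degrades SNR by √2 — the mechanism behind the
  dwell-time trade-off the evaluation module measures.
* **Artifacts.** Speckles of 1–8 px are planted clear of cells so that the
  size filter must remove every one of them.

What the simulator does **not** emulate: detector physics (escape peaks,
pile-up, energy crosstalk), spectrum-fitting residuals and their spatially
correlated errors, touching or dividing cells, intensity gradients inside
cells, and drift between repeated scans of one area. Synthetic type A/B
populations are therefore close to linearly separable in feature space,
and recovery tests score near-perfect dice; passing them validates the
machinery (segmentation, features, embedding, clustering, ranking), not
the clustering accuracy attainable on real beamline data, where published
values run from ~0.64 (small subsamples) to ~0.86 (full data).

## Numerical choices

* **Otsu.** 256 equal-width bins over `[min, max]`; candidate thresholds
  are interior bin edges; class statistics use the exact pixel values per
  class (not bin midpoints); ties break toward the lower threshold;
  foreground is strictly above the scaled threshold. A constant image has
  no threshold — segmentation then returns a background-only mask with a
  warning.
* **Filter-then-threshold.** The 1.25 multiplier applies to the Otsu value
  of the *median-filtered* composite, and the filter pads borders by edge
  reflection. Thresholding runs on raw filtered counts; no normalization
  (standardizing a single scan's composite would only shift/scale the
  histogram and leave the Otsu split at the same pixels).
* **Connectivity.** 8-neighbor, the conservative choice against splitting
  one cell along a diagonal boundary; verified against a flood-fill oracle.
* **Eccentricity.** From the normalized second central moments of the
  pixel set with the classical 1/12 per-axis pixel-extent term, so a
  single pixel is a tiny square (e = 0) and even a one-pixel-wide line
  stays strictly below 1.
* **PCA determinism.** Each principal axis's sign is fixed so its
  largest-magnitude coefficient is positive (first index on ties); two
  fits of the same data are bit-identical. Standardization refuses
  zero-variance features by name rather than dividing by zero.
* **Fuzzy updates.** A point coincident with a center takes an indicator
  weight row (the update is otherwise singular). Initialization comes from
  a hard k-means run under the same seed: deterministic and fast to
  converge. Convergence is `max |ΔW| < 1e-9`; the objective is
  non-increasing across iterations and tests assert it.
* **Empty k-means clusters.** With k-means++ starts on ≥ k distinct
  points these are rare; a run that still collapses is restarted from a
  fresh k-means++ draw rather than patched mid-iteration.
* **Dice matching.** Clusters are unordered, so the cluster-to-label
  bijection is chosen by exhaustive search (exact for k ≤ 4) to maximize
  the mean dice \(2T_P/(2T_P+F_P+F_N)\).
* **Subsampling.** Per-type sample sizes are `ceiling(p × n_type)` —
  with 81 + 25 cells this reproduces the reference study's published
  per-type counts at every proportion (e.g. 69 + 22 = 91 at 85%).
* **SNR.** `(mean inside mask − mean outside) / sd(outside)` — a
  contrast-to-background-noise definition. The reference study prints SNR
  values but not a formula, so this is a documented package choice; only
  the monotone dwell-time trend is treated as comparable, never the
  printed magnitudes.

## Design decisions where the design was open

* **Scan container.** Upstream fitting software emits `.h5` maps but the
  internal layout is not standardized; the package defines its own
  documented HDF5 layout (`/scan` attributes + one dataset per channel
  under `/scan/channels/`) with exact round-tripping, plus a best-effort
  `read_scan_maps()` adapter whose dataset paths are a guess and are
  documented as such.
* **Interactive selection.** The lasso selector of a GUI workflow is
  replaced by `select_in_polygon()` (point-in-polygon over PC scores) and
  plain index sets — the same operation, headless and testable.
* **Per-selected-cell neighbors.** Nearest-neighbor recommendation
  returns one neighbor per selected cell, de-duplicated and
  distance-sorted, rather than one global neighbor.
* **K-heuristic scope.** Typing by "higher mean K = healthy" is only
  defined for the two-treatment (A vs B) case; azide/Cu-treated cells
  (type C) carry the *highest* K, so the heuristic deliberately errors for
  k ≠ 2 instead of guessing.
* **Axis convention.** Stage x runs along columns, y along rows, origin
  at the top-left pixel centre; metadata origins are stored (y, x),
  emitted scan requests are (x, y). Beamlines with flipped axes remap at
  the integration layer.

## Known limitations

* Otsu assumes a bimodal histogram. On a scan containing **no** cells but
  ordinary background noise, the threshold lands inside the noise
  distribution and spurious small detections can survive the size filter;
  a constant (signal-free) image is caught, but noise-only scans are not.
  Inspect flagged low-confidence cells, or the per-scan region counts in
  the run log, when a scan may be empty.
* Binarization is not idempotent in a single step: re-binarizing a mask
  keeps eroding one-pixel protrusions for a few passes before reaching a
  fixed point. This is inherent to the median filter and harmless in the
  one-pass pipeline.
* Touching or dividing cells are not split (no watershed); they surface
  as large-area, low-confidence outliers, which is the intended signal
  for manual review.
* The treatment-type heuristic and the k = 2 defaults target the
  two-population experiment; more types need more features/PCs and a
  different labeling rule.

## Problem sizes used by the test suite

The suite exercises full-size scans where it matters and small instances
elsewhere: the bookkeeping check simulates the complete five-scan
reference layout (up to 321 × 321 px, 106 cells); parameter recovery uses
five 220 × 220 scans of 20 + 20 cells; the subsampling experiment runs
200 repetitions per proportion on the 81 + 25-cell table; the dwell-time
trend uses 20 seeds × three dwells on a 163 × 163 scene of 18 cells.
Oracle-equivalence checks (Otsu, PCA, fuzzy weights, dice, nearest
neighbor) run on instances of at most 100 rows against brute-force
reimplementations written independently in the test helpers.
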