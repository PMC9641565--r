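# xrfroi

Cell detection and fine-scan recommendation for X-ray fluorescence (XRF)
microscopy.

## What it is for

At a scanning XRF beamline, a fast **coarse scan** of a cryo-preserved
sample produces one 2D fluorescence-count map per chemical element (K, P,
S, Ca, Zn, Fe, ...). Fine-resolution scans are far too slow to cover the
whole field, so someone must decide *where* to scan next. For single-cell
studies of bacteria — e.g. distinguishing healthy cells from
ethanol-poisoned ones by their inorganic content — `xrfroi` makes that
decision reproducible and automatic:

1. **Segment**: sum the K+P+S+Ca maps, median-filter (3×3), binarize at
   1.25× the Otsu threshold, extract 8-connected components and discard
   any of ≤ 8 pixels (image-processing artifacts).
2. **Featurize**: per detected cell, the 7-vector
   (a, e, K, P, Ca, Zn, Fe) — area, eccentricity, and the maximum
   fluorescence count of each element over the cell's pixels.
3. **Embed**: standardize and run PCA (X_s = USVᵀ; scores X_sV, loadings
   VS/(n−1)); keep the first 2 PCs.
4. **Cluster**: hard k-means (k = 2) and fuzzy k-means (m = 2) on the 2-PC
   scores. Each cell's **confidence** is its largest membership weight
   w_ij (rows of W sum to 1); cells below 0.99 are flagged as borderline.
   The cluster with the higher mean K is labeled type A (healthy) — intact
   membranes retain potassium — and the other type B (poisoned).
5. **Recommend**: nearest neighbors (Euclidean, 2-PC plane) of selected
   cells, or confidence-ranked cluster members, emitted as stage
   coordinates (µm) for the acquisition system.

A synthetic-scan simulator (elliptical cells, treatment-specific element
profiles, dwell-time-scaled Poisson noise, planted artifacts, full ground
truth) makes the entire pipeline testable without beamline data, and an
evaluation module scores clusterings with the dice coefficient
DS = 2T_P/(2T_P + F_P + F_N) after optimal cluster↔label matching.

## Worked example

Simulate a coarse scan with 12 healthy (A) and 8 poisoned (B) cells plus
4 speckle artifacts, then run the full pipeline:

```r
library(xrfroi)

sim <- generate_scan(shape = c(200, 200), n_cells_by_type = c(A = 12, B = 8),
                     dwell_time = 100, artifact_count = 4, seed = 7)
res <- run_pipeline(list(sim$map_set), out_dir = "out")
cat(res$log, sep = "\n")
#> xrfroi pipeline, seed = 1
#> config: composite = K+P+S+Ca; features = K,P,Ca,Zn,Fe (max); otsu x 1.25; reject <= 8 px; 2 PCs; k = 2; m = 2; confidence < 0.99 flagged
#> scan synthetic: 20 regions found, 0 rejected (<= 8 px), 20 cells kept
#> feature table: 20 cells x 7 features
#> clustering: k = 2, inertia = 31.717; 15/20 cells below confidence 0.99
```

All 20 planted cells are recovered (the artifacts are erased by the
median filter or rejected by the ≤ 8 px rule). The scree shows the first
two PCs carrying ~79% of the variance, and the K-heuristic typing matches
the planted ground truth exactly:

```r
round(scree(res$pca), 3)
#> [1] 0.574 0.216 0.100 0.094 0.011 0.003 0.001

table(res$treatment$predicted)
#>  A  B
#> 12  8

truth <- match_rois_to_truth(do.call(c, unname(res$rois)), sim$ground_truth)
dice(res$kmeans$labels, truth$true_label)$mean_dice
#> [1] 1
```

The ranked recommendation for cluster 1 (top rows; `centroid_*_um` are
stage coordinates ready for a fine-scan request):

```r
head(res$recommendations[[1]]$table, 3)
#>   index confidence   scan_id roi_id centroid_y_um centroid_x_um
#> 1     5  0.9985014 synthetic      5      8.048387      21.31452
#> 2    20  0.9957158 synthetic     20     43.858333      30.91667
#> 3     7  0.9822756 synthetic      7      9.000000       4.00000
```

`out/` now holds `rois.csv`, `features.csv`, `clustering.csv`,
`pca_model.json`, per-cluster `recommendation_cluster*.json` scan
requests, PNG masks and `run_log.txt`. The same workflow is scriptable
from a shell via the installed `exec/xrfroi` entry point
(`xrfroi simulate | segment | features | cluster | recommend | evaluate | run`).

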