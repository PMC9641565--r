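# Evaluation: dice-score clustering accuracy, the stratified subsampling
# experiment, SNR against a reference mask, and ROI-to-ground-truth matching.

# all permutations of a small vector (k <= 4 in practice: <= 24 orderings)
permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Dice-score accuracy of a clustering against ground-truth labels
#'
#' Clusters are unordered, so the bijection between predicted clusters and
#' ground-truth label values maximizing the mean dice score is selected by
#' exhaustive search. For a cluster matched to label `l`, predictions in
#' the cluster are positives and `DS = 2 TP / (2 TP + FP + FN)`.
#'
#' @param pred Predicted cluster assignment (any atomic vector).
#' @param true Ground-truth labels, same length, same number of distinct
#'   values as `pred` has clusters.
#' @return List with `per_cluster_dice` (named by cluster), `mean_dice`,
#'   and `matching` (cluster -> label).
#' @export
dice <- function(pred, true) {
  if (length(pred) != length(true)) {
    stopf("pred (%d) and true (%d) differ in length", length(pred), length(true))
  }
  clusters <- sort(unique(pred))
  labels <- sort(unique(true))
  if (length(clusters) != length(labels)) {
    stopf("number of clusters (%d) and of label values (%d) differ",
          length(clusters), length(labels))
  }
  best <- NULL
  for (perm in permutations(labels)) {
    ds <- vapply(seq_along(clusters), function(i) {
      tp <- sum(pred == clusters[i] & true == perm[i])
      fp <- sum(pred == clusters[i] & true != perm[i])
      fn <- sum(pred != clusters[i] & true == perm[i])
      if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    }, numeric(1))
    if (is.null(best) || mean(ds) > best$mean_dice) {
      best <- list(per_cluster_dice = stats::setNames(ds, as.character(clusters)),
                   mean_dice = mean(ds),
                   matching = stats::setNames(perm, as.character(clusters)))
    }
  }
  best
}

#' Stratified subsampling experiment: dice score versus sample proportion
#'
#' For each proportion `p`, repeats `reps` times: sample
#' `ceiling(p * n_type)` cells of each type without replacement, embed the
#' sample with its own standardization + PCA (first `n_components` scores),
#' cluster with hard k-means (`k` = number of types), and score the labels
#' with [dice()]; the row reports the mean dice over repetitions.
#' Deterministic for a fixed seed.
#'
#' @param feature_table Feature table with a `true_label` column.
#' @param proportions Numeric proportions in (0, 1].
#' @param reps Samplings per proportion.
#' @param seed Integer master seed.
#' @param n_components PCs used for clustering.
#' @param n_init k-means starts per repetition.
#' @return Object of class `xrf_subsample`: a data.frame with one row per
#'   proportion (`proportion`, `mean_dice`, one `n_<type>` column per type,
#'   `n_total`), attributes `reps` and `seed`.
#' @export
subsample_experiment <- function(feature_table, proportions, reps = 1000,
                                 seed = NULL, n_components = 2, n_init = 10) {
  if (is.null(feature_table$true_label)) {
    stopf("feature table needs a true_label column")
  }
  types <- sort(unique(feature_table$true_label))
  if (length(types) < 2) stopf("need at least 2 label types")
  if (reps < 1) stopf("reps must be >= 1")
  k <- length(types)
  X_all <- feature_matrix(feature_table)
  idx_by_type <- lapply(types, function(t) which(feature_table$true_label == t))
  n_by_type <- lengths(idx_by_type)
  rep_seeds <- derive_seeds(seed, length(proportions) * reps)
  rows <- lapply(seq_along(proportions), function(pi) {
    p <- proportions[pi]
    n_samp <- ceiling(p * n_by_type)
    if (sum(n_samp) < k || any(n_samp < 1)) {
      stopf("proportion %.2f leaves too few cells to cluster", p)
    }
    scores_rep <- vapply(seq_len(reps), function(r) {
      with_seed(rep_seeds[(pi - 1L) * reps + r], {
        idx <- unlist(lapply(seq_along(types), function(t) {
          take <- idx_by_type[[t]]
          take[sample.int(length(take), n_samp[t])]
        }))
        model <- fit_pca(standardize(X_all[idx, , drop = FALSE]))
        sc <- project(model, n_components = min(n_components, ncol(model$V)))
        km <- hard_kmeans(sc, k = k, seed = NULL, n_init = n_init)
        dice(km$labels, feature_table$true_label[idx])$mean_dice
      })
    }, numeric(1))
    row <- data.frame(proportion = p, mean_dice = mean(scores_rep))
    for (t in seq_along(types)) row[[paste0("n_", types[t])]] <- n_samp[t]
    row$n_total <- sum(n_samp)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  class(out) <- c("xrf_subsample", class(out))
  out
}

#' Signal-to-noise ratio of a scan against a reference mask
#'
#' Contrast-to-background-noise definition:
#' `SNR = (mean inside mask - mean outside) / sd outside`. One definition
#' among several in use; chosen and documented as this package's
#' convention.
#'
#' @param image Numeric matrix (e.g. a segmentation composite).
#' @param reference_mask Binary matrix of the same shape with both classes
#'   present.
#' @return Scalar SNR.
#' @export
snr <- function(image, reference_mask) {
  if (!all(dim(image) == dim(reference_mask))) {
    stopf("image and mask shapes differ")
  }
  m <- reference_mask > 0
  if (!any(m) || all(m)) stopf("reference mask must contain both classes")
  inside <- image[m]; outside <- image[!m]
  s <- stats::sd(outside)
  if (s == 0) stopf("background is constant: SNR undefined")
  (mean(inside) - mean(outside)) / s
}

#' Match recovered ROIs to planted ground-truth cells
#'
#' For each ROI, reports the planted cell maximizing intersection-over-union
#' with the ROI's pixel set, the IoU achieved, and that cell's type label
#' (NA when nothing overlaps).
#'
#' @param rois List of `xrf_roi`.
#' @param ground_truth An `xrf_ground_truth`.
#' @return data.frame with `roi_id`, `cell_index`, `iou`, `true_label`.
#' @export
match_rois_to_truth <- function(rois, ground_truth) {
  shape <- dim(ground_truth$true_mask)
  cell_ids <- lapply(ground_truth$cell_pixels, function(p) {
    p[, 1] * shape[2] + p[, 2]
  })
  rows <- lapply(rois, function(roi) {
    rid <- roi$pixels[, 1] * shape[2] + roi$pixels[, 2]
    ious <- vapply(cell_ids, function(cid) {
      inter <- length(intersect(rid, cid))
      if (inter == 0) return(0)
      inter / length(union(rid, cid))
    }, numeric(1))
    if (length(ious) == 0 || max(ious) == 0) {
      data.frame(roi_id = roi$roi_id, cell_index = NA_integer_,
                 iou = 0, true_label = NA_character_, stringsAsFactors = FALSE)
    } else {
      ci <- which.max(ious)
      data.frame(roi_id = roi$roi_id, cell_index = ci, iou = ious[ci],
                 true_label = ground_truth$labels[ci], stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(roi_id = integer(0), cell_index = integer(0),
               iou = numeric(0), true_label = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Write a subsampling result as CSV
#'
#' @param result An `xrf_subsample`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_subsample_csv <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
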