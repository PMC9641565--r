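# End-to-end pipeline: coarse scans -> masks -> ROIs -> features -> PCA ->
# clustering -> ranked fine-scan recommendations, with artifacts on disk
# and a run log.

#' Pipeline configuration
#'
#' All tunables of the coarse-to-fine workflow in one place. The defaults
#' are the working constants of the method: K+P+S+Ca segmentation
#' composite, 1.25x Otsu threshold, components of more than 8 px kept,
#' 7-feature vector via maximum counts, 2 PCs, k = 2 clusters, fuzziness
#' m = 2, confidence cutoff 0.99.
#'
#' @param segmentation_channels Channels summed into the composite image.
#' @param elements Element features of the feature vector.
#' @param aggregator Per-ROI count statistic (`"max"` or `"mean"`).
#' @param otsu_multiplier Multiplier on the Otsu threshold.
#' @param min_pixels Exclusive component-size cutoff (reject `<= min_pixels`).
#' @param n_components PCs retained for clustering/recommendation.
#' @param k Number of clusters.
#' @param m Fuzziness of the fuzzy k-means.
#' @param confidence_threshold Low-confidence flagging cutoff.
#' @param seed Master seed funnelling all randomness.
#' @param n_bins Otsu histogram bins.
#' @return A named list of class `xrf_config`.
#' @export
pipeline_config <- function(segmentation_channels = c("K", "P", "S", "Ca"),
                            elements = c("K", "P", "Ca", "Zn", "Fe"),
                            aggregator = "max",
                            otsu_multiplier = 1.25,
                            min_pixels = 8,
                            n_components = 2,
                            k = 2,
                            m = 2,
                            confidence_threshold = 0.99,
                            seed = 1,
                            n_bins = 256) {
  structure(list(segmentation_channels = segmentation_channels,
                 elements = elements, aggregator = aggregator,
                 otsu_multiplier = otsu_multiplier, min_pixels = min_pixels,
                 n_components = n_components, k = k, m = m,
                 confidence_threshold = confidence_threshold,
                 seed = seed, n_bins = n_bins),
            class = "xrf_config")
}

#' Load a pipeline configuration from YAML with optional overrides
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments;
#'   NULL for pure defaults.
#' @param ... Named overrides applied after the file.
#' @return An `xrf_config`.
#' @export
load_pipeline_config <- function(path = NULL, ...) {
  vals <- if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: '%s'", path)
    yaml::read_yaml(path)
  } else list()
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stopf("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Segment one scan into ROIs
#'
#' Composite image, 3x3 median filter + scaled-Otsu binarization, connected
#' components, artifact rejection — one call.
#'
#' @param map_set An [elemental_map_set()].
#' @param config An `xrf_config`.
#' @return List with `mask` (a `segmentation_mask`) and `rois`.
#' @export
segment_scan <- function(map_set, config = pipeline_config()) {
  comp <- composite_map(map_set, config$segmentation_channels)
  mask <- binarize(comp, otsu_multiplier = config$otsu_multiplier,
                   n_bins = config$n_bins)
  rois <- extract_rois(mask, map_set$metadata, min_pixels = config$min_pixels)
  list(mask = mask, rois = rois)
}

roi_info_table <- function(rois) {
  if (!length(rois)) {
    return(data.frame(scan_id = character(0), roi_id = integer(0),
                      centroid_y_um = numeric(0), centroid_x_um = numeric(0)))
  }
  data.frame(
    scan_id = vapply(rois, `[[`, character(1), "scan_id"),
    roi_id = vapply(rois, `[[`, integer(1), "roi_id"),
    centroid_y_um = vapply(rois, function(r) r$centroid_um[["y"]], numeric(1)),
    centroid_x_um = vapply(rois, function(r) r$centroid_um[["x"]], numeric(1)),
    stringsAsFactors = FALSE)
}

#' Run the coarse-scan to recommendation pipeline
#'
#' Reads the scans, segments each one, builds the pooled feature table,
#' fits the PCA, clusters the 2-PC scores with hard and fuzzy k-means,
#' flags low-confidence cells, applies the potassium treatment-type
#' heuristic (k = 2), and writes per-stage artifacts plus a run log under
#' `out_dir`. Rerunning with the same inputs and seed reproduces identical
#' CSV content.
#'
#' @param scans Character vector of scan file paths (read with
#'   [read_scan()]), or a list of [elemental_map_set()] objects.
#' @param config An `xrf_config`.
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing artifacts.
#' @return Invisibly, a list: `map_sets`, `masks`, `rois`, `features`,
#'   `pca`, `scores`, `kmeans`, `fuzzy`, `flags`, `treatment`,
#'   `recommendations`, `log` (character vector of log lines).
#' @export
run_pipeline <- function(scans, config = pipeline_config(), out_dir = NULL) {
  log <- c(sprintf("xrfroi pipeline, seed = %s", config$seed),
           sprintf("config: composite = %s; features = %s (%s); otsu x %g; reject <= %d px; %d PCs; k = %d; m = %g; confidence < %g flagged",
                   paste(config$segmentation_channels, collapse = "+"),
                   paste(config$elements, collapse = ","), config$aggregator,
                   config$otsu_multiplier, config$min_pixels,
                   config$n_components, config$k, config$m,
                   config$confidence_threshold))
  if (is.character(scans)) {
    map_sets <- lapply(scans, read_scan)
  } else if (inherits(scans, "elemental_map_set")) {
    map_sets <- list(scans)
  } else map_sets <- scans
  names(map_sets) <- vapply(map_sets, function(s) s$metadata$scan_id, character(1))

  masks <- list(); rois_by_scan <- list()
  for (sid in names(map_sets)) {
    seg <- tryCatch(segment_scan(map_sets[[sid]], config),
                    error = function(e) stopf("segmentation failed for scan '%s': %s",
                                              sid, conditionMessage(e)))
    masks[[sid]] <- seg$mask
    rois_by_scan[[sid]] <- seg$rois
    log <- c(log, sprintf("scan %s: %d regions found, %d rejected (<= %d px), %d cells kept",
                          sid, attr(seg$rois, "n_regions"),
                          attr(seg$rois, "n_rejected"), config$min_pixels,
                          length(seg$rois)))
  }
  all_rois <- do.call(c, c(unname(rois_by_scan), list(use.names = FALSE)))
  features <- build_feature_table(all_rois, map_sets,
                                  elements = config$elements,
                                  aggregator = config$aggregator)
  log <- c(log, sprintf("feature table: %d cells x %d features",
                        nrow(features), length(config$elements) + 2L))

  pca <- scores2 <- km <- fc <- flags <- treatment <- NULL
  recommendations <- list()
  if (nrow(features) >= max(2, config$k)) {
    pca <- fit_pca(feature_matrix(features))
    scores2 <- project(pca, n_components = min(config$n_components, ncol(pca$V)))
    km <- hard_kmeans(scores2, k = config$k, seed = config$seed)
    fc <- fuzzy_kmeans(scores2, k = config$k, m = config$m, seed = config$seed)
    flags <- flag_low_confidence(fc$confidence, config$confidence_threshold)
    log <- c(log, sprintf("clustering: k = %d, inertia = %.6g; %d/%d cells below confidence %g",
                          config$k, km$inertia, sum(flags), length(flags),
                          config$confidence_threshold))
    if (config$k == 2) {
      treatment <- tryCatch(assign_treatment_labels(fc, features),
                            error = function(e) {
                              warnf("treatment typing skipped: %s", conditionMessage(e))
                              NULL
                            })
    }
    info <- roi_info_table(all_rois)
    for (cl in seq_len(config$k)) {
      recommendations[[cl]] <- recommend_from_cluster(fc, cl, roi_info = info)
    }
  } else {
    log <- c(log, "clustering skipped: fewer cells than clusters")
    warnf("clustering skipped: %d cells < k = %d", nrow(features), config$k)
  }

  result <- list(map_sets = map_sets, masks = masks, rois = rois_by_scan,
                 features = features, pca = pca, scores = scores2,
                 kmeans = km, fuzzy = fc, flags = flags,
                 treatment = treatment, recommendations = recommendations,
                 log = log)
  if (!is.null(out_dir)) write_pipeline_artifacts(result, config, out_dir)
  invisible(result)
}

write_pipeline_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_rois <- do.call(c, c(unname(result$rois), list(use.names = FALSE)))
  write_rois_csv(all_rois, file.path(out_dir, "rois.csv"))
  write_feature_table(result$features, file.path(out_dir, "features.csv"))
  if (requireNamespace("png", quietly = TRUE)) {
    dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
    for (sid in names(result$masks)) {
      write_mask_png(result$masks[[sid]],
                     file.path(out_dir, "masks", paste0(sid, "_mask.png")))
    }
  }
  if (!is.null(result$pca)) {
    write_pca_model(result$pca, file.path(out_dir, "pca_model.json"))
    info <- roi_info_table(all_rois)
    W <- result$fuzzy$W
    clus <- data.frame(scan_id = info$scan_id, roi_id = info$roi_id,
                       hard_label = result$kmeans$labels,
                       stringsAsFactors = FALSE)
    for (j in seq_len(ncol(W))) clus[[paste0("w", j)]] <- W[, j]
    clus$confidence <- result$fuzzy$confidence
    clus$flagged <- result$flags
    clus$predicted_type <- if (!is.null(result$treatment)) {
      result$treatment$predicted
    } else NA_character_
    utils::write.csv(clus, file.path(out_dir, "clustering.csv"),
                     row.names = FALSE, quote = FALSE)
    for (cl in seq_along(result$recommendations)) {
      write_scan_request(result$recommendations[[cl]],
                         file.path(out_dir, sprintf("recommendation_cluster%d.json", cl)))
    }
  }
  writeLines(result$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
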