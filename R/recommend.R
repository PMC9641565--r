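# Fine-scan recommendation: nearest neighbors in the 2D PC plane,
# confidence-ranked cluster members, and stage-coordinate emission.
#
# Stage-coordinate convention: x runs along columns, y along rows; the
# metadata origin is the stage position of the scan's top-left pixel
# centre. Set `flip` arguments at the beamline-integration layer if the
# instrument's axes run the other way.

#' Recommend nearest neighbors of selected cells in PC space
#'
#' For each selected row, finds the non-selected, non-excluded row with the
#' smallest Euclidean distance in the 2D PC plane (ties broken toward the
#' lower row index). Results are de-duplicated (keeping each neighbor's
#' smallest distance) and sorted by increasing distance.
#'
#' @param selected Integer indices (1-based rows of `scores2d`) of the
#'   user-selected cells.
#' @param scores2d n x 2 matrix of PC scores.
#' @param exclude Additional indices never to recommend (e.g. already
#'   fine-scanned cells).
#' @param roi_info Optional data.frame aligned with `scores2d` rows carrying
#'   `scan_id`, `roi_id`, `centroid_y_um`, `centroid_x_um`; its columns are
#'   attached to the recommendation.
#' @return Object of class `xrf_recommendation` with `criterion =
#'   "nearest_neighbor"` and a `table` data.frame (columns `index`,
#'   `distance`, plus `roi_info` columns) sorted by distance.
#' @export
nearest_neighbor <- function(selected, scores2d, exclude = integer(0),
                             roi_info = NULL) {
  X <- as.matrix(scores2d)
  selected <- as.integer(selected)
  if (length(selected) == 0) stopf("selection is empty")
  candidates <- setdiff(seq_len(nrow(X)), union(selected, as.integer(exclude)))
  if (length(candidates) == 0) stopf("no candidate cells remain after exclusion")
  hits <- lapply(selected, function(s) {
    d <- sqrt(rowSums((X[candidates, , drop = FALSE] -
                         matrix(X[s, ], length(candidates), ncol(X), byrow = TRUE))^2))
    best <- candidates[which.min(d)]  # which.min: first minimum = lowest index
    c(index = best, distance = min(d))
  })
  tab <- as.data.frame(do.call(rbind, hits))
  tab <- tab[order(tab$distance, tab$index), , drop = FALSE]
  tab <- tab[!duplicated(tab$index), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(roi_info)) tab <- cbind(tab, roi_info[tab$index, , drop = FALSE])
  rownames(tab) <- NULL
  structure(list(criterion = "nearest_neighbor", source_selection = selected,
                 excluded = as.integer(exclude), table = tab),
            class = "xrf_recommendation")
}

#' Recommend confidence-ranked members of a cluster
#'
#' Returns members of the target cluster with confidence at least
#' `min_confidence`, sorted by decreasing confidence and truncated to
#' `n_recommend`.
#'
#' @param fc An `xrf_fcm`.
#' @param target_cluster Cluster index in `1..k`.
#' @param n_recommend Maximum number of cells to return.
#' @param min_confidence Minimum confidence to include.
#' @param roi_info Optional aligned data.frame; see [nearest_neighbor()].
#' @return `xrf_recommendation` with `criterion = "cluster_confidence"`; the
#'   table has columns `index`, `confidence` (+ `roi_info` columns). Empty
#'   with a warning if no member passes the filter.
#' @export
recommend_from_cluster <- function(fc, target_cluster, n_recommend = Inf,
                                   min_confidence = 0, roi_info = NULL) {
  if (!target_cluster %in% seq_len(fc$k)) {
    stopf("target_cluster must be in 1..%d", fc$k)
  }
  idx <- which(fc$hard_labels == target_cluster &
                 fc$confidence >= min_confidence)
  if (length(idx) == 0) {
    warnf("no cells in cluster %d pass min_confidence = %g",
          target_cluster, min_confidence)
  }
  ord <- idx[order(-fc$confidence[idx], idx)]
  ord <- utils::head(ord, n_recommend)
  tab <- data.frame(index = ord, confidence = fc$confidence[ord])
  if (!is.null(roi_info) && length(ord)) {
    tab <- cbind(tab, roi_info[ord, , drop = FALSE])
  }
  rownames(tab) <- NULL
  structure(list(criterion = "cluster_confidence",
                 target_cluster = target_cluster, table = tab),
            class = "xrf_recommendation")
}

#' @export
print.xrf_recommendation <- function(x, ...) {
  cat(sprintf("<xrf_recommendation> criterion = %s, %d cells\n",
              x$criterion, nrow(x$table)))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Convert an ROI centroid to stage coordinates
#'
#' `x = origin_x + centroid_col * pixel_step`,
#' `y = origin_y + centroid_row * pixel_step`, with the metadata origin at
#' the top-left pixel centre (origin stored in (y, x) order, result
#' returned in (x, y) order).
#'
#' @param roi An `xrf_roi`.
#' @param metadata The scan's [scan_metadata()].
#' @return Named numeric `(x, y)` in micrometres.
#' @export
roi_to_stage <- function(roi, metadata) {
  c(x = unname(metadata$origin[2] + roi$centroid_px[2] * metadata$pixel_step),
    y = unname(metadata$origin[1] + roi$centroid_px[1] * metadata$pixel_step))
}

#' Select scatter points inside a polygon in PC space
#'
#' Headless replacement for an interactive lasso selector: an even-odd-rule
#' point-in-polygon test over the 2D scores.
#'
#' @param scores2d n x 2 matrix.
#' @param polygon Vertex matrix (v x 2) of a closed polygon in the same
#'   coordinates (closure is implicit).
#' @return Integer indices of the rows inside the polygon.
#' @export
select_in_polygon <- function(scores2d, polygon) {
  X <- as.matrix(scores2d); P <- as.matrix(polygon)
  nv <- nrow(P)
  inside <- rep(FALSE, nrow(X))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- P[i, 1]; yi <- P[i, 2]; xj <- P[j, 1]; yj <- P[j, 2]
    crosses <- ((yi > X[, 2]) != (yj > X[, 2])) &
      (X[, 1] < (xj - xi) * (X[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  which(inside)
}

#' Write a recommendation as a minimal JSON scan request
#'
#' Emits the list of recommended fine-scan targets with stage coordinates,
#' consumable by acquisition control software.
#'
#' @param rec An `xrf_recommendation` whose table carries `scan_id`,
#'   `roi_id`, `centroid_y_um`, `centroid_x_um` columns (supply `roi_info`
#'   when building it).
#' @param path Output JSON path.
#' @param suggested_window Fine-scan window edge length in micrometres.
#' @return Invisibly, `path`.
#' @export
write_scan_request <- function(rec, path, suggested_window = 5) {
  tab <- rec$table
  needed <- c("scan_id", "roi_id", "centroid_y_um", "centroid_x_um")
  if (nrow(tab) > 0 && !all(needed %in% names(tab))) {
    stopf("recommendation table lacks ROI columns (%s); pass roi_info when recommending",
          paste(setdiff(needed, names(tab)), collapse = ", "))
  }
  targets <- lapply(seq_len(nrow(tab)), function(i) {
    list(scan_id = tab$scan_id[i], roi_id = tab$roi_id[i],
         x_um = tab$centroid_x_um[i], y_um = tab$centroid_y_um[i],
         suggested_window_um = suggested_window)
  })
  jsonlite::write_json(list(criterion = rec$criterion, targets = targets),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
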