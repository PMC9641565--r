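# Segmentation: composite image, Otsu threshold, binarization, ROI extraction.
#
# Pixel convention (package-wide): 0-based (row, col) coordinates, row-major
# raster order; bounding boxes are half-open [r0, r1) x [c0, c1).

#' Composite intensity image for segmentation
#'
#' Sums the named element channels into a single coarse intensity image;
#' by default K + P + S + Ca, the combination in which bacterial cells
#' contrast best against the background.
#'
#' @param map_set An [elemental_map_set()].
#' @param channels Channels to sum.
#' @return A numeric matrix of summed counts.
#' @export
composite_map <- function(map_set, channels = c("K", "P", "S", "Ca")) {
  sel <- select_channels(map_set, channels)
  Reduce(`+`, sel$channels)
}

#' 3x3 median filter with symmetric border padding
#'
#' Borders are edge-reflected (the edge row/column is mirrored), so output
#' dimensions equal input dimensions.
#'
#' @param image Numeric matrix.
#' @return Filtered matrix of the same dimensions.
#' @export
median_filter3 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  pr <- c(1L, seq_len(nr), nr)
  pc <- c(1L, seq_len(nc), nc)
  P <- image[pr, pc]
  # 9 shifted views as columns, then a vectorized 9-element sorting network
  cols <- vector("list", 9L)
  i <- 1L
  for (dr in 0:2) for (dc in 0:2) {
    cols[[i]] <- as.vector(P[dr + seq_len(nr), dc + seq_len(nc)])
    i <- i + 1L
  }
  for (pass in 1:8) {
    for (j in seq_len(9L - pass)) {
      lo <- pmin(cols[[j]], cols[[j + 1L]])
      hi <- pmax(cols[[j]], cols[[j + 1L]])
      cols[[j]] <- lo
      cols[[j + 1L]] <- hi
    }
  }
  matrix(cols[[5L]], nr, nc)
}

#' Otsu threshold over a fixed-width histogram
#'
#' Builds a 256-bin (by default) equal-width histogram over `[min, max]`
#' and returns the bin-edge threshold maximizing the between-class variance,
#' with class statistics computed from the exact pixel values falling in
#' each class. Ties are broken toward the lower threshold.
#'
#' @param image Numeric matrix or vector with at least two distinct values.
#' @param n_bins Number of histogram bins.
#' @return The scalar threshold `t`; foreground is `value > t`.
#' @export
otsu_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  mn <- min(x); mx <- max(x)
  if (mx <= mn) {
    cond <- simpleError("constant image: no Otsu threshold exists")
    class(cond) <- c("xrfroi_degenerate_image", class(cond))
    stop(cond)
  }
  w <- (mx - mn) / n_bins
  bin <- pmin(pmax(ceiling((x - mn) / w), 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  sm <- numeric(n_bins)
  agg <- rowsum(x, bin)
  sm[as.integer(rownames(agg))] <- agg[, 1]
  n <- length(x); tot <- sum(sm)
  cum_n <- cumsum(cnt)[-n_bins]
  cum_s <- cumsum(sm)[-n_bins]
  valid <- cum_n > 0 & cum_n < n
  bcv <- rep(-Inf, n_bins - 1L)
  mu0 <- cum_s[valid] / cum_n[valid]
  mu1 <- (tot - cum_s[valid]) / (n - cum_n[valid])
  bcv[valid] <- (cum_n[valid] / n) * ((n - cum_n[valid]) / n) * (mu0 - mu1)^2
  k <- which.max(bcv)  # which.max takes the first maximum: lower-threshold tie-break
  mn + k * w
}

#' Binarize a composite image into a cell/background mask
#'
#' Applies the 3x3 median filter, computes the Otsu threshold on the
#' filtered image, scales it by `otsu_multiplier` (default 1.25) and marks
#' pixels strictly above the scaled threshold as foreground (1 = cell,
#' 0 = background).
#'
#' @param image Numeric matrix (typically from [composite_map()]).
#' @param otsu_multiplier Multiplier applied to the raw Otsu value.
#' @param n_bins Histogram bins for [otsu_threshold()].
#' @return An object of class `segmentation_mask`: list with `mask`
#'   (integer 0/1 matrix), `threshold_used`, `otsu_raw`, `otsu_multiplier`.
#'   A constant (degenerate) image yields an all-zero mask with a warning.
#' @export
binarize <- function(image, otsu_multiplier = 1.25, n_bins = 256) {
  filtered <- median_filter3(image)
  otsu_raw <- tryCatch(otsu_threshold(filtered, n_bins),
                       xrfroi_degenerate_image = function(e) NA_real_)
  if (is.na(otsu_raw)) {
    warnf("degenerate (constant) image after filtering: background-only mask")
    mask <- matrix(0L, nrow(image), ncol(image))
    return(structure(list(mask = mask, threshold_used = NA_real_,
                          otsu_raw = NA_real_, otsu_multiplier = otsu_multiplier),
                     class = "segmentation_mask"))
  }
  threshold_used <- otsu_multiplier * otsu_raw
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[filtered > threshold_used] <- 1L
  structure(list(mask = mask, threshold_used = threshold_used,
                 otsu_raw = otsu_raw, otsu_multiplier = otsu_multiplier),
            class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat(sprintf("<segmentation_mask> %d x %d, %d foreground px, threshold %.4g (%.4g x Otsu %.4g)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold_used,
              x$otsu_multiplier, x$otsu_raw))
  invisible(x)
}

# 8-connected component labeling of a binary matrix. Returns an integer
# matrix of labels (0 = background), label ids in raster order of each
# component's first pixel.
label_components <- function(mask) {
  M <- mask > 0
  nr <- nrow(M); nc <- ncol(M)
  L <- matrix(0L, nr, nc)
  fg <- which(M)
  if (length(fg) == 0) return(L)
  edges_from <- integer(0); edges_to <- integer(0)
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr); r1 <- min(nr, nr - dr)
    c0 <- max(1L, 1L - dc); c1 <- min(nc, nc - dc)
    if (r0 > r1 || c0 > c1) next
    sub1 <- M[r0:r1, c0:c1, drop = FALSE]
    sub2 <- M[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc), drop = FALSE]
    hit <- which(sub1 & sub2)
    if (!length(hit)) next
    snr <- r1 - r0 + 1L
    rr <- ((hit - 1L) %% snr) + r0
    cc <- ((hit - 1L) %/% snr) + c0
    edges_from <- c(edges_from, (cc - 1L) * nr + rr)
    edges_to <- c(edges_to, (cc + dc - 1L) * nr + rr + dr)
  }
  v1 <- match(edges_from, fg); v2 <- match(edges_to, fg)
  g <- igraph::make_graph(as.vector(rbind(v1, v2)), n = length(fg),
                          directed = FALSE)
  memb <- igraph::components(g)$membership
  # renumber components by raster (row-major) order of their first pixel
  rr <- ((fg - 1L) %% nr)      # 0-based row
  cc <- ((fg - 1L) %/% nr)     # 0-based col
  raster_key <- rr * nc + cc
  first_key <- tapply(raster_key, memb, min)
  new_id <- integer(length(first_key))
  new_id[order(first_key)] <- seq_along(first_key)
  L[fg] <- new_id[memb]
  L
}

#' Extract candidate-cell ROIs from a segmentation mask
#'
#' Labels 8-connected foreground components and rejects any component of
#' `min_pixels` pixels or fewer (default: reject <= 8 px, keep >= 9 px),
#' which removes small image-processing artifacts. ROI ids are assigned in
#' raster order of each component's first pixel.
#'
#' @param mask A `segmentation_mask` from [binarize()], or a binary matrix.
#' @param metadata [scan_metadata()] used for scan id and stage coordinates.
#' @param min_pixels Exclusive size cutoff: components with
#'   `n_pixels <= min_pixels` are rejected.
#' @return A list of `xrf_roi` objects. Each has `roi_id`, `scan_id`,
#'   `pixels` (m x 2 integer matrix of 0-based (row, col)), `n_pixels`,
#'   `bbox` (half-open, `c(r0, r1, c0, c1)`), `centroid_px` (0-based
#'   (row, col)), `centroid_um` (named `(y, x)` stage coordinates). The list
#'   carries attributes `n_regions` (pre-filter) and `n_rejected`.
#' @export
extract_rois <- function(mask, metadata, min_pixels = 8) {
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  if (!all(m %in% c(0L, 1L, FALSE, TRUE))) stopf("mask must be binary")
  L <- label_components(m)
  n_comp <- max(L)
  rois <- list()
  n_rejected <- 0L
  nr <- nrow(m)
  next_id <- 1L
  for (comp in seq_len(n_comp)) {
    idx <- which(L == comp)
    if (length(idx) <= min_pixels) {
      n_rejected <- n_rejected + 1L
      next
    }
    r <- (idx - 1L) %% nr        # 0-based
    c <- (idx - 1L) %/% nr
    cen <- c(mean(r), mean(c))
    roi <- structure(list(
      roi_id = next_id,
      scan_id = metadata$scan_id,
      pixels = cbind(row = as.integer(r), col = as.integer(c)),
      n_pixels = length(idx),
      bbox = c(r0 = min(r), r1 = max(r) + 1L, c0 = min(c), c1 = max(c) + 1L),
      centroid_px = cen,
      centroid_um = c(y = metadata$origin[1] + cen[1] * metadata$pixel_step,
                      x = metadata$origin[2] + cen[2] * metadata$pixel_step)
    ), class = "xrf_roi")
    rois[[next_id]] <- roi
    next_id <- next_id + 1L
  }
  attr(rois, "n_regions") <- n_comp
  attr(rois, "n_rejected") <- n_rejected
  rois
}

#' @export
print.xrf_roi <- function(x, ...) {
  cat(sprintf("<xrf_roi> %s/%d: %d px, centroid (%.2f, %.2f) px, (%.2f, %.2f) um (y, x)\n",
              x$scan_id, x$roi_id, x$n_pixels, x$centroid_px[1], x$centroid_px[2],
              x$centroid_um[1], x$centroid_um[2]))
  invisible(x)
}

#' Write an ROI list to CSV
#'
#' @param rois List of `xrf_roi` from [extract_rois()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_rois_csv <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r) {
    data.frame(scan_id = r$scan_id, roi_id = r$roi_id, n_pixels = r$n_pixels,
               bbox_r0 = r$bbox[1], bbox_r1 = r$bbox[2],
               bbox_c0 = r$bbox[3], bbox_c1 = r$bbox[4],
               centroid_row = r$centroid_px[1], centroid_col = r$centroid_px[2],
               centroid_y_um = r$centroid_um[1], centroid_x_um = r$centroid_um[2],
               stringsAsFactors = FALSE)
  }))
  if (is.null(df)) {
    df <- data.frame(scan_id = character(), roi_id = integer(),
                     n_pixels = integer(), bbox_r0 = integer(), bbox_r1 = integer(),
                     bbox_c0 = integer(), bbox_c1 = integer(),
                     centroid_row = numeric(), centroid_col = numeric(),
                     centroid_y_um = numeric(), centroid_x_um = numeric())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a binary mask as an 8-bit PNG (0/1 values)
#'
#' @param mask A `segmentation_mask` or binary matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_mask_png <- function(mask, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stopf("the 'png' package is required to write PNG masks")
  }
  m <- if (inherits(mask, "segmentation_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m > 0), nrow(m), ncol(m)), path)
  invisible(path)
}
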