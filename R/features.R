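# Per-ROI features: morphology (area, eccentricity) and per-element
# fluorescence statistics. The canonical feature vector is
# (a, e, K, P, Ca, Zn, Fe): area, eccentricity and the maximum fluorescence
# count of each element over the ROI's pixels.

#' ROI area in pixels
#'
#' @param roi An `xrf_roi`.
#' @return Integer pixel count.
#' @export
roi_area <- function(roi) roi$n_pixels

#' ROI eccentricity
#'
#' Eccentricity of the ellipse with the same normalized second central
#' moments as the pixel region: with moment-ellipse axis terms
#' `lambda_major >= lambda_minor`,
#' `e = sqrt(1 - lambda_minor / lambda_major)`. The per-axis moment includes
#' the classical 1/12 pixel-extent term, so a single pixel is a tiny square
#' (e = 0) and even a 1-pixel-wide line has e strictly below 1.
#'
#' @param roi An `xrf_roi`.
#' @return Eccentricity in `[0, 1)`: 0 for a circle, near 1 for a line.
#' @export
roi_eccentricity <- function(roi) {
  r <- roi$pixels[, 1]; c <- roi$pixels[, 2]
  mu_rr <- mean((r - mean(r))^2) + 1 / 12
  mu_cc <- mean((c - mean(c))^2) + 1 / 12
  mu_rc <- mean((r - mean(r)) * (c - mean(c)))
  common <- sqrt(((mu_rr - mu_cc) / 2)^2 + mu_rc^2)
  l_major <- (mu_rr + mu_cc) / 2 + common
  l_minor <- (mu_rr + mu_cc) / 2 - common
  sqrt(1 - l_minor / l_major)
}

#' Per-ROI fluorescence statistic for one channel
#'
#' Applies an aggregator to the multiset of channel counts at the ROI's
#' pixels. The default, the maximum count, is the feature used for cell
#' typing; the mean is also built in, and any reduction function of one
#' numeric vector may be supplied.
#'
#' @param roi An `xrf_roi`.
#' @param grid Numeric matrix of one element channel (unfiltered counts).
#' @param aggregator `"max"`, `"mean"`, or a function `numeric -> scalar`.
#' @return Scalar statistic.
#' @export
roi_element_stat <- function(roi, grid, aggregator = "max") {
  pix <- roi$pixels
  if (any(pix[, 1] < 0 | pix[, 1] >= nrow(grid) |
          pix[, 2] < 0 | pix[, 2] >= ncol(grid))) {
    stopf("ROI %s/%s has pixels outside the channel grid", roi$scan_id, roi$roi_id)
  }
  vals <- grid[pix + 1L]
  f <- if (is.function(aggregator)) aggregator
       else switch(aggregator,
                   max = max, mean = mean,
                   stopf("unknown aggregator '%s'", aggregator))
  as.numeric(f(vals))
}

#' Build the feature table for a set of ROIs
#'
#' One row per ROI in roi-id order, with the canonical column order
#' `(a, e, <elements...>)` after the `scan_id`/`roi_id` keys. With the
#' defaults this is the 7-feature vector (a, e, K, P, Ca, Zn, Fe).
#'
#' @param rois List of `xrf_roi` from [extract_rois()] (one or several scans
#'   concatenated).
#' @param map_sets An [elemental_map_set()], or a named list of them keyed
#'   by `scan_id` when ROIs come from several scans.
#' @param elements Element channels to include as features.
#' @param aggregator Statistic over ROI pixels; see [roi_element_stat()].
#' @return A data.frame with columns `scan_id`, `roi_id`, `a`, `e`, then one
#'   column per element; attributes `elements` and `aggregator`.
#' @export
build_feature_table <- function(rois, map_sets,
                                elements = c("K", "P", "Ca", "Zn", "Fe"),
                                aggregator = "max") {
  single <- inherits(map_sets, "elemental_map_set")
  get_set <- function(scan_id) {
    if (single) return(map_sets)
    ms <- map_sets[[scan_id]]
    if (is.null(ms)) stopf("no map set supplied for scan '%s'", scan_id)
    ms
  }
  agg_name <- if (is.function(aggregator)) "custom" else aggregator
  rows <- lapply(rois, function(roi) {
    ms <- get_set(roi$scan_id)
    missing <- setdiff(elements, names(ms$channels))
    if (length(missing)) {
      stopf("channel not found: %s", paste(missing, collapse = ", "))
    }
    stats <- vapply(elements, function(el) {
      roi_element_stat(roi, ms$channels[[el]], aggregator)
    }, numeric(1))
    df <- data.frame(scan_id = roi$scan_id, roi_id = roi$roi_id,
                     a = roi_area(roi), e = roi_eccentricity(roi),
                     stringsAsFactors = FALSE)
    for (el in elements) df[[el]] <- stats[[el]]
    df
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    df <- data.frame(scan_id = character(0), roi_id = integer(0),
                     a = numeric(0), e = numeric(0), stringsAsFactors = FALSE)
    for (el in elements) df[[el]] <- numeric(0)
    df
  }
  # validate channel presence even when there are no ROIs
  if (length(rows) == 0 && single) {
    missing <- setdiff(elements, names(map_sets$channels))
    if (length(missing)) stopf("channel not found: %s", paste(missing, collapse = ", "))
  }
  rownames(tab) <- NULL
  attr(tab, "elements") <- elements
  attr(tab, "aggregator") <- agg_name
  tab
}

#' Numeric feature matrix from a feature table
#'
#' @param table Feature table from [build_feature_table()].
#' @return Numeric matrix `n x f` in canonical column order.
#' @export
feature_matrix <- function(table) {
  cols <- c("a", "e", attr(table, "elements") %||% c("K", "P", "Ca", "Zn", "Fe"))
  as.matrix(table[, cols, drop = FALSE])
}
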