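#' Scan metadata
#'
#' Per-scan acquisition metadata for one coarse XRF raster scan.
#'
#' @param scan_id Character scalar identifying the scan.
#' @param pixel_step Raster step size in micrometres (e.g. 0.25).
#' @param dwell_time Per-pixel X-ray exposure in milliseconds.
#' @param origin Stage coordinates of the top-left pixel centre in
#'   micrometres, given in (row-axis, col-axis) order — i.e. `(y, x)`,
#'   consistent with the package-wide (row, col) pixel convention. Stage
#'   scan requests emit `(x, y)`; see [roi_to_stage()].
#' @param shape Integer pair `(rows, cols)` of the scan grid.
#' @return An object of class `scan_metadata`.
#' @export
scan_metadata <- function(scan_id, pixel_step, dwell_time,
                          origin = c(0, 0), shape) {
  scan_id <- as.character(scan_id)[1]
  pixel_step <- as.numeric(pixel_step)[1]
  dwell_time <- as.numeric(dwell_time)[1]
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  if (!is.finite(pixel_step) || pixel_step <= 0) stopf("pixel_step must be > 0")
  if (!is.finite(dwell_time) || dwell_time <= 0) stopf("dwell_time must be > 0")
  if (length(origin) != 2 || any(!is.finite(origin))) {
    stopf("origin must be a finite (x, y) pair in um")
  }
  if (length(shape) != 2 || any(shape < 1L)) {
    stopf("shape must be (rows, cols) with both dimensions >= 1")
  }
  structure(
    list(scan_id = scan_id, pixel_step = pixel_step, dwell_time = dwell_time,
         origin = origin, shape = shape),
    class = "scan_metadata"
  )
}

#' @export
print.scan_metadata <- function(x, ...) {
  cat(sprintf("<scan_metadata> %s: %d x %d px, step %g um, dwell %g ms, origin (%g, %g) um\n",
              x$scan_id, x$shape[1], x$shape[2], x$pixel_step, x$dwell_time,
              x$origin[1], x$origin[2]))
  invisible(x)
}

#' Multi-channel elemental map set
#'
#' Bundles one coarse scan's per-element fluorescence count maps with its
#' acquisition metadata. All channel grids must share the metadata shape;
#' counts are non-negative (fitted counts that dip below zero from background
#' subtraction are clamped to 0 with a warning).
#'
#' @param metadata A [scan_metadata()] object.
#' @param channels Named list of numeric matrices, one per element channel,
#'   all of dimension `metadata$shape`.
#' @return An object of class `elemental_map_set`.
#' @export
elemental_map_set <- function(metadata, channels) {
  if (!inherits(metadata, "scan_metadata")) stopf("metadata must be a scan_metadata")
  if (!is.list(channels) || length(channels) == 0) {
    stopf("at least one channel is required")
  }
  nms <- names(channels)
  if (is.null(nms) || any(!nzchar(nms))) stopf("channels must be named")
  if (anyDuplicated(nms)) stopf("channel names must be unique")
  channels <- lapply(seq_along(channels), function(i) {
    g <- channels[[i]]
    if (!is.matrix(g) || !is.numeric(g)) {
      stopf("channel '%s' must be a numeric matrix", nms[i])
    }
    if (!all(dim(g) == metadata$shape)) {
      stopf("channel '%s' has shape %d x %d, expected %d x %d",
            nms[i], nrow(g), ncol(g), metadata$shape[1], metadata$shape[2])
    }
    if (anyNA(g)) stopf("channel '%s' contains NA counts", nms[i])
    if (any(g < 0)) {
      warnf("channel '%s': %d negative counts clamped to 0", nms[i], sum(g < 0))
      g[g < 0] <- 0
    }
    storage.mode(g) <- "double"
    g
  })
  names(channels) <- nms
  structure(list(metadata = metadata, channels = channels),
            class = "elemental_map_set")
}

#' @export
print.elemental_map_set <- function(x, ...) {
  print(x$metadata)
  cat(sprintf("  channels (%d): %s\n", length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Subset channels of a map set, preserving the requested order
#'
#' @param map_set An [elemental_map_set()].
#' @param channel_names Character vector of channel names to keep, in order.
#' @return An `elemental_map_set` with exactly those channels.
#' @export
select_channels <- function(map_set, channel_names) {
  missing <- setdiff(channel_names, names(map_set$channels))
  if (length(missing)) {
    stopf("channel not found: %s", paste(missing, collapse = ", "))
  }
  map_set$channels <- map_set$channels[channel_names]
  map_set
}

# ---------------------------------------------------------------------------
# HDF5 layout (native): group "/scan" carrying attributes scan_id (string),
# pixel_step_um, dwell_time_ms (floats), origin_um (float pair); one 2D
# float64 dataset per element under "/scan/channels/<NAME>". A sidecar
# attribute channel_order preserves channel ordering (HDF5 group members
# are name-sorted).

#' Write a scan to HDF5
#'
#' Stores the map set in the package's documented HDF5 layout (see Details).
#' Counts are stored as 64-bit floats, so the round trip through
#' [read_scan()] is lossless.
#'
#' @details Layout: group `/scan` with attributes `scan_id`, `pixel_step_um`,
#'   `dwell_time_ms`, `origin_um` and `channel_order`; one 2D float dataset
#'   per element channel under `/scan/channels/<NAME>`.
#'
#' @param map_set An [elemental_map_set()].
#' @param path Output file path (`.h5`); overwritten if present.
#' @return Invisibly, `path`.
#' @export
write_scan <- function(map_set, path) {
  if (!inherits(map_set, "elemental_map_set")) {
    stopf("map_set must be an elemental_map_set")
  }
  if (length(map_set$channels) == 0) stopf("at least one channel is required")
  if (file.exists(path) && unlink(path) != 0) stopf("cannot overwrite '%s'", path)
  ok <- tryCatch(rhdf5::h5createFile(path), error = function(e) FALSE)
  if (!isTRUE(ok)) stopf("cannot create HDF5 file '%s'", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "scan")
  rhdf5::h5createGroup(path, "scan/channels")
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, "scan")
  md <- map_set$metadata
  rhdf5::h5writeAttribute(md$scan_id, gid, "scan_id")
  rhdf5::h5writeAttribute(as.numeric(md$pixel_step), gid, "pixel_step_um")
  rhdf5::h5writeAttribute(as.numeric(md$dwell_time), gid, "dwell_time_ms")
  rhdf5::h5writeAttribute(as.numeric(md$origin), gid, "origin_um")
  rhdf5::h5writeAttribute(names(map_set$channels), gid, "channel_order")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  for (nm in names(map_set$channels)) {
    rhdf5::h5write(map_set$channels[[nm]], path, paste0("scan/channels/", nm))
  }
  invisible(path)
}

#' Read a scan from HDF5
#'
#' @param path Path to a scan file written by [write_scan()].
#' @param channel_names Optional character vector: return exactly these
#'   channels, in this order. Default: all stored channels in stored order.
#' @return An [elemental_map_set()].
#' @export
read_scan <- function(path, channel_names = NULL) {
  if (!file.exists(path)) stopf("scan file not found: '%s'", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  attrs <- tryCatch(rhdf5::h5readAttributes(path, "scan"),
                    error = function(e) stopf("'%s' is not a valid scan file", path))
  needed <- c("scan_id", "pixel_step_um", "dwell_time_ms", "origin_um")
  if (!all(needed %in% names(attrs))) {
    stopf("'%s': missing scan attributes (%s)", path,
          paste(setdiff(needed, names(attrs)), collapse = ", "))
  }
  stored <- as.character(attrs$channel_order %||%
                           rhdf5::h5ls(path)$name[rhdf5::h5ls(path)$group == "/scan/channels"])
  take <- if (is.null(channel_names)) stored else as.character(channel_names)
  missing <- setdiff(take, stored)
  if (length(missing)) {
    stopf("channel not found: %s", paste(missing, collapse = ", "))
  }
  channels <- lapply(take, function(nm) {
    g <- rhdf5::h5read(path, paste0("scan/channels/", nm))
    if (!is.matrix(g)) g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  names(channels) <- take
  shapes <- vapply(channels, dim, integer(2))
  if (ncol(shapes) > 1 && any(shapes[1, ] != shapes[1, 1] | shapes[2, ] != shapes[2, 1])) {
    stopf("'%s': stored channels disagree in shape", path)
  }
  md <- scan_metadata(
    scan_id = as.character(attrs$scan_id),
    pixel_step = as.numeric(attrs$pixel_step_um),
    dwell_time = as.numeric(attrs$dwell_time_ms),
    origin = as.numeric(attrs$origin_um),
    shape = dim(channels[[1]])
  )
  elemental_map_set(md, channels)
}

#' Best-effort reader for MAPS-style fitted .h5 files
#'
#' The per-pixel spectrum-fitting software commonly used at XRF beamlines
#' emits fitted count maps in an HDF5 layout that is not formally documented;
#' this adapter guesses the usual dataset paths (`/MAPS/XRF_roi` or
#' `/MAPS/XRF_fits`, with `/MAPS/channel_names`). It is provided as a
#' convenience for real beamline files and makes no round-trip guarantee;
#' [read_scan()] / [write_scan()] with the package's own layout are the
#' supported path.
#'
#' @param path Path to a MAPS-style `.h5` file.
#' @param channel_names Optional channel subset, in order.
#' @param pixel_step,dwell_time,origin Metadata not reliably recoverable from
#'   such files; supply them from the scan log.
#' @param scan_id Scan identifier; defaults to the file name.
#' @return An [elemental_map_set()].
#' @export
read_scan_maps <- function(path, channel_names = NULL, pixel_step = 0.25,
                           dwell_time = 100, origin = c(0, 0),
                           scan_id = basename(path)) {
  if (!file.exists(path)) stopf("scan file not found: '%s'", path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  paths <- paste(ls$group, ls$name, sep = "/")
  cube_path <- intersect(c("/MAPS/XRF_roi", "/MAPS/XRF_fits"), paths)
  name_path <- intersect("/MAPS/channel_names", paths)
  if (!length(cube_path) || !length(name_path)) {
    stopf("'%s' does not look like a MAPS-style file (no XRF_roi/XRF_fits cube)", path)
  }
  cube <- rhdf5::h5read(path, cube_path[1])
  nms <- as.character(rhdf5::h5read(path, name_path[1]))
  if (length(dim(cube)) != 3 || dim(cube)[3] != length(nms)) {
    # channel axis may come first in some exports
    if (length(dim(cube)) == 3 && dim(cube)[1] == length(nms)) {
      cube <- aperm(cube, c(2, 3, 1))
    } else {
      stopf("'%s': cannot align channel axis with channel_names", path)
    }
  }
  channels <- lapply(seq_along(nms), function(i) {
    g <- cube[, , i]
    g[g < 0] <- 0
    g
  })
  names(channels) <- nms
  md <- scan_metadata(scan_id, pixel_step, dwell_time, origin, dim(channels[[1]]))
  ms <- elemental_map_set(md, channels)
  if (!is.null(channel_names)) ms <- select_channels(ms, channel_names)
  ms
}

# ---------------------------------------------------------------------------
# Feature-table CSV

#' Write a feature table to CSV
#'
#' Columns: `scan_id`, `roi_id`, `area_px`, `eccentricity`, then one
#' `<aggregator>_<element>` column per element (e.g. `max_K`), plus
#' `true_label` when present.
#'
#' @param table A feature table from [build_feature_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(table, path) {
  elements <- attr(table, "elements") %||% c("K", "P", "Ca", "Zn", "Fe")
  agg <- attr(table, "aggregator") %||% "max"
  out <- data.frame(scan_id = table$scan_id, roi_id = table$roi_id,
                    area_px = table$a, eccentricity = table$e,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (el in elements) out[[paste0(agg, "_", el)]] <- table[[el]]
  if (!is.null(table$true_label)) out$true_label <- table$true_label
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Inverse of [write_feature_table()]; numeric columns round-trip to within
#' 1e-12 relative (values are written with full precision).
#'
#' @param path CSV path.
#' @return A feature table (data.frame) in canonical column order.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: '%s'", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("scan_id", "roi_id", "area_px", "eccentricity")
  if (!all(base_cols %in% names(raw))) {
    stopf("'%s' is not a feature-table CSV (missing %s)", path,
          paste(setdiff(base_cols, names(raw)), collapse = ", "))
  }
  stat_cols <- grep("^[a-zA-Z]+_[A-Z][a-z]?$", names(raw), value = TRUE)
  stat_cols <- setdiff(stat_cols, base_cols)
  if (length(stat_cols) == 0 && nrow(raw) >= 0) {
    stopf("'%s': no element statistic columns found", path)
  }
  agg <- unique(sub("_[A-Z][a-z]?$", "", stat_cols))
  if (length(agg) != 1) stopf("'%s': mixed aggregator prefixes (%s)",
                              path, paste(agg, collapse = ", "))
  elements <- sub("^[a-zA-Z]+_", "", stat_cols)
  tab <- data.frame(scan_id = as.character(raw$scan_id),
                    roi_id = as.integer(raw$roi_id),
                    a = as.numeric(raw$area_px),
                    e = as.numeric(raw$eccentricity),
                    stringsAsFactors = FALSE)
  for (i in seq_along(elements)) tab[[elements[i]]] <- as.numeric(raw[[stat_cols[i]]])
  if ("true_label" %in% names(raw)) tab$true_label <- as.character(raw$true_label)
  attr(tab, "elements") <- elements
  attr(tab, "aggregator") <- agg
  tab
}
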