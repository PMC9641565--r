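# Synthetic coarse-scan simulator with known ground truth.
#
# Emulates fitted-count XRF maps of plunge-frozen bacterial cells: elliptical
# cells with treatment-specific per-element expected count rates, a flat
# background rate, small speckle artifacts, and Poisson shot noise whose
# expectation scales linearly with dwell time.

#' Default per-element intensity profiles
#'
#' Expected fitted counts per pixel at the reference dwell time (100 ms).
#' The background rate applies everywhere; cell rates add nothing — inside
#' a cell the pixel rate is `background + cell rate`. The magnitudes are
#' simulator choices (no absolute count scale exists for the real system);
#' what matters is the qualitative ordering they encode: healthy (type A)
#' cells retain high intracellular K, ethanol-poisoned (type B) cells leak
#' K through the compromised inner membrane while showing elevated Ca, Zn
#' and P, and azide/copper-treated (type C) cells carry the highest K.
#'
#' @return Named list: `background` (named rate vector), one named rate
#'   vector per type (`A`, `B`, `C`), `artifact` (rates for speckle
#'   artifacts) and `reference_dwell` (ms).
#' @export
default_profiles <- function() {
  list(
    background = c(K = 2, P = 2, S = 2, Ca = 2, Zn = 2, Fe = 2),
    A = c(K = 60, P = 40, S = 30, Ca = 8,  Zn = 6,  Fe = 5),
    B = c(K = 15, P = 55, S = 30, Ca = 30, Zn = 20, Fe = 5),
    C = c(K = 90, P = 40, S = 30, Ca = 10, Zn = 8,  Fe = 5),
    artifact = c(K = 50, P = 50, S = 50, Ca = 50, Zn = 0, Fe = 0),
    reference_dwell = 100
  )
}

#' Specification of one planted cell
#'
#' @param center 0-based (row, col) pixel centre.
#' @param semi_axes `(a_major, a_minor)` in pixels, `a_major >= a_minor > 0`.
#' @param orientation Major-axis angle in radians (0 = along columns).
#' @param type_label One of `"A"`, `"B"`, `"C"`.
#' @param intensity Named per-element expected counts per pixel inside the
#'   cell, at the reference dwell.
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(center, semi_axes, orientation, type_label, intensity) {
  if (semi_axes[1] < semi_axes[2] || semi_axes[2] <= 0) {
    stopf("semi_axes must satisfy a_major >= a_minor > 0")
  }
  if (any(intensity < 0)) stopf("cell intensities must be >= 0")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation)[1],
                 type_label = as.character(type_label)[1],
                 intensity = intensity),
            class = "cell_spec")
}

#' Rasterize a cell spec into pixel coordinates
#'
#' A pixel belongs to the cell when its centre lies inside the ellipse
#' (centre-of-pixel inclusion), so area and eccentricity of the resulting
#' region track the closed-form ellipse values.
#'
#' @param spec A [cell_spec()].
#' @param shape Scan shape `(rows, cols)`; pixels outside are dropped.
#' @return Integer m x 2 matrix of 0-based (row, col) coordinates.
#' @export
rasterize_cell <- function(spec, shape) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]
  r0 <- spec$center[1]; c0 <- spec$center[2]
  th <- spec$orientation
  rmin <- max(0L, floor(r0 - a)); rmax <- min(shape[1] - 1L, ceiling(r0 + a))
  cmin <- max(0L, floor(c0 - a)); cmax <- min(shape[2] - 1L, ceiling(c0 + a))
  if (rmin > rmax || cmin > cmax) {
    return(cbind(row = integer(0), col = integer(0)))
  }
  rr <- rmin:rmax; cc <- cmin:cmax
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  dr <- R - r0; dc <- C - c0
  # major axis along columns when orientation = 0
  u <- dc * cos(th) + dr * sin(th)
  v <- -dc * sin(th) + dr * cos(th)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside)
  cbind(row = as.integer(R[idx]), col = as.integer(C[idx]))
}

# mark pixels plus a chebyshev-`radius` halo in a logical occupancy matrix
mark_dilated <- function(occ, pixels, radius = 2L) {
  nr <- nrow(occ); nc <- ncol(occ)
  for (dr in -radius:radius) for (dc in -radius:radius) {
    r <- pixels[, 1] + dr; c <- pixels[, 2] + dc
    ok <- r >= 0L & r < nr & c >= 0L & c < nc
    occ[cbind(r[ok] + 1L, c[ok] + 1L)] <- TRUE
  }
  occ
}

#' Generate a synthetic coarse scan with ground truth
#'
#' Plants non-overlapping elliptical cells of the requested treatment types
#' plus small speckle artifacts, then draws every pixel of every channel as
#' an independent Poisson variate with mean
#' `(background rate + local rate) * dwell_time / reference_dwell`.
#'
#' @param shape Scan shape `(rows, cols)` in pixels.
#' @param n_cells_by_type Named integer vector, e.g. `c(A = 10, B = 5)`.
#' @param dwell_time Dwell time in ms; expected counts scale with it.
#' @param profiles Profile configuration as from [default_profiles()].
#' @param artifact_count Number of speckle artifacts (1-8 px each) to plant.
#' @param seed Integer seed; the scan and ground truth are deterministic
#'   functions of it.
#' @param scan_id,pixel_step,origin Scan metadata (see [scan_metadata()]).
#' @param semi_major_range,semi_minor_range Uniform sampling ranges (px) for
#'   cell semi-axes. Defaults emulate rod-shaped bacteria at a 0.25 um step:
#'   lengths 2-3.5 um, widths 0.7-1.1 um.
#' @param max_retries Placement attempts per object before a placement error.
#' @return List with `map_set` (an [elemental_map_set()]) and `ground_truth`
#'   (class `xrf_ground_truth`: `cell_specs`, `labels`, `cell_pixels`,
#'   `true_mask` 0/1 matrix, `artifact_pixels`).
#' @export
generate_scan <- function(shape, n_cells_by_type, dwell_time = 100,
                          profiles = default_profiles(), artifact_count = 0,
                          seed = NULL, scan_id = "synthetic",
                          pixel_step = 0.25, origin = c(0, 0),
                          semi_major_range = c(4, 7),
                          semi_minor_range = c(1.4, 2.2),
                          max_retries = 200) {
  shape <- as.integer(shape)
  elements <- names(profiles$background)
  required <- c("K", "P", "S", "Ca", "Zn", "Fe")
  if (!all(required %in% elements)) {
    stopf("profiles must define at least channels %s",
          paste(required, collapse = ", "))
  }
  types <- names(n_cells_by_type)
  unknown <- setdiff(types, names(profiles))
  if (length(unknown)) stopf("no profile for cell type: %s", paste(unknown, collapse = ", "))
  for (ty in types) {
    extra <- setdiff(names(profiles[[ty]]), elements)
    if (length(extra)) stopf("unknown element in profile '%s': %s", ty,
                             paste(extra, collapse = ", "))
  }
  ref <- profiles$reference_dwell %||% 100
  seeds <- derive_seeds(seed, 2)
  scene <- with_seed(seeds[1], plant_scene(
    shape, n_cells_by_type, profiles, artifact_count,
    semi_major_range, semi_minor_range, max_retries))
  channels <- with_seed(seeds[2],
                        sample_counts(scene$rate, dwell_time, ref))
  md <- scan_metadata(scan_id, pixel_step, dwell_time, origin, shape)
  list(map_set = elemental_map_set(md, channels),
       ground_truth = scene$ground_truth)
}

# Plant the deterministic scene structure (cells + artifacts + rate maps)
# using the current RNG stream.
plant_scene <- function(shape, n_cells_by_type, profiles, artifact_count,
                        semi_major_range, semi_minor_range, max_retries) {
  elements <- names(profiles$background)
  types <- names(n_cells_by_type)
  {
    occ <- matrix(FALSE, shape[1], shape[2])   # dilated occupancy, no-go zone
    rate <- lapply(elements, function(el) {
      matrix(profiles$background[[el]], shape[1], shape[2])
    })
    names(rate) <- elements

    cell_specs <- list(); labels <- character(0); cell_pixels <- list()
    true_mask <- matrix(0L, shape[1], shape[2])
    for (ty in types) {
      for (i in seq_len(n_cells_by_type[[ty]])) {
        placed <- FALSE
        for (try in seq_len(max_retries)) {
          a <- stats::runif(1, semi_major_range[1], semi_major_range[2])
          b <- stats::runif(1, semi_minor_range[1], semi_minor_range[2])
          th <- stats::runif(1, 0, pi)
          cen <- c(stats::runif(1, a + 1, shape[1] - a - 2),
                   stats::runif(1, a + 1, shape[2] - a - 2))
          spec <- cell_spec(cen, c(a, b), th, ty, profiles[[ty]])
          pix <- rasterize_cell(spec, shape)
          if (nrow(pix) == 0 || any(occ[pix + 1L])) next
          occ <- mark_dilated(occ, pix, 2L)
          true_mask[pix + 1L] <- 1L
          for (el in names(profiles[[ty]])) {
            rate[[el]][pix + 1L] <- rate[[el]][pix + 1L] + profiles[[ty]][[el]]
          }
          cell_specs[[length(cell_specs) + 1L]] <- spec
          labels <- c(labels, ty)
          cell_pixels[[length(cell_pixels) + 1L]] <- pix
          placed <- TRUE
          break
        }
        if (!placed) stopf("could not place cell %d of type %s without overlap after %d retries",
                           i, ty, max_retries)
      }
    }

    art_rates <- profiles$artifact %||% c(K = 50, P = 50, S = 50, Ca = 50)
    artifact_pixels <- cbind(row = integer(0), col = integer(0))
    for (i in seq_len(artifact_count)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        size <- sample.int(8L, 1L)
        seed_px <- c(sample.int(shape[1] - 2L, 1L), sample.int(shape[2] - 2L, 1L))
        pix <- matrix(seed_px, 1, 2)
        while (nrow(pix) < size) {
          base <- pix[sample.int(nrow(pix), 1L), ]
          step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample.int(4L, 1L), ]
          cand <- base + step
          if (cand[1] < 0 || cand[1] >= shape[1] || cand[2] < 0 || cand[2] >= shape[2]) next
          if (!any(pix[, 1] == cand[1] & pix[, 2] == cand[2])) pix <- rbind(pix, cand)
        }
        if (any(occ[pix + 1L])) next
        occ <- mark_dilated(occ, pix, 2L)
        for (el in intersect(names(art_rates), elements)) {
          rate[[el]][pix + 1L] <- rate[[el]][pix + 1L] + art_rates[[el]]
        }
        artifact_pixels <- rbind(artifact_pixels, pix)
        placed <- TRUE
        break
      }
      if (!placed) stopf("could not place artifact %d without overlap after %d retries",
                         i, max_retries)
    }

    gt <- structure(list(cell_specs = cell_specs, labels = labels,
                         cell_pixels = cell_pixels, true_mask = true_mask,
                         artifact_pixels = artifact_pixels),
                    class = "xrf_ground_truth")
    list(rate = rate, ground_truth = gt)
  }
}

# Poisson counts at a given dwell from per-channel rate maps (rates are
# expected counts per pixel at the reference dwell). Current RNG stream.
sample_counts <- function(rate, dwell_time, reference_dwell) {
  scale <- dwell_time / reference_dwell
  lapply(rate, function(rt) {
    matrix(stats::rpois(length(rt), rt * scale), nrow(rt), ncol(rt))
  })
}

#' Generate one scene scanned at several dwell times
#'
#' Plants a single scene (cell placement, types, artifacts) and draws an
#' independent Poisson count realization of it at each requested dwell
#' time — the in-silico analogue of rescanning the same sample area faster.
#'
#' @inheritParams generate_scan
#' @param dwell_times Numeric vector of dwell times in ms, one scan each.
#' @return List with `map_sets` (list of [elemental_map_set()], one per
#'   dwell time, in input order) and `ground_truth` (shared).
#' @export
generate_scan_series <- function(shape, n_cells_by_type, dwell_times,
                                 profiles = default_profiles(),
                                 artifact_count = 0, seed = NULL,
                                 scan_id = "synthetic", pixel_step = 0.25,
                                 origin = c(0, 0),
                                 semi_major_range = c(4, 7),
                                 semi_minor_range = c(1.4, 2.2),
                                 max_retries = 200) {
  shape <- as.integer(shape)
  ref <- profiles$reference_dwell %||% 100
  seeds <- derive_seeds(seed, 1 + length(dwell_times))
  scene <- with_seed(seeds[1], plant_scene(
    shape, n_cells_by_type, profiles, artifact_count,
    semi_major_range, semi_minor_range, max_retries))
  map_sets <- lapply(seq_along(dwell_times), function(i) {
    channels <- with_seed(seeds[1 + i],
                          sample_counts(scene$rate, dwell_times[i], ref))
    md <- scan_metadata(sprintf("%s_dwell%g", scan_id, dwell_times[i]),
                        pixel_step, dwell_times[i], origin, shape)
    elemental_map_set(md, channels)
  })
  list(map_sets = map_sets, ground_truth = scene$ground_truth)
}

#' @export
print.xrf_ground_truth <- function(x, ...) {
  cat(sprintf("<xrf_ground_truth> %d cells (%s), %d artifact px\n",
              length(x$cell_specs),
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", "),
              nrow(x$artifact_pixels)))
  invisible(x)
}

#' Measure SNR across scans of the same scene
#'
#' Computes [snr()] of each scan's segmentation composite against the true
#' cell mask, in input order. All scans must share the scene shape.
#'
#' @param scans List of [elemental_map_set()] objects of one scene.
#' @param true_mask Binary reference mask of the scene (e.g.
#'   `ground_truth$true_mask`).
#' @param channels Channels summed for the intensity image.
#' @return Numeric vector of SNR values, one per scan, in input order.
#' @export
expected_snr_ordering <- function(scans, true_mask,
                                  channels = c("K", "P", "S", "Ca")) {
  if (length(scans) < 1) stopf("at least one scan is required")
  shapes <- vapply(scans, function(s) s$metadata$shape, integer(2))
  if (any(shapes[1, ] != nrow(true_mask) | shapes[2, ] != ncol(true_mask))) {
    stopf("all scans must match the reference mask shape")
  }
  vapply(scans, function(s) snr(composite_map(s, channels), true_mask), numeric(1))
}

#' Write ground truth to JSON / read it back
#'
#' Cell pixel sets and the mask are reconstructed from the stored specs by
#' [rasterize_cell()], which is deterministic, so the round trip is exact.
#'
#' @param gt An `xrf_ground_truth`.
#' @param path JSON path.
#' @param shape Scan shape used to re-rasterize on read.
#' @return `write_ground_truth`: invisibly `path`; `read_ground_truth`: an
#'   `xrf_ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  cells <- lapply(seq_along(gt$cell_specs), function(i) {
    s <- gt$cell_specs[[i]]
    list(center = s$center, semi_axes = s$semi_axes,
         orientation = s$orientation, type_label = s$type_label,
         intensity = as.list(s$intensity))
  })
  jsonlite::write_json(
    list(shape = dim(gt$true_mask), cells = cells,
         artifact_pixels = unname(gt$artifact_pixels)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path, shape = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- shape %||% as.integer(raw$shape)
  cells <- raw$cells
  specs <- list(); labels <- character(0); pixels <- list()
  true_mask <- matrix(0L, shape[1], shape[2])
  n <- if (is.data.frame(cells)) nrow(cells) else length(cells)
  for (i in seq_len(n)) {
    ci <- if (is.data.frame(cells)) lapply(cells, `[[`, i) else cells[[i]]
    spec <- cell_spec(unlist(ci$center), unlist(ci$semi_axes), ci$orientation,
                      ci$type_label, unlist(ci$intensity))
    pix <- rasterize_cell(spec, shape)
    true_mask[pix + 1L] <- 1L
    specs[[i]] <- spec; labels <- c(labels, spec$type_label); pixels[[i]] <- pix
  }
  ap <- raw$artifact_pixels
  ap <- if (length(ap)) matrix(as.integer(as.matrix(ap)), ncol = 2,
                               dimnames = list(NULL, c("row", "col")))
        else cbind(row = integer(0), col = integer(0))
  structure(list(cell_specs = specs, labels = labels, cell_pixels = pixels,
                 true_mask = true_mask, artifact_pixels = ap),
            class = "xrf_ground_truth")
}
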