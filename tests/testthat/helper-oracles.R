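# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately use naive loops and must stay
# independent of the package's code paths.

# 8-connected component labeling by BFS flood fill; returns a list of
# integer vectors of linear (column-major, 1-based) pixel indices.
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (cc in seq_len(nc)) for (rr in seq_len(nr)) {
    if (mask[rr, cc] <= 0 || seen[rr, cc]) next
    queue <- list(c(rr, cc)); seen[rr, cc] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      members <- c(members, (p[2] - 1L) * nr + p[1])
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] > 0 && !seen[r2, c2]) {
          seen[r2, c2] <- TRUE
          queue[[length(queue) + 1L]] <- c(r2, c2)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# Exhaustive Otsu search: classify raw pixels at each candidate bin edge and
# maximize the between-class variance directly.
oracle_otsu <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  mn <- min(x); mx <- max(x)
  w <- (mx - mn) / n_bins
  best_t <- NA_real_; best_v <- -Inf
  n <- length(x)
  for (k in 1:(n_bins - 1)) {
    t <- mn + k * w
    lo <- x[x <= t]; hi <- x[x > t]
    if (!length(lo) || !length(hi)) next
    v <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# Direct 3x3 median with symmetric (edge-repeating) padding, via loops.
oracle_median3 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  out <- matrix(NA_real_, nr, nc)
  clamp <- function(i, n) pmin(pmax(i, 1L), n)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- numeric(0)
    for (dr in -1:1) for (dc in -1:1) {
      vals <- c(vals, image[clamp(r + dr, nr), clamp(c + dc, nc)])
    }
    out[r, c] <- median(vals)
  }
  out
}

# Exhaustive dice: try every bijection clusters -> labels, counting the
# confusion entries with explicit loops.
oracle_dice_mean <- function(pred, true) {
  clusters <- sort(unique(pred)); labels <- sort(unique(true))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (r in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  best <- -Inf
  for (p in perms(labels)) {
    total <- 0
    for (i in seq_along(clusters)) {
      tp <- fp <- fn <- 0
      for (j in seq_along(pred)) {
        if (pred[j] == clusters[i] && true[j] == p[i]) tp <- tp + 1
        if (pred[j] == clusters[i] && true[j] != p[i]) fp <- fp + 1
        if (pred[j] != clusters[i] && true[j] == p[i]) fn <- fn + 1
      }
      total <- total + 2 * tp / (2 * tp + fp + fn)
    }
    best <- max(best, total / length(clusters))
  }
  best
}

# Brute-force nearest neighbor over all pairs.
oracle_nearest <- function(s, X, forbidden) {
  best_i <- NA_integer_; best_d <- Inf
  for (i in seq_len(nrow(X))) {
    if (i %in% forbidden) next
    d <- sqrt(sum((X[i, ] - X[s, ])^2))
    if (d < best_d - 1e-15) { best_d <- d; best_i <- i }
  }
  c(best_i, best_d)
}

# Build an ROI object directly from a 0-based pixel matrix (bypasses
# segmentation) for feature-level tests.
make_roi <- function(pixels, scan_id = "t", roi_id = 1L,
                     pixel_step = 0.25, origin = c(0, 0)) {
  pixels <- as.matrix(pixels)
  pixels <- matrix(as.integer(pixels), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  cen <- colMeans(pixels)
  structure(list(roi_id = roi_id, scan_id = scan_id, pixels = pixels,
                 n_pixels = nrow(pixels),
                 bbox = c(r0 = min(pixels[, 1]), r1 = max(pixels[, 1]) + 1L,
                          c0 = min(pixels[, 2]), c1 = max(pixels[, 2]) + 1L),
                 centroid_px = cen,
                 centroid_um = c(y = origin[1] + cen[1] * pixel_step,
                                 x = origin[2] + cen[2] * pixel_step)),
            class = "xrf_roi")
}

# Rasterize a 0-based solid ellipse independently of the package.
oracle_ellipse_pixels <- function(center, a, b, theta, shape) {
  out <- NULL
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1)) {
    u <- (c - center[2]) * cos(theta) + (r - center[1]) * sin(theta)
    v <- -(c - center[2]) * sin(theta) + (r - center[1]) * cos(theta)
    if ((u / a)^2 + (v / b)^2 <= 1) out <- rbind(out, c(r, c))
  }
  out
}

# Two well-separated Gaussian blobs in 2D.
make_blobs <- function(n_per = 20, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  X <- rbind(cbind(rnorm(n_per, 0, sd), rnorm(n_per, 0, sd)),
             cbind(rnorm(n_per, sep, sd), rnorm(n_per, sep, sd)))
  list(X = X, labels = rep(1:2, each = n_per))
}

# Small map set built by hand.
make_map_set <- function(channels, scan_id = "t", pixel_step = 0.25,
                         dwell = 100, origin = c(0, 0)) {
  md <- scan_metadata(scan_id, pixel_step, dwell, origin, dim(channels[[1]]))
  elemental_map_set(md, channels)
}
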