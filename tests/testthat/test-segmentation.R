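# Composite construction, Otsu thresholding, binarization and ROI
# extraction with artifact rejection.

test_that("composite map equals the per-pixel sum of the requested channels", {
  zero <- make_map_set(list(K = matrix(0, 5, 5), P = matrix(0, 5, 5),
                            S = matrix(0, 5, 5), Ca = matrix(0, 5, 5)))
  expect_true(all(composite_map(zero) == 0))

  const <- make_map_set(list(K = matrix(1, 3, 3), P = matrix(2, 3, 3),
                             S = matrix(3, 3, 3), Ca = matrix(4, 3, 3)))
  expect_true(all(composite_map(const) == 10))

  set.seed(11)
  rnd <- make_map_set(list(K = matrix(runif(256), 16), P = matrix(runif(256), 16),
                           S = matrix(runif(256), 16), Ca = matrix(runif(256), 16)))
  expected <- matrix(0, 16, 16)
  for (nm in c("K", "P", "S", "Ca")) {
    for (i in 1:16) for (j in 1:16) expected[i, j] <- expected[i, j] + rnd$channels[[nm]][i, j]
  }
  expect_equal(composite_map(rnd), expected)
  expect_error(composite_map(zero, c("K", "Cl")), "Cl")
})

test_that("otsu threshold separates a two-level image and matches the exhaustive oracle", {
  x <- matrix(rep(c(0, 10), each = 50), 10)
  t2 <- otsu_threshold(x)
  expect_gt(t2, 0); expect_lt(t2, 10)
  expect_equal(sum(x > t2), 50)

  set.seed(5)
  bimodal <- matrix(c(rnorm(600, 5, 1), rnorm(150, 25, 2)), 30)
  expect_equal(otsu_threshold(bimodal), oracle_otsu(bimodal), tolerance = 1e-12)

  set.seed(6)
  for (i in 1:5) {
    img <- matrix(rgamma(400, shape = sample(1:4, 1), rate = 0.3), 20)
    expect_equal(otsu_threshold(img), oracle_otsu(img), tolerance = 1e-12)
  }

  lone <- matrix(0, 100, 100); lone[40, 60] <- 50
  expect_lt(otsu_threshold(lone), 50)
  expect_error(otsu_threshold(matrix(3, 4, 4)), "constant")
})

test_that("median filter matches a direct 3x3 computation with reflected borders", {
  set.seed(12)
  img <- matrix(rpois(15 * 11, 9), 15, 11)
  expect_equal(median_filter3(img), oracle_median3(img))
  ramp <- matrix(seq_len(36), 6)
  expect_equal(median_filter3(ramp), oracle_median3(ramp))
})

test_that("binarize applies 1.25x the Otsu value of the filtered image", {
  img <- matrix(0, 20, 20)
  img[8:12, 8:12] <- 100                     # bright 5x5 square, no noise
  sm <- binarize(img)
  expect_equal(sm$threshold_used / sm$otsu_raw, 1.25)
  sq <- as.vector(outer(8:12, 8:12, function(r, c) (c - 1) * 20 + r))
  on <- which(sm$mask == 1)
  expect_true(all(on %in% sq))               # erosion only, no dilation
  expect_gte(length(on), 9)
  expect_equal(length(on), 21)               # square minus the 4 corners

  expect_warning(deg <- binarize(matrix(7, 10, 10)), "degenerate")
  expect_true(all(deg$mask == 0))
})

test_that("binarization is idempotent on stable masks and converges on noisy ones", {
  # the median-filtered bright square (a plus shape) is an exact fixed point
  img <- matrix(0, 20, 20); img[8:12, 8:12] <- 100
  m1 <- binarize(img)$mask
  expect_identical(binarize(m1 + 0)$mask, m1)

  # on a noisy-scan mask, repeated binarization erodes 1-px protrusions for
  # a step or two, then reaches an exactly idempotent fixed point
  sim <- generate_scan(c(80, 80), c(A = 4, B = 2), seed = 21)
  m <- binarize(composite_map(sim$map_set))$mask
  converged <- FALSE
  for (i in 1:30) {
    m_next <- binarize(m + 0)$mask
    if (identical(m_next, m)) { converged <- TRUE; break }
    m <- m_next
  }
  expect_true(converged)
})

test_that("ROI extraction uses 8-connectivity and rejects components of 8 pixels or fewer", {
  md <- scan_metadata("seg", 0.25, 100, c(0, 0), c(30, 30))
  empty <- matrix(0L, 30, 30)
  expect_identical(extract_rois(empty, md), structure(list(), n_regions = 0L,
                                                      n_rejected = 0L))

  two <- matrix(0L, 30, 30)
  two[2:3, 2:5] <- 1L                        # 8 px -> rejected
  two[10:12, 10:12] <- 1L                    # 9 px -> kept
  rois <- extract_rois(two, md)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$n_pixels, 9)
  expect_equal(attr(rois, "n_regions"), 2L)
  expect_equal(attr(rois, "n_rejected"), 1L)

  # diagonal chain is a single 8-connected component
  diag_mask <- matrix(0L, 30, 30)
  for (i in 1:12) diag_mask[i + 2, i + 2] <- 1L
  expect_length(extract_rois(diag_mask, md), 1)

  # components of sizes 1..20 in separate stripes: rejected exactly {1..8}
  sizes <- matrix(0L, 50, 90)
  for (s in 1:20) {
    r <- 2 + 2 * s
    sizes[r, 2:(1 + s)] <- 1L
  }
  kept <- extract_rois(sizes, md <- scan_metadata("sz", 0.25, 100, c(0, 0), c(50, 90)))
  expect_equal(sort(vapply(kept, `[[`, integer(1), "n_pixels")), 9:20)
  expect_equal(attr(kept, "n_rejected"), 8L)
})

test_that("component labeling agrees with a BFS flood-fill oracle", {
  set.seed(31)
  for (i in 1:4) {
    m <- matrix(rbinom(40 * 40, 1, 0.35), 40, 40)
    L <- xrfroi:::label_components(m)
    comps <- oracle_components(m)
    expect_equal(max(L), length(comps))
    got <- lapply(seq_len(max(L)), function(k) sort(which(L == k)))
    # same partition regardless of numbering
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(comps, paste, collapse = ","))
  }
})

test_that("ROIs are disjoint, lie inside the mask, and carry stage coordinates", {
  sim <- generate_scan(c(70, 70), c(A = 4), seed = 8,
                       origin = c(100, 200), pixel_step = 0.5)
  seg <- segment_scan(sim$map_set)
  all_pix <- do.call(rbind, lapply(seg$rois, `[[`, "pixels"))
  expect_equal(nrow(all_pix), nrow(unique(all_pix)))      # pairwise disjoint
  expect_true(all(seg$mask$mask[all_pix + 1L] == 1))      # subset of mask
  roi <- seg$rois[[1]]
  expect_equal(roi$centroid_um[["y"]], 100 + roi$centroid_px[1] * 0.5)
  expect_equal(roi$centroid_um[["x"]], 200 + roi$centroid_px[2] * 0.5)
  expect_equal(roi$bbox[["r1"]] - roi$bbox[["r0"]],
               max(roi$pixels[, 1]) - min(roi$pixels[, 1]) + 1)
})
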