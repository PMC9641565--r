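# Synthetic scan generator: determinism, noise statistics, ground truth.

test_that("a fixed seed reproduces maps and ground truth exactly", {
  a <- generate_scan(c(60, 60), c(A = 3, B = 2), artifact_count = 2, seed = 99)
  b <- generate_scan(c(60, 60), c(A = 3, B = 2), artifact_count = 2, seed = 99)
  expect_identical(a$map_set$channels, b$map_set$channels)
  expect_identical(a$ground_truth$true_mask, b$ground_truth$true_mask)
  expect_identical(a$ground_truth$labels, b$ground_truth$labels)
  c <- generate_scan(c(60, 60), c(A = 3, B = 2), artifact_count = 2, seed = 100)
  expect_false(identical(a$map_set$channels, c$map_set$channels))
})

test_that("an empty scene is background-only noise with an all-zero mask", {
  sim <- generate_scan(c(40, 40), c(), seed = 1)
  expect_true(all(sim$ground_truth$true_mask == 0))
  expect_length(sim$ground_truth$cell_specs, 0)
  # background-rate Poisson counts, nothing bright
  expect_lt(max(composite_map(sim$map_set)), 40)
})

test_that("Poisson noise has variance approximately equal to the mean on flat background", {
  sim <- generate_scan(c(120, 120), c(), dwell_time = 100, seed = 2)
  for (ch in c("K", "Ca")) {
    v <- as.numeric(sim$map_set$channels[[ch]])
    expect_equal(var(v), mean(v), tolerance = 0.2)
    expect_equal(mean(v), 2, tolerance = 0.2)     # background rate
  }
  # expectation scales with dwell time
  half <- generate_scan(c(120, 120), c(), dwell_time = 50, seed = 2)
  expect_equal(mean(half$map_set$channels$K), 1, tolerance = 0.25)
})

test_that("planted cells exceed background in every configured element", {
  sim <- generate_scan(c(80, 80), c(B = 5), seed = 4)
  inmask <- sim$ground_truth$true_mask == 1
  prof <- default_profiles()
  for (el in names(prof$B)) {
    if (prof$B[[el]] == 0) next
    expect_gt(mean(sim$map_set$channels[[el]][inmask]),
              mean(sim$map_set$channels[[el]][!inmask]))
  }
  # every cell's pixels lie inside the mask support
  for (pix in sim$ground_truth$cell_pixels) {
    expect_true(all(sim$ground_truth$true_mask[pix + 1L] == 1))
  }
})

test_that("types A and B separate in (max K, max Ca) expectation space", {
  prof <- default_profiles()
  # expected per-pixel rates: A is K-high/Ca-low, B the reverse
  expect_gt(prof$A[["K"]], prof$B[["K"]])
  expect_gt(prof$B[["Ca"]], prof$A[["Ca"]])
  sim <- generate_scan(c(140, 140), c(A = 8, B = 8), seed = 13)
  seg <- segment_scan(sim$map_set)
  tab <- build_feature_table(seg$rois, sim$map_set)
  truth <- match_rois_to_truth(seg$rois, sim$ground_truth)
  kA <- tab$K[truth$true_label == "A"]; kB <- tab$K[truth$true_label == "B"]
  expect_gt(min(kA), max(kB))             # linearly separable on max K alone
})

test_that("impossible placements and unknown profile elements raise errors", {
  expect_error(generate_scan(c(24, 24), c(A = 40), seed = 1, max_retries = 30),
               "place")
  bad <- default_profiles()
  bad$A <- c(bad$A, Xx = 5)
  expect_error(generate_scan(c(50, 50), c(A = 1), profiles = bad, seed = 1),
               "unknown element")
  expect_error(generate_scan(c(50, 50), c(D = 1), seed = 1), "no profile")
})

test_that("planted cells larger than 8 px are recovered one-to-one by segmentation", {
  sim <- generate_scan(c(150, 150), c(A = 10), seed = 17)
  seg <- segment_scan(sim$map_set)
  expect_length(seg$rois, 10)
  truth <- match_rois_to_truth(seg$rois, sim$ground_truth)
  expect_true(all(truth$iou > 0.5))
  expect_equal(sort(unique(truth$cell_index)), 1:10)   # one ROI per planted cell
})

test_that("speckle artifacts are all removed by the size filter", {
  sim <- generate_scan(c(120, 120), c(A = 4), artifact_count = 6, seed = 23)
  expect_gt(nrow(sim$ground_truth$artifact_pixels), 0)
  seg <- segment_scan(sim$map_set)
  truth <- match_rois_to_truth(seg$rois, sim$ground_truth)
  expect_length(seg$rois, 4)
  expect_true(all(!is.na(truth$cell_index)))     # every kept ROI is a real cell
  # no kept ROI touches an artifact pixel
  art <- sim$ground_truth$artifact_pixels
  art_id <- art[, 1] * 120 + art[, 2]
  for (roi in seg$rois) {
    roi_id <- roi$pixels[, 1] * 120 + roi$pixels[, 2]
    expect_length(intersect(roi_id, art_id), 0)
  }
})

test_that("ground truth survives a JSON round trip", {
  sim <- generate_scan(c(50, 50), c(A = 2, B = 1), artifact_count = 2, seed = 31)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$ground_truth, f)
  back <- read_ground_truth(f)
  expect_identical(back$true_mask, sim$ground_truth$true_mask)
  expect_identical(back$labels, sim$ground_truth$labels)
  expect_equal(back$artifact_pixels, sim$ground_truth$artifact_pixels,
               ignore_attr = TRUE)
})

test_that("SNR ordering over a dwell series reports one value per scan, in order", {
  series <- generate_scan_series(c(60, 60), c(C = 4),
                                 dwell_times = c(50, 25, 12.5), seed = 41)
  snrs <- expected_snr_ordering(series$map_sets, series$ground_truth$true_mask)
  expect_length(snrs, 3)
  expect_true(all(is.finite(snrs)))
  single <- expected_snr_ordering(series$map_sets[1], series$ground_truth$true_mask)
  expect_length(single, 1)
  expect_equal(single, snrs[1])
  # two scans at the same dwell agree within sampling error
  twin <- generate_scan_series(c(60, 60), c(C = 4), dwell_times = c(25, 25), seed = 41)
  s2 <- expected_snr_ordering(twin$map_sets, twin$ground_truth$true_mask)
  expect_equal(s2[1], s2[2], tolerance = 0.25)
})
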