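# Hard and fuzzy k-means, confidence, flagging, treatment typing.

test_that("hard k-means closed-form cases", {
  set.seed(1)
  X <- matrix(rnorm(40), 20, 2)
  km1 <- hard_kmeans(X, k = 1, seed = 5)
  expect_equal(km1$centers[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(km1$inertia, sum(sweep(X, 2, colMeans(X))^2))

  kmn <- hard_kmeans(X, k = 20, seed = 5)
  expect_equal(kmn$inertia, 0, tolerance = 1e-12)

  expect_error(hard_kmeans(X, k = 21, seed = 1), "at least")
})

test_that("hard k-means separates well-separated blobs and is seed-deterministic", {
  blobs <- make_blobs(25, sep = 10, sd = 1, seed = 3)
  km <- hard_kmeans(blobs$X, k = 2, seed = 11)
  agree <- max(mean((km$labels == 1) == (blobs$labels == 1)),
               mean((km$labels == 2) == (blobs$labels == 1)))
  expect_equal(agree, 1)
  km2 <- hard_kmeans(blobs$X, k = 2, seed = 11)
  expect_identical(km$labels, km2$labels)
  expect_identical(km$centers, km2$centers)
})

test_that("fuzzy weights: coincident point gets an indicator row, equidistant point splits evenly", {
  X <- rbind(c(0, 0), c(4, 0), c(2, 0), c(0.1, 0), c(3.9, 0))
  fc <- fuzzy_kmeans(X, k = 2, m = 2, seed = 7)
  expect_equal(rowSums(fc$W), rep(1, 5), tolerance = 1e-9)
  # by symmetry, converged centers straddle x = 2: middle point splits 50/50
  mid <- fc$W[3, ]
  expect_equal(unname(mid), c(0.5, 0.5), tolerance = 1e-6)
  # a point exactly at a converged center gets weight 1 there
  W <- xrfroi:::fcm_weights(X, centers = rbind(c(0.1, 0), c(3.9, 0)), m = 2)$W
  expect_equal(unname(W[4, ]), c(1, 0))
  expect_equal(unname(W[5, ]), c(0, 1))
})

test_that("converged fuzzy weights satisfy the membership formula (brute-force recomputation)", {
  set.seed(22)
  X <- rbind(matrix(rnorm(12, 0, 1), 6, 2), matrix(rnorm(12, 6, 1), 6, 2))
  fc <- fuzzy_kmeans(X, k = 2, m = 2, seed = 2, tol = 1e-12)
  W_direct <- matrix(NA_real_, 12, 2)
  for (i in 1:12) for (j in 1:2) {
    dij <- sqrt(sum((X[i, ] - fc$centers[j, ])^2))
    acc <- 0
    for (cc in 1:2) {
      dic <- sqrt(sum((X[i, ] - fc$centers[cc, ])^2))
      acc <- acc + (dij / dic)^(2 / (2 - 1))
    }
    W_direct[i, j] <- 1 / acc
  }
  expect_equal(fc$W, W_direct, tolerance = 1e-8)
  expect_true(all(diff(fc$objective_trace) <= 1e-10))
})

test_that("fuzzy clustering agrees with an independent fuzzy c-means implementation", {
  skip_if_not_installed("e1071")
  blobs <- make_blobs(15, sep = 8, sd = 1, seed = 6)
  fc <- fuzzy_kmeans(blobs$X, k = 2, m = 2, seed = 3, tol = 1e-12)
  ref <- e1071::cmeans(blobs$X, centers = 2, m = 2, iter.max = 500)
  # align cluster order by matching centers
  d1 <- sum((fc$centers[1, ] - ref$centers[1, ])^2) +
    sum((fc$centers[2, ] - ref$centers[2, ])^2)
  d2 <- sum((fc$centers[1, ] - ref$centers[2, ])^2) +
    sum((fc$centers[2, ] - ref$centers[1, ])^2)
  perm <- if (d1 <= d2) 1:2 else 2:1
  expect_equal(fc$centers, unname(ref$centers[perm, ]), tolerance = 1e-3)
  expect_equal(fc$W, unname(ref$membership[, perm]), tolerance = 1e-3)
})

test_that("m -> 1+ recovers hard k-means labels; m <= 1 is rejected", {
  blobs <- make_blobs(20, sep = 10, sd = 1, seed = 8)
  km <- hard_kmeans(blobs$X, k = 2, seed = 4)
  fc <- fuzzy_kmeans(blobs$X, k = 2, m = 1.05, seed = 4)
  agree <- max(mean(fc$hard_labels == km$labels),
               mean(fc$hard_labels == (3 - km$labels)))
  expect_equal(agree, 1)
  expect_error(fuzzy_kmeans(blobs$X, k = 2, m = 1), "hard_kmeans")
  expect_error(fuzzy_kmeans(blobs$X[1:1, , drop = FALSE], k = 2), "at least")
})

test_that("confidence is the rowwise maximum weight and grows toward the centers", {
  W <- rbind(c(0.5, 0.5), c(1, 0), c(0.3, 0.7))
  expect_equal(confidence(W), c(0.5, 1, 0.7))
  set.seed(12)
  Wr <- matrix(runif(30), 10, 3); Wr <- Wr / rowSums(Wr)
  brute <- numeric(10)
  for (i in 1:10) { b <- -Inf; for (j in 1:3) b <- max(b, Wr[i, j]); brute[i] <- b }
  expect_equal(confidence(Wr), brute)

  # 1-D two-center geometry: between boundary and center, confidence is
  # provably monotone in the distance from the decision boundary
  centers <- rbind(c(-2, 0), c(2, 0))
  xs <- c(0.2, 0.5, 1.0, 1.5, 1.9)
  conf <- vapply(xs, function(x) {
    max(xrfroi:::fcm_weights(matrix(c(x, 0), 1), centers, m = 2)$W)
  }, numeric(1))
  expect_true(all(diff(conf) > 0))
})

test_that("low-confidence flagging is strictly below the threshold", {
  expect_identical(flag_low_confidence(c(0.99, 0.9899999, 0.5, 1), 0.99),
                   c(FALSE, TRUE, TRUE, FALSE))
  expect_error(flag_low_confidence(0.5, 0), "threshold")
  expect_error(flag_low_confidence(0.5, 1.2), "threshold")
  # at threshold 1, everything except exact-center points is flagged
  blobs <- make_blobs(10, sep = 8, seed = 9)
  fc <- fuzzy_kmeans(blobs$X, k = 2, seed = 1)
  flags <- flag_low_confidence(fc$confidence, 1)
  expect_identical(flags, fc$confidence < 1)
})

test_that("the potassium heuristic labels the K-rich cluster type A", {
  sim <- generate_scan(c(180, 180), c(A = 12, B = 12), seed = 19)
  seg <- segment_scan(sim$map_set)
  tab <- build_feature_table(seg$rois, sim$map_set)
  truth <- match_rois_to_truth(seg$rois, sim$ground_truth)
  model <- fit_pca(standardize(feature_matrix(tab)))
  fc <- fuzzy_kmeans(project(model, n_components = 2), k = 2, seed = 5)
  res <- assign_treatment_labels(fc, tab)
  expect_gte(mean(res$predicted == truth$true_label), 0.9)
  # mapping itself: the cluster with higher mean K is "A"
  mk <- tapply(tab$K, fc$hard_labels, mean)
  expect_equal(unname(res$mapping[names(which.max(mk))]), "A")

  # swapping cluster indices leaves predictions unchanged
  fc_swapped <- fc
  fc_swapped$hard_labels <- 3L - fc$hard_labels
  fc_swapped$W <- fc$W[, 2:1]
  fc_swapped$centers <- fc$centers[2:1, ]
  res2 <- assign_treatment_labels(fc_swapped, tab)
  expect_identical(res2$predicted, res$predicted)

  # equal mean K -> tie error
  km <- list(k = 2, labels = c(1L, 1L, 2L, 2L))
  class(km) <- "xrf_kmeans"
  tie_tab <- data.frame(K = c(1, 3, 2, 2))
  expect_error(assign_treatment_labels(km, tie_tab), "manually")
  km3 <- list(k = 3, labels = c(1L, 2L, 3L)); class(km3) <- "xrf_kmeans"
  expect_error(assign_treatment_labels(km3, data.frame(K = 1:3)), "k = 3")
})
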