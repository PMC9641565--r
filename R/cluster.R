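# Hard k-means and fuzzy k-means on PC scores, membership confidence,
# low-confidence flagging and treatment-type assignment.

# k-means++ initial centers (D^2 sampling); draws from the current RNG stream
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  if (k > 1) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in 2:k) {
      pick <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
      centers[j, ] <- X[pick, ]
      nd <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
      d2 <- pmin(d2, nd)
    }
  }
  centers
}

#' Hard k-means clustering
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ starts, keeping
#' the best of `n_init` runs by within-cluster sum of squares (inertia).
#' Deterministic for a fixed seed. Should an initialization collapse to an
#' empty cluster, that run is restarted from a fresh k-means++ draw.
#'
#' @param scores n x d numeric matrix (typically the first two PC scores).
#' @param k Number of clusters, `1 <= k <= n`.
#' @param seed Integer seed (NULL: use the current RNG stream).
#' @param n_init Number of independent starts.
#' @param max_iter Maximum Lloyd iterations per start.
#' @return Object of class `xrf_kmeans`: `k`, `centers` (k x d), `labels`
#'   (1..k per row), `inertia`.
#' @export
hard_kmeans <- function(scores, k = 2, seed = NULL, n_init = 10, max_iter = 300) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (k < 1) stopf("k must be >= 1")
  if (n < k) stopf("need at least k = %d points, got %d", k, n)
  with_seed(seed, {
    best <- NULL
    for (i in seq_len(n_init)) {
      fit <- NULL
      for (attempt in 1:5) {
        init <- kmeanspp_init(X, k)
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(X, centers = init, iter.max = max_iter,
                                         algorithm = "Lloyd")),
          error = function(e) NULL)
        if (!is.null(fit)) break
      }
      if (is.null(fit)) stopf("k-means failed to find %d non-empty clusters", k)
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    structure(list(k = k, centers = unname(best$centers),
                   labels = as.integer(best$cluster),
                   inertia = best$tot.withinss),
              class = "xrf_kmeans")
  })
}

#' @export
print.xrf_kmeans <- function(x, ...) {
  cat(sprintf("<xrf_kmeans> k = %d, n = %d, inertia = %.4g\n",
              x$k, length(x$labels), x$inertia))
  invisible(x)
}

# membership weights given centers: w_ij = 1 / sum_c (d_ij / d_ic)^(2/(m-1));
# a point coincident with a center gets an indicator row.
fcm_weights <- function(X, centers, m) {
  n <- nrow(X); k <- nrow(centers)
  D2 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    D2[, j] <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
  }
  W <- matrix(0, n, k)
  zero_rows <- which(apply(D2, 1, function(d) any(d == 0)))
  reg_rows <- setdiff(seq_len(n), zero_rows)
  if (length(reg_rows)) {
    P <- D2[reg_rows, , drop = FALSE]^(-1 / (m - 1))
    W[reg_rows, ] <- P / rowSums(P)
  }
  for (i in zero_rows) {
    j <- which(D2[i, ] == 0)[1]
    W[i, j] <- 1
  }
  list(W = W, D2 = D2)
}

#' Fuzzy k-means (fuzzy c-means) clustering
#'
#' Minimizes `sum_i sum_j w_ij^m ||x_i - c_j||^2` subject to row-stochastic
#' membership weights `w_ij` by alternating the classical updates: weights
#' `w_ij = 1 / sum_c (||x_i - c_j|| / ||x_i - c_c||)^(2/(m-1))`, then
#' centers `c_j = sum_i w_ij^m x_i / sum_i w_ij^m`. The fuzziness `m`
#' defaults to 2; `m = 1` is hard clustering (use [hard_kmeans()]). A point
#' coincident with a center receives weight 1 there and 0 elsewhere. The
#' per-cell confidence is the largest membership weight.
#'
#' @param scores n x d numeric matrix.
#' @param k Number of clusters.
#' @param m Fuzziness, strictly greater than 1.
#' @param seed Integer seed, used for the hard k-means initialization.
#' @param max_iter Maximum alternating iterations.
#' @param tol Convergence threshold on `max |delta W|`.
#' @return Object of class `xrf_fcm`: `k`, `m`, `centers`, `W` (n x k,
#'   rows sum to 1), `objective`, `objective_trace`, `confidence`
#'   (rowwise max of W), `hard_labels` (rowwise argmax), `n_iter`.
#' @export
fuzzy_kmeans <- function(scores, k = 2, m = 2, seed = NULL,
                         max_iter = 300, tol = 1e-9) {
  X <- as.matrix(scores)
  n <- nrow(X)
  if (m <= 1) stopf("m must be > 1 for fuzzy clustering; use hard_kmeans() for m = 1")
  if (n < k) stopf("need at least k = %d points, got %d", k, n)
  centers <- hard_kmeans(X, k, seed = seed)$centers
  W_prev <- NULL
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    wd <- fcm_weights(X, centers, m)
    W <- wd$W
    trace <- c(trace, sum(W^m * wd$D2))
    if (!is.null(W_prev) && max(abs(W - W_prev)) < tol) break
    W_prev <- W
    Wm <- W^m
    centers <- (t(Wm) %*% X) / colSums(Wm)
  }
  conf <- do.call(pmax, as.data.frame(W))
  structure(list(k = k, m = m, centers = centers, W = W,
                 objective = trace[length(trace)], objective_trace = trace,
                 confidence = as.numeric(conf),
                 hard_labels = max.col(W, ties.method = "first"),
                 n_iter = it),
            class = "xrf_fcm")
}

#' @export
print.xrf_fcm <- function(x, ...) {
  cat(sprintf("<xrf_fcm> k = %d, m = %g, n = %d, objective = %.4g (%d iter)\n",
              x$k, x$m, nrow(x$W), x$objective, x$n_iter))
  invisible(x)
}

#' Per-cell clustering confidence
#'
#' The confidence metric of a cell is its largest cluster-membership weight;
#' values near 1/k mark borderline cells, artifacts or anomalies.
#'
#' @param fc An `xrf_fcm`, or an n x k weight matrix.
#' @return Numeric vector in `[1/k, 1]`.
#' @export
confidence <- function(fc) {
  W <- if (inherits(fc, "xrf_fcm")) fc$W else as.matrix(fc)
  apply(W, 1, max)
}

#' Flag cells whose confidence falls below a threshold
#'
#' Strictly below: a confidence exactly at the threshold is not flagged.
#'
#' @param conf Numeric confidences in `[0, 1]`.
#' @param threshold Cutoff in `(0, 1]`, default 0.99.
#' @return Logical vector, TRUE = low confidence.
#' @export
flag_low_confidence <- function(conf, threshold = 0.99) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stopf("threshold must lie in (0, 1]")
  }
  conf < threshold
}

#' Assign treatment-type labels to two clusters via the potassium heuristic
#'
#' Healthy cells frozen in a live state retain high intracellular K, while
#' membrane-compromised (poisoned) cells leak it; with two clusters, the
#' cluster with the higher mean K feature is therefore labeled type A
#' (healthy) and the other type B (poisoned). Defined only for k = 2.
#'
#' @param clustering An `xrf_kmeans` or `xrf_fcm` with k = 2.
#' @param feature_table Feature table aligned row-for-row with the clustered
#'   scores.
#' @param element Feature column driving the heuristic (default `"K"`).
#' @return List with `mapping` (cluster index -> "A"/"B") and `predicted`
#'   (per-cell labels).
#' @export
assign_treatment_labels <- function(clustering, feature_table, element = "K") {
  labels <- if (inherits(clustering, "xrf_fcm")) clustering$hard_labels
            else clustering$labels
  if (clustering$k != 2) {
    stopf("the K heuristic distinguishes two treatments; k = %d", clustering$k)
  }
  if (nrow(feature_table) != length(labels)) {
    stopf("feature table (%d rows) does not align with clustering (%d cells)",
          nrow(feature_table), length(labels))
  }
  vals <- feature_table[[element]]
  if (is.null(vals)) stopf("feature table has no '%s' column", element)
  m1 <- mean(vals[labels == 1]); m2 <- mean(vals[labels == 2])
  if (isTRUE(all.equal(m1, m2))) {
    stopf("clusters have equal mean %s; assign treatment types manually", element)
  }
  mapping <- if (m1 > m2) c("A", "B") else c("B", "A")
  list(mapping = stats::setNames(mapping, c("1", "2")),
       predicted = mapping[labels])
}
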