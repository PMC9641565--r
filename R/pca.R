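# PCA on the standardized feature table: principal axes, scores, loadings,
# explained-variance ratios.

#' Standardize a feature matrix
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1
#' (n - 1 denominator).
#'
#' @param X Numeric n x f matrix, n >= 2.
#' @return The standardized matrix with attributes `means` and `stds`.
#' @export
standardize <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stopf("standardization needs at least 2 rows")
  means <- colMeans(X)
  stds <- apply(X, 2, stats::sd)
  zero <- which(stds == 0 | !is.finite(stds))
  if (length(zero)) {
    nms <- colnames(X)[zero] %||% as.character(zero)
    stopf("zero-variance feature(s): %s", paste(nms, collapse = ", "))
  }
  Xs <- sweep(sweep(X, 2, means, `-`), 2, stds, `/`)
  attr(Xs, "means") <- means
  attr(Xs, "stds") <- stds
  Xs
}

#' Fit a PCA model
#'
#' Computes the singular value decomposition `Xs = U S V^T` of the
#' standardized data. The columns of `V` are the principal axes, ordered by
#' decreasing eigenvalue `lambda = s^2 / (n - 1)` of the covariance matrix
#' `C = X^T X / (n - 1)`; scores are the projections `Xs V`, and loadings
#' are `V S / (n - 1)`. Each axis's sign is fixed so that its
#' largest-magnitude coefficient is positive (first index on ties), making
#' repeated fits bit-comparable.
#'
#' @param X Raw or standardized feature matrix. A raw matrix is standardized
#'   internally; a matrix from [standardize()] is used as is.
#' @return Object of class `xrf_pca`: `n`, `f`, `feature_names`, `means`,
#'   `stds`, `V` (f x k), `eigenvalues`, `singular_values`, `scores`
#'   (n x k), `loadings` (f x k), `explained_ratio` (k = min(n, f)).
#' @export
fit_pca <- function(X) {
  Xs <- if (!is.null(attr(X, "means")) && !is.null(attr(X, "stds"))) X
        else standardize(X)
  n <- nrow(Xs); f <- ncol(Xs)
  if (n < 2) stopf("PCA needs at least 2 rows")
  sv <- svd(Xs)
  V <- sv$v; d <- sv$d; U <- sv$u
  # deterministic sign: largest-|coefficient| entry of each axis positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- Xs %*% V
  eigenvalues <- d^2 / (n - 1)
  loadings <- V %*% diag(d, length(d)) / (n - 1)
  feature_names <- colnames(Xs) %||% paste0("f", seq_len(f))
  rownames(V) <- rownames(loadings) <- feature_names
  colnames(V) <- colnames(loadings) <- colnames(scores) <-
    paste0("PC", seq_len(ncol(V)))
  structure(list(n = n, f = f, feature_names = feature_names,
                 means = attr(Xs, "means"), stds = attr(Xs, "stds"),
                 V = V, eigenvalues = eigenvalues, singular_values = d,
                 scores = scores, loadings = loadings,
                 explained_ratio = eigenvalues / sum(eigenvalues)),
            class = "xrf_pca")
}

#' @export
print.xrf_pca <- function(x, ...) {
  cat(sprintf("<xrf_pca> %d samples x %d features\n", x$n, x$f))
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", x$explained_ratio), collapse = " "), "\n")
  invisible(x)
}

#' Project data into the principal-component space of a fitted model
#'
#' New rows are standardized with the model's means and standard deviations
#' and projected on the first `n_components` principal axes. Two components
#' are the working space for clustering and recommendation.
#'
#' @param model An `xrf_pca`.
#' @param X_new Numeric matrix with the model's `f` columns. Defaults to the
#'   training scores.
#' @param n_components Number of leading components to keep.
#' @return n x n_components score matrix.
#' @export
project <- function(model, X_new = NULL, n_components = 2) {
  if (n_components > ncol(model$V)) {
    stopf("n_components (%d) exceeds available components (%d)",
          n_components, ncol(model$V))
  }
  if (is.null(X_new)) {
    return(model$scores[, seq_len(n_components), drop = FALSE])
  }
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != model$f) {
    stopf("X_new has %d columns, model expects %d", ncol(X_new), model$f)
  }
  Xs <- sweep(sweep(X_new, 2, model$means, `-`), 2, model$stds, `/`)
  Xs %*% model$V[, seq_len(n_components), drop = FALSE]
}

#' Scree: explained-variance ratio per component
#'
#' @param model An `xrf_pca`.
#' @return Non-increasing numeric vector summing to 1.
#' @export
scree <- function(model) model$explained_ratio

#' Serialize a PCA model to JSON / read it back
#'
#' @param model An `xrf_pca`.
#' @param path JSON path.
#' @return `write_pca_model`: invisibly `path`; `read_pca_model`: an
#'   `xrf_pca` (scores are not stored; refit or [project()] new data).
#' @export
write_pca_model <- function(model, path) {
  jsonlite::write_json(
    list(n = model$n, f = model$f, feature_names = model$feature_names,
         means = model$means, stds = model$stds,
         V = model$V, eigenvalues = model$eigenvalues,
         singular_values = model$singular_values,
         explained_ratio = model$explained_ratio),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  V <- as.matrix(raw$V)
  rownames(V) <- raw$feature_names
  means <- stats::setNames(as.numeric(raw$means), raw$feature_names)
  stds <- stats::setNames(as.numeric(raw$stds), raw$feature_names)
  structure(list(n = raw$n, f = raw$f, feature_names = raw$feature_names,
                 means = means, stds = stds, V = V,
                 eigenvalues = as.numeric(raw$eigenvalues),
                 singular_values = as.numeric(raw$singular_values),
                 scores = NULL,
                 loadings = V %*% diag(as.numeric(raw$singular_values),
                                       length(raw$singular_values)) / (raw$n - 1),
                 explained_ratio = as.numeric(raw$explained_ratio)),
            class = "xrf_pca")
}
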