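# Squared Euclidean cross-distances between the rows of A and B.
cross_dist2 <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Fit a generalized regression neural network
#'
#' A GRNN is a memory-based kernel regressor (Nadaraya-Watson with a
#' Gaussian kernel): fitting stores the training exemplars verbatim, and
#' prediction is a kernel-weighted average of the stored targets. There is
#' no iterative training, which is what makes the GRNN cheap enough to
#' serve as the error monitor inside wrapper feature selection.
#'
#' @param X Numeric matrix of descriptor vectors (rows = exemplars), with
#'   column names. Descriptors are expected on a standardized scale so the
#'   single isotropic bandwidth is meaningful.
#' @param y Numeric targets, one per row of `X`.
#' @param sigma Bandwidth (> 0), in standardized-descriptor units.
#' @return A `grnn` model storing `X`, `y`, `sigma` and the descriptor
#'   names.
#' @export
grnn_fit <- function(X, y, sigma) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit error: empty training set", call. = FALSE)
  if (length(y) != nrow(X)) {
    stop("fit error: length(y) != nrow(X)", call. = FALSE)
  }
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("validation error: non-finite entries in training data",
         call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("sigma must be a single positive number", call. = FALSE)
  }
  structure(
    list(X = X, y = as.numeric(y), sigma = sigma,
         descriptor_names = colnames(X)),
    class = "grnn"
  )
}

# Kernel-weighted predictions from a precomputed squared-distance matrix
# (queries x exemplars). Stabilized by subtracting the row-wise minimum
# squared distance, so the nearest exemplar always has weight 1 and the
# denominator can never underflow to zero.
grnn_predict_d2 <- function(d2, y, sigma) {
  m <- apply(d2, 1, min)
  w <- exp(-(d2 - m) / (2 * sigma^2))
  as.numeric(w %*% y) / rowSums(w)
}

#' Predict from a GRNN
#'
#' Returns the Gaussian-kernel weighted average of the stored targets,
#' `sum_i y_i exp(-d_i^2 / (2 sigma^2)) / sum_i exp(-d_i^2 / (2 sigma^2))`,
#' with `d_i` the Euclidean distance to exemplar `i`. Predictions are
#' convex combinations of the training targets and are numerically
#' stabilized so far-away queries degrade to the nearest exemplar rather
#' than 0/0.
#'
#' @param object A `grnn` model.
#' @param newdata Numeric matrix (or single vector) of query descriptor
#'   vectors; if it has column names they are aligned to the model's.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.grnn <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$descriptor_names)) {
    missing <- setdiff(object$descriptor_names, colnames(newdata))
    if (length(missing)) {
      stop("shape error: query missing descriptor(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    newdata <- newdata[, object$descriptor_names, drop = FALSE]
  }
  if (ncol(newdata) != ncol(object$X)) {
    stop("shape error: query has ", ncol(newdata),
         " descriptors, model expects ", ncol(object$X), call. = FALSE)
  }
  d2 <- cross_dist2(newdata, object$X)
  grnn_predict_d2(d2, object$y, object$sigma)
}

#' Default bandwidth grid
#'
#' Log-spaced grid of candidate GRNN bandwidths in standardized-descriptor
#' units.
#'
#' @param from,to Grid range.
#' @param length.out Number of grid points.
#' @export
grnn_sigma_grid <- function(from = 0.05, to = 2, length.out = 20) {
  exp(seq(log(from), log(to), length.out = length.out))
}

#' Select the GRNN bandwidth on a holdout set
#'
#' Fits a GRNN on the non-holdout rows and returns the grid bandwidth that
#' minimizes holdout RMSE; ties are broken toward the larger (smoother)
#' bandwidth.
#'
#' @param X Descriptor matrix (all rows).
#' @param y Targets.
#' @param holdout Integer row indices of the holdout set (disjoint from the
#'   fit rows, which are all remaining rows).
#' @param grid Candidate bandwidths (all > 0).
#' @return Selected bandwidth, with attributes `"rmse"` (its holdout RMSE)
#'   and `"grid_rmse"` (the full profile).
#' @export
grnn_select_bandwidth <- function(X, y, holdout, grid = grnn_sigma_grid()) {
  X <- as.matrix(X)
  holdout <- as.integer(holdout)
  if (length(holdout) == 0L) {
    stop("validation error: empty holdout set", call. = FALSE)
  }
  if (length(grid) == 0L || any(grid <= 0)) {
    stop("grid must be non-empty and positive", call. = FALSE)
  }
  fit_idx <- setdiff(seq_len(nrow(X)), holdout)
  if (length(fit_idx) == 0L) stop("no fit rows left", call. = FALSE)
  d2 <- cross_dist2(X[holdout, , drop = FALSE], X[fit_idx, , drop = FALSE])
  yf <- y[fit_idx]
  rmse <- vapply(grid, function(s) {
    sqrt(mean((grnn_predict_d2(d2, yf, s) - y[holdout])^2))
  }, numeric(1))
  best <- max(which(rmse <= min(rmse) + 1e-12))
  structure(grid[best], rmse = rmse[best],
            grid_rmse = stats::setNames(rmse, signif(grid, 4)))
}
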