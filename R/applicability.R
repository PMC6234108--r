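#' Fit a PCA applicability domain
#'
#' Performs correlation-matrix PCA (descriptors are standardized first;
#' their units are incommensurate) on the training descriptors, retains
#' the smallest number of components `k` reaching `variance_target` of the
#' total variance, and sets the in-domain threshold to the 0.975 quantile
#' of the chi-squared distribution with `k` degrees of freedom. Squared
#' Mahalanobis distances in the retained component space are approximately
#' chi-squared(k) for cases drawn from the training distribution, which
#' makes the quantile threshold distributionally coherent.
#'
#' @param train_table A `descriptor_table` of training compounds (cleaned:
#'   no zero-variance descriptors).
#' @param variance_target Fraction of variance to retain, in (0, 1].
#' @param quantile Chi-squared quantile for the threshold (default 0.975).
#' @return An `ad_model` with `center`, `scale`, `loadings` (p x k,
#'   orthonormal), `eigenvalues`, `k` and `threshold`.
#' @export
fit_ad <- function(train_table, variance_target = 0.95, quantile = 0.975) {
  stopifnot(inherits(train_table, "descriptor_table"),
            variance_target > 0, variance_target <= 1)
  sds <- apply(train_table$X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance descriptor(s): ",
         paste(colnames(train_table$X)[sds == 0], collapse = ", "),
         " (run clean_descriptors first)", call. = FALSE)
  }
  pr <- stats::prcomp(train_table$X, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  prop <- cumsum(ev) / sum(ev)
  k <- which(prop >= variance_target - 1e-12)[1]
  # never retain numerically null directions
  k <- min(k, sum(ev > 1e-10))
  structure(
    list(center = pr$center, scale = pr$scale,
         loadings = pr$rotation[, seq_len(k), drop = FALSE],
         eigenvalues = ev[seq_len(k)], k = as.integer(k),
         threshold = stats::qchisq(quantile, df = k),
         quantile = quantile, variance_target = variance_target),
    class = "ad_model"
  )
}

#' @export
print.ad_model <- function(x, ...) {
  cat(sprintf("ad_model: %d component(s) (%.0f%% variance target), chi-squared(%d) %.3f quantile threshold = %.3f\n",
              x$k, 100 * x$variance_target, x$k, x$quantile, x$threshold))
  invisible(x)
}

ad_scores <- function(model, X) {
  missing <- setdiff(rownames(model$loadings), colnames(X))
  if (length(missing)) {
    stop("schema error: missing descriptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- X[, rownames(model$loadings), drop = FALSE]
  Xs <- sweep(X, 2, model$center[colnames(X)], "-")
  Xs <- sweep(Xs, 2, model$scale[colnames(X)], "/")
  Xs %*% model$loadings
}

#' Squared distance of cases from the applicability-domain centre
#'
#' Squared Mahalanobis distance in the retained principal-component space:
#' `sum_j score_j^2 / eigenvalue_j`. The training mean scores exactly 0.
#'
#' @param model An `ad_model`.
#' @param x A `descriptor_table`, a named numeric vector, or a matrix with
#'   the model's descriptor columns.
#' @return Numeric vector of squared distances (>= 0).
#' @export
ad_distance <- function(model, x) {
  stopifnot(inherits(model, "ad_model"))
  if (inherits(x, "descriptor_table")) {
    X <- x$X
  } else if (is.null(dim(x))) {
    X <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  } else {
    X <- as.matrix(x)
  }
  S <- ad_scores(model, X)
  d2 <- as.numeric(sweep(S^2, 2, model$eigenvalues, "/") %*%
                     rep(1, model$k))
  stats::setNames(d2, rownames(X))
}

#' Flag compounds outside the applicability domain
#'
#' A compound is out of domain when its squared PC-space distance exceeds
#' the chi-squared threshold.
#'
#' @param model An `ad_model`.
#' @param table A `descriptor_table`.
#' @return Data frame (`compound_id`, `distance`, `outside`) in table row
#'   order, with attribute `"flagged"`: the out-of-domain ids sorted by
#'   distance, largest first.
#' @export
ad_flag <- function(model, table) {
  stopifnot(inherits(table, "descriptor_table"))
  d2 <- ad_distance(model, table)
  out <- data.frame(compound_id = table$ids, distance = as.numeric(d2),
                    outside = as.numeric(d2) > model$threshold,
                    stringsAsFactors = FALSE)
  flagged <- out[out$outside, , drop = FALSE]
  attr(out, "flagged") <- flagged$compound_id[order(-flagged$distance)]
  out
}
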