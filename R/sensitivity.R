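sensitivity_eval_ids <- function(table, split, eval_ids) {
  if (!is.null(eval_ids)) return(eval_ids)
  if (!is.null(split)) {
    ids <- c(split$verify_ids, split$test_ids)
    if (length(ids)) return(ids)
    return(split$train_ids)
  }
  table$ids
}

#' Descriptor-importance error ratio
#'
#' Quantifies how much a model relies on one descriptor by degrading that
#' descriptor and measuring the inflation of prediction error:
#' `ratio = degraded RMSE / baseline RMSE`. A ratio near 1 marks an
#' unimportant descriptor; ratios well above 1 mark important ones.
#'
#' Two degradation modes: `"mean_substitution"` (default) replaces the
#' descriptor column with its training mean and re-predicts with the fixed
#' model — a descriptor the model provably ignores scores exactly 1;
#' `"retrain"` refits the same architecture without the descriptor and
#' compares.
#'
#' @param model A `trained_model`.
#' @param table A `descriptor_table` with observed logBCF.
#' @param descriptor Descriptor name to degrade.
#' @param split A `split_assignment`; the evaluation subset defaults to
#'   verification + test rows (importance should reflect generalization
#'   error). Required for `"retrain"` mode.
#' @param mode `"mean_substitution"` or `"retrain"`.
#' @param eval_ids Optional explicit evaluation ids (overrides `split`).
#' @return The error ratio (> 0), with attributes `"baseline_rmse"` and
#'   `"degraded_rmse"`.
#' @export
error_ratio <- function(model, table, descriptor, split = NULL,
                        mode = c("mean_substitution", "retrain"),
                        eval_ids = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "trained_model"))
  if (!descriptor %in% model$descriptor_names) {
    stop("schema error: '", descriptor, "' is not a model descriptor",
         call. = FALSE)
  }
  ids <- sensitivity_eval_ids(table, split, eval_ids)
  eval_tbl <- subset_rows(table, ids)
  obs <- eval_tbl$logbcf
  base_pred <- predict(model, eval_tbl)
  baseline <- sqrt(mean((base_pred - obs)^2))

  degraded <- switch(mode,
    mean_substitution = {
      deg_tbl <- eval_tbl
      deg_tbl$X[, descriptor] <- model$train_center_raw[descriptor]
      sqrt(mean((predict(model, deg_tbl) - obs)^2))
    },
    retrain = {
      if (is.null(split)) {
        stop("retrain mode needs the training split", call. = FALSE)
      }
      keep <- setdiff(model$descriptor_names, descriptor)
      reduced <- model
      reduced$descriptor_names <- keep
      refit <- retrain_cross_species(
        reduced, subset_descriptors(table, keep), split)
      sqrt(mean((predict(refit, subset_rows(subset_descriptors(table, keep),
                                            ids)) - obs)^2))
    }
  )
  structure(degraded / baseline, baseline_rmse = baseline,
            degraded_rmse = degraded)
}

#' Rank descriptors by error ratio
#'
#' Computes [error_ratio()] for every model descriptor and sorts the
#' ratios in decreasing order (ties broken alphabetically, so the report
#' is deterministic). Because the error ratio of strongly collinear
#' descriptors is unreliable — degrading one leaves its redundant partner
#' to carry the signal — any descriptor involved in a pair with absolute
#' Pearson correlation above `collinearity_cutoff` is annotated with its
#' partners.
#'
#' @inheritParams error_ratio
#' @param collinearity_cutoff Absolute correlation above which a pair is
#'   flagged (default 0.65).
#' @return A `sensitivity_report`: list with `ranking` (data frame
#'   `descriptor`, `error_ratio`, `collinear_with`), `baseline_rmse`,
#'   `mode`, `eval_ids` and `collinear_pairs`.
#' @export
rank_descriptors <- function(model, table, split = NULL,
                             mode = c("mean_substitution", "retrain"),
                             eval_ids = NULL, collinearity_cutoff = 0.65) {
  mode <- match.arg(mode)
  ids <- sensitivity_eval_ids(table, split, eval_ids)
  ratios <- vapply(model$descriptor_names, function(d) {
    as.numeric(error_ratio(model, table, d, split = split, mode = mode,
                           eval_ids = ids))
  }, numeric(1))
  baseline <- attr(error_ratio(model, table, model$descriptor_names[1],
                               split = split, mode = "mean_substitution",
                               eval_ids = ids), "baseline_rmse")

  X <- subset_descriptors(table, model$descriptor_names)$X
  R <- stats::cor(X)
  pairs <- which(abs(R) > collinearity_cutoff & upper.tri(R), arr.ind = TRUE)
  collinear_pairs <- data.frame(
    a = rownames(R)[pairs[, 1]], b = colnames(R)[pairs[, 2]],
    r = R[pairs], stringsAsFactors = FALSE)
  partners <- function(d) {
    with <- c(collinear_pairs$b[collinear_pairs$a == d],
              collinear_pairs$a[collinear_pairs$b == d])
    if (length(with)) paste(sort(with), collapse = ";") else ""
  }
  ranking <- data.frame(
    descriptor = model$descriptor_names,
    error_ratio = unname(ratios),
    collinear_with = vapply(model$descriptor_names, partners, character(1)),
    stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$error_ratio, ranking$descriptor), ]
  rownames(ranking) <- NULL
  if (nrow(collinear_pairs)) {
    warning("error ratios of collinear descriptors are unreliable: ",
            paste(sprintf("%s-%s (r = %.2f)", collinear_pairs$a,
                          collinear_pairs$b, collinear_pairs$r),
                  collapse = ", "), call. = FALSE)
  }
  structure(
    list(ranking = ranking, baseline_rmse = baseline, mode = mode,
         eval_ids = ids, collinear_pairs = collinear_pairs),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity_report (%s): baseline RMSE %.4f on %d cases\n",
              x$mode, x$baseline_rmse, length(x$eval_ids)))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}
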