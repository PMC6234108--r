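#' Regression performance metrics
#'
#' RMSE (root of the mean squared residual), MAE (mean absolute residual)
#' and R-squared defined as the squared Pearson correlation between
#' observed and predicted values — the "correlation coefficient R2"
#' convention, which differs from `1 - SS_res/SS_tot` for biased
#' predictors. If either vector has zero variance, R2 is undefined and
#' reported as `NA` with a warning.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A `metrics` list: `n`, `rmse`, `mae`, `r2`.
#' @export
compute_metrics <- function(observed, predicted) {
  observed <- as.numeric(observed)
  predicted <- as.numeric(predicted)
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  if (length(observed) < 1L) stop("need at least one case", call. = FALSE)
  res <- predicted - observed
  r2 <- if (length(observed) < 2L || stats::sd(observed) == 0 ||
            stats::sd(predicted) == 0) {
    warning("R2 undefined: zero variance in observed or predicted values",
            call. = FALSE)
    NA_real_
  } else {
    stats::cor(observed, predicted)^2
  }
  structure(
    list(n = length(observed), rmse = sqrt(mean(res^2)),
         mae = mean(abs(res)), r2 = r2),
    class = "metrics"
  )
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("n = %d, RMSE = %.4f, MAE = %.4f, R2 = %s\n", x$n, x$rmse,
              x$mae, ifelse(is.na(x$r2), "NA", sprintf("%.4f", x$r2))))
  invisible(x)
}

#' Per-subset metrics for a trained model
#'
#' Convenience wrapper producing the training / verification / test rows
#' of a model-comparison table.
#'
#' @param model A `trained_model`.
#' @param table A `descriptor_table` with observed logBCF.
#' @param split A `split_assignment`.
#' @return Data frame with one row per non-empty subset: `subset`, `n`,
#'   `rmse`, `mae`, `r2`.
#' @export
metrics_by_subset <- function(model, table, split) {
  subsets <- list(training = split$train_ids, verification = split$verify_ids,
                  test = split$test_ids)
  rows <- lapply(names(subsets), function(nm) {
    ids <- subsets[[nm]]
    if (length(ids) == 0L) return(NULL)
    sub <- subset_rows(table, ids)
    m <- compute_metrics(sub$logbcf, predict(model, sub))
    data.frame(subset = nm, n = m$n, rmse = m$rmse, mae = m$mae, r2 = m$r2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Repeated k-fold cross-validation
#'
#' Random k-fold resampling repeated `repeats` times; every compound
#' appears in a held-out fold exactly once per repeat. For each fold the
#' supplied `fit` function is trained on the remaining rows and scored on
#' the fold; scores are aggregated across all `k * repeats` evaluations.
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param fit Function `(table, split) -> trained_model`; it receives a
#'   `split_assignment` whose `train_ids` are the non-fold rows and whose
#'   `test_ids` are the fold (verify is empty — carve a verification set
#'   out of the training ids inside `fit` if the learner needs one).
#' @param k Number of folds (default 10).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed.
#' @return List with `scores` (data frame `repeat_`, `fold`, `n`, `rmse`,
#'   `r2`), `rmse_mean`, `rmse_sd`, `r2_mean`, `r2_sd`.
#' @export
repeated_kfold <- function(table, fit, k = 10, repeats = 5, seed = 1L) {
  n <- n_compounds(table)
  if (k < 2L) stop("fold error: k must be >= 2", call. = FALSE)
  if (n < k) stop("fold error: n (", n, ") < k (", k, ")", call. = FALSE)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    assignment <- sample(rep(seq_len(k), length.out = n))
    for (fold in seq_len(k)) {
      fold_ids <- table$ids[assignment == fold]
      train_ids <- setdiff(table$ids, fold_ids)
      split <- structure(list(train_ids = train_ids,
                              verify_ids = character(0),
                              test_ids = fold_ids, seed = seed),
                         class = "split_assignment")
      model <- fit(table, split)
      sub <- subset_rows(table, fold_ids)
      m <- suppressWarnings(compute_metrics(sub$logbcf, predict(model, sub)))
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = rep_i, fold = fold, n = m$n, rmse = m$rmse, r2 = m$r2)
    }
  }
  scores <- do.call(rbind, rows)
  list(scores = scores,
       rmse_mean = mean(scores$rmse), rmse_sd = stats::sd(scores$rmse),
       r2_mean = mean(scores$r2, na.rm = TRUE),
       r2_sd = stats::sd(scores$r2, na.rm = TRUE))
}

#' REACH bioaccumulation thresholds
#'
#' Default category boundaries on the BCF scale follow REACH Annex XIII:
#' bioaccumulative (B) above 2000 L/kg, very bioaccumulative (vB) above
#' 5000 L/kg. Configurable because regulatory regimes differ.
#'
#' @param b_threshold BCF above which a compound is B (default 2000).
#' @param vb_threshold BCF above which a compound is vB (default 5000).
#' @return A `pbt_thresholds` list.
#' @export
pbt_thresholds <- function(b_threshold = 2000, vb_threshold = 5000) {
  if (!(b_threshold > 0 && vb_threshold > b_threshold)) {
    stop("need 0 < b_threshold < vb_threshold", call. = FALSE)
  }
  structure(list(b_threshold = b_threshold, vb_threshold = vb_threshold),
            class = "pbt_thresholds")
}

#' Classify compounds into REACH bioaccumulation categories
#'
#' Converts logBCF back to the BCF scale and assigns nB (not
#' bioaccumulative), B or vB. A BCF exactly equal to a boundary falls in
#' the lower category.
#'
#' @param logbcf Numeric vector of log10 BCF values.
#' @param thresholds A [pbt_thresholds()].
#' @return Factor with levels `nB`, `B`, `vB`.
#' @examples
#' pbt_classify(c(3, 3.5, 4)) # nB, B, vB
#' @export
pbt_classify <- function(logbcf, thresholds = pbt_thresholds()) {
  stopifnot(inherits(thresholds, "pbt_thresholds"))
  # compare on the log scale (monotone-equivalent to the BCF scale) so a
  # logBCF exactly at log10(threshold) lands in the lower category
  x <- as.numeric(logbcf)
  cat <- ifelse(x > log10(thresholds$vb_threshold), "vB",
                ifelse(x > log10(thresholds$b_threshold), "B", "nB"))
  factor(cat, levels = c("nB", "B", "vB"))
}

#' Category-level classification report
#'
#' Classifies observed and predicted logBCF into nB/B/vB and
#' cross-tabulates them. A false negative is a compound whose true
#' category is higher than its predicted one (under-prediction of hazard);
#' a false positive is the reverse. Correct, false-negative and
#' false-positive rates sum to 1.
#'
#' @param observed,predicted Numeric logBCF vectors of equal length.
#' @param thresholds A [pbt_thresholds()].
#' @return A `classification_report`: `confusion` (3x3 table, truth rows x
#'   prediction columns), `correct_rate`, `false_negative_rate`,
#'   `false_positive_rate`, `n`.
#' @export
classification_report <- function(observed, predicted,
                                  thresholds = pbt_thresholds()) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted must have equal length", call. = FALSE)
  }
  truth <- pbt_classify(observed, thresholds)
  pred <- pbt_classify(predicted, thresholds)
  confusion <- table(truth = truth, predicted = pred)
  n <- length(observed)
  ti <- as.integer(truth)
  pi_ <- as.integer(pred)
  structure(
    list(confusion = confusion,
         correct_rate = sum(ti == pi_) / n,
         false_negative_rate = sum(pi_ < ti) / n,
         false_positive_rate = sum(pi_ > ti) / n,
         n = n, thresholds = thresholds),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("classification_report: n = %d, correct %.1f%%, false negative %.1f%%, false positive %.1f%%\n",
              x$n, 100 * x$correct_rate, 100 * x$false_negative_rate,
              100 * x$false_positive_rate))
  print(x$confusion)
  invisible(x)
}
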