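#' Specify a multilayer perceptron
#'
#' Describes a 3- or 4-layer MLP (input layer, 1 or 2 tanh hidden layers,
#' one linear output unit) trained by full-batch back-propagation
#' (`"bp"`, fixed learning rate) or Polak-Ribiere conjugate gradient
#' descent (`"cgd"`, backtracking line search) for at most
#' `max_iterations` full passes, with early stopping implemented as a
#' checkpoint restore of the best-verification-error iteration. The
#' reference architecture used for the final bioconcentration model is
#' `mlp_spec(hidden = c(14, 10))`: a 4-layer network with 14 and 10 hidden
#' nodes.
#'
#' @param hidden Integer vector of 1 or 2 hidden-layer sizes.
#' @param algorithm `"cgd"` or `"bp"`.
#' @param max_iterations Training iterations (default 100).
#' @param learning_rate Step size for `"bp"`.
#' @param patience Iterations without verification improvement before
#'   stopping; default `Inf` (train the full budget, restore the best
#'   checkpoint).
#' @param standardize Centre/scale descriptors by training statistics
#'   before training (default `TRUE`; tanh units saturate on raw
#'   descriptor scales).
#' @param seed Integer seed for weight initialization.
#' @return An `mlp_spec`.
#' @export
mlp_spec <- function(hidden = c(14, 10), algorithm = c("cgd", "bp"),
                     max_iterations = 100, learning_rate = 0.05,
                     patience = Inf, standardize = TRUE, seed = 1L) {
  algorithm <- match.arg(algorithm)
  hidden <- as.integer(hidden)
  if (!length(hidden) %in% 1:2 || any(hidden < 1L)) {
    stop("spec error: 1 or 2 hidden layers of positive size required",
         call. = FALSE)
  }
  stopifnot(max_iterations >= 1, learning_rate > 0, patience >= 1)
  structure(
    list(hidden = hidden, algorithm = algorithm,
         max_iterations = as.integer(max_iterations),
         learning_rate = learning_rate, patience = patience,
         standardize = standardize, seed = as.integer(seed)),
    class = "mlp_spec"
  )
}

new_trained_model <- function(kind, params, spec, preprocessing,
                              descriptor_names, train_center_raw,
                              training_log = NULL) {
  structure(
    list(kind = kind, params = params, spec = spec,
         preprocessing = preprocessing,
         descriptor_names = descriptor_names,
         train_center_raw = train_center_raw,
         training_log = training_log),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (%s): %d descriptor(s)\n", x$kind,
              length(x$descriptor_names)))
  if (!is.null(x$training_log)) {
    i <- which.min(x$training_log$verify_rmse)
    cat(sprintf("  best checkpoint: iteration %d, verify RMSE %.4f\n",
                x$training_log$iteration[i], x$training_log$verify_rmse[i]))
  }
  invisible(x)
}

model_training_inputs <- function(table, split, standardize) {
  tr <- subset_rows(table, split$train_ids)
  preprocessing <- NULL
  if (standardize) {
    std <- standardize(table, split$train_ids)
    table_s <- std$table
    preprocessing <- std$record
  } else {
    table_s <- table
  }
  list(Xtr = subset_rows(table_s, split$train_ids)$X,
       ytr = table$logbcf[split$train_ids],
       Xv = if (length(split$verify_ids)) {
         subset_rows(table_s, split$verify_ids)$X
       } else {
         NULL
       },
       yv = if (length(split$verify_ids)) table$logbcf[split$verify_ids],
       preprocessing = preprocessing,
       train_center_raw = colMeans(tr$X))
}

#' Train a multilayer perceptron
#'
#' Minimizes full-batch mean-squared error on the training rows, records
#' the verification RMSE after every iteration, and returns the weights of
#' the best-verification iteration (early stopping). Deterministic for a
#' fixed `spec$seed`.
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param split A `split_assignment` with non-empty train and verify
#'   subsets.
#' @param spec An [mlp_spec()].
#' @return A `trained_model` of kind `"mlp"` with a `training_log` data
#'   frame (`iteration`, `train_rmse`, `verify_rmse`).
#' @export
train_mlp <- function(table, split, spec = mlp_spec()) {
  stopifnot(inherits(spec, "mlp_spec"))
  if (length(split$train_ids) == 0L || length(split$verify_ids) == 0L) {
    stop("train and verification subsets must be non-empty", call. = FALSE)
  }
  inp <- model_training_inputs(table, split, spec$standardize)
  layer_sizes <- c(ncol(inp$Xtr), spec$hidden, 1L)
  par <- mlp_init_params(layer_sizes, spec$seed)
  run <- mlp_train_loop(par, inp$Xtr, inp$ytr, inp$Xv, inp$yv,
                        spec$algorithm, spec$max_iterations,
                        spec$learning_rate, spec$patience)
  new_trained_model("mlp", run$par, spec, inp$preprocessing,
                    colnames(inp$Xtr), inp$train_center_raw,
                    training_log = run$log)
}

#' Train a radial basis function network
#'
#' Places `centers` Gaussian units by k-means on the (standardized)
#' training descriptors, sets each unit's width to the distance to its
#' nearest other centre, and solves for the output weights by regularized
#' least squares. Deterministic for a fixed seed.
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param split A `split_assignment`.
#' @param centers Number of radial units (<= number of training rows).
#' @param seed Integer seed for k-means initialization.
#' @param ridge Output-layer ridge penalty (default `1e-8`).
#' @param standardize Centre/scale descriptors by training statistics.
#' @return A `trained_model` of kind `"rbf"`.
#' @export
train_rbf <- function(table, split, centers, seed = 1L, ridge = 1e-8,
                      standardize = TRUE) {
  n_train <- length(split$train_ids)
  if (centers > n_train) {
    stop("spec error: centers (", centers, ") > training rows (", n_train,
         ")", call. = FALSE)
  }
  inp <- model_training_inputs(table, split, standardize)
  set.seed(seed)
  C <- if (centers == n_train) {
    inp$Xtr
  } else {
    stats::kmeans(inp$Xtr, centers, nstart = 5, iter.max = 100)$centers
  }
  C <- as.matrix(C)
  widths <- if (nrow(C) > 1L) {
    dc <- as.matrix(stats::dist(C))
    diag(dc) <- Inf
    w <- apply(dc, 1, min)
    w[w < 1e-8] <- max(stats::median(w), 1e-8)
    w
  } else {
    sqrt(mean(cross_dist2(inp$Xtr, C)))
  }
  Phi <- cbind(1, exp(-sweep(cross_dist2(inp$Xtr, C), 2, 2 * widths^2, "/")))
  A <- crossprod(Phi) + ridge * diag(ncol(Phi))
  beta <- solve(A, crossprod(Phi, inp$ytr))
  new_trained_model("rbf",
                    list(centers = C, widths = widths,
                         beta = as.numeric(beta)),
                    list(centers = centers, seed = seed, ridge = ridge,
                         standardize = standardize),
                    inp$preprocessing, colnames(inp$Xtr),
                    inp$train_center_raw)
}

#' Train a baseline regressor
#'
#' Baseline models for comparison with the neural networks: ordinary
#' least squares and ridge regression via closed-form normal-equation
#' solves, and k-nearest-neighbour regression (uniform or inverse-distance
#' weighted).
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param split A `split_assignment`.
#' @param kind `"linear"`, `"ridge"` or `"knn"`.
#' @param hyper Kind-specific hyperparameters: `lambda` (ridge penalty,
#'   default 1), `k` (neighbours, default 5), `weighted` (kNN weighting,
#'   default `FALSE`).
#' @param standardize Centre/scale descriptors for `"ridge"`/`"knn"`
#'   (always `FALSE` for `"linear"`, whose coefficients live on the raw
#'   descriptor scale).
#' @return A `trained_model`.
#' @export
train_baseline <- function(table, split, kind = c("linear", "ridge", "knn"),
                           hyper = list(), standardize = kind != "linear") {
  kind <- match.arg(kind)
  if (kind == "linear") standardize <- FALSE
  inp <- model_training_inputs(table, split, standardize)
  Xtr <- inp$Xtr
  ytr <- inp$ytr
  params <- switch(kind,
    linear = {
      if (nrow(Xtr) <= ncol(Xtr)) {
        stop("need more training rows than descriptors for OLS",
             call. = FALSE)
      }
      D <- cbind("(Intercept)" = 1, Xtr)
      qrD <- qr(D)
      if (qrD$rank < ncol(D)) {
        stop("rank error: singular design matrix; consider kind = 'ridge'",
             call. = FALSE)
      }
      list(coef = stats::setNames(as.numeric(qr.coef(qrD, ytr)), colnames(D)))
    },
    ridge = {
      lambda <- if (is.null(hyper$lambda)) 1 else hyper$lambda
      xbar <- colMeans(Xtr)
      Xc <- sweep(Xtr, 2, xbar, "-")
      ybar <- mean(ytr)
      beta <- solve(crossprod(Xc) + lambda * diag(ncol(Xc)),
                    crossprod(Xc, ytr - ybar))
      list(beta = stats::setNames(as.numeric(beta), colnames(Xtr)),
           xbar = xbar, ybar = ybar, lambda = lambda)
    },
    knn = {
      k <- if (is.null(hyper$k)) 5L else as.integer(hyper$k)
      if (k < 1L || k > nrow(Xtr)) {
        stop("k must be between 1 and the number of training rows",
             call. = FALSE)
      }
      list(X = Xtr, y = ytr, k = k,
           weighted = isTRUE(hyper$weighted))
    }
  )
  new_trained_model(kind, params, list(kind = kind, hyper = hyper,
                                       standardize = standardize),
                    inp$preprocessing, colnames(Xtr), inp$train_center_raw)
}

#' Train a GRNN as a standalone model
#'
#' Wraps [grnn_fit()] in the common `trained_model` interface; if `sigma`
#' is `NULL` the bandwidth is selected on the verification rows.
#'
#' @param table A `descriptor_table` with a logBCF target.
#' @param split A `split_assignment`.
#' @param sigma Bandwidth, or `NULL` to select from `grid`.
#' @param grid Candidate bandwidths.
#' @param standardize Centre/scale descriptors by training statistics.
#' @return A `trained_model` of kind `"grnn"`.
#' @export
train_grnn <- function(table, split, sigma = NULL, grid = grnn_sigma_grid(),
                       standardize = TRUE) {
  inp <- model_training_inputs(table, split, standardize)
  if (is.null(sigma)) {
    if (is.null(inp$Xv)) {
      stop("bandwidth selection needs a verification subset", call. = FALSE)
    }
    Xall <- rbind(inp$Xtr, inp$Xv)
    yall <- c(inp$ytr, inp$yv)
    sigma <- as.numeric(grnn_select_bandwidth(
      Xall, yall, holdout = nrow(inp$Xtr) + seq_len(nrow(inp$Xv)),
      grid = grid))
  }
  fit <- grnn_fit(inp$Xtr, inp$ytr, sigma)
  new_trained_model("grnn", fit, list(sigma = sigma,
                                      standardize = standardize),
                    inp$preprocessing, colnames(inp$Xtr),
                    inp$train_center_raw)
}

#' Predict logBCF for a table of compounds
#'
#' Aligns the table's descriptor columns to the model's (by name), applies
#' the stored standardization record if any, and evaluates the model.
#'
#' @param object A `trained_model`.
#' @param newdata A `descriptor_table` (or numeric matrix with named
#'   columns) containing all of the model's descriptors.
#' @param ... Unused.
#' @return Named numeric vector of predicted logBCF, one per compound.
#' @export
predict.trained_model <- function(object, newdata, ...) {
  if (inherits(newdata, "descriptor_table")) {
    ids <- newdata$ids
    X <- newdata$X
  } else {
    X <- as.matrix(newdata)
    ids <- rownames(X)
  }
  missing <- setdiff(object$descriptor_names, colnames(X))
  if (length(missing)) {
    stop("schema error: missing descriptor column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- X[, object$descriptor_names, drop = FALSE]
  if (nrow(X) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (!is.null(object$preprocessing)) {
    rec <- object$preprocessing
    X <- sweep(X, 2, rec$center[colnames(X)], "-")
    X <- sweep(X, 2, rec$scale[colnames(X)], "/")
  }
  pred <- switch(object$kind,
    mlp = mlp_predict_raw(object$params, X),
    rbf = {
      Phi <- cbind(1, exp(-sweep(cross_dist2(X, object$params$centers), 2,
                                 2 * object$params$widths^2, "/")))
      as.numeric(Phi %*% object$params$beta)
    },
    linear = {
      as.numeric(cbind(1, X) %*% object$params$coef)
    },
    ridge = {
      Xc <- sweep(X, 2, object$params$xbar, "-")
      object$params$ybar + as.numeric(Xc %*% object$params$beta)
    },
    knn = {
      d2 <- cross_dist2(X, object$params$X)
      k <- object$params$k
      apply_k <- function(i) {
        ord <- order(d2[i, ])[seq_len(k)]
        if (object$params$weighted) {
          w <- 1 / (sqrt(d2[i, ord]) + 1e-8)
          sum(w * object$params$y[ord]) / sum(w)
        } else {
          mean(object$params$y[ord])
        }
      }
      vapply(seq_len(nrow(X)), apply_k, numeric(1))
    },
    grnn = predict.grnn(object$params, X),
    stop("unknown model kind: ", object$kind, call. = FALSE)
  )
  stats::setNames(pred, ids)
}

#' Reinitialise a model architecture on a new species' data
#'
#' Rebuilds a model of the same kind, architecture and descriptor set with
#' freshly initialized weights (no transfer of trained parameters) and
#' trains it on the new dataset — the workflow used to port a fish-trained
#' architecture to invertebrate bioconcentration data.
#'
#' @param model A `trained_model` whose architecture and descriptor set to
#'   reuse.
#' @param new_table A `descriptor_table` containing the same descriptors.
#' @param new_split A `split_assignment` over `new_table`.
#' @param seed Optional new initialization seed; default keeps the
#'   original spec's seed.
#' @return A freshly trained `trained_model`.
#' @export
retrain_cross_species <- function(model, new_table, new_split, seed = NULL) {
  stopifnot(inherits(model, "trained_model"))
  missing <- setdiff(model$descriptor_names, descriptor_names(new_table))
  if (length(missing)) {
    stop("schema error: new table missing descriptor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl <- subset_descriptors(new_table, model$descriptor_names)
  switch(model$kind,
    mlp = {
      spec <- model$spec
      if (!is.null(seed)) spec$seed <- as.integer(seed)
      train_mlp(tbl, new_split, spec)
    },
    rbf = {
      s <- model$spec
      centers <- min(s$centers, length(new_split$train_ids))
      train_rbf(tbl, new_split, centers,
                seed = if (is.null(seed)) s$seed else seed,
                ridge = s$ridge, standardize = s$standardize)
    },
    grnn = train_grnn(tbl, new_split, sigma = NULL,
                      standardize = model$spec$standardize),
    linear = ,
    ridge = ,
    knn = train_baseline(tbl, new_split, model$kind, model$spec$hyper,
                         standardize = model$spec$standardize),
    stop("unknown model kind: ", model$kind, call. = FALSE)
  )
}

#' Serialize / restore a trained model
#'
#' Writes a portable JSON bundle (weights or exemplars, spec,
#' standardization record, descriptor names) and reads it back.
#'
#' @param model A `trained_model` or `grnn`.
#' @param path File path.
#' @return `write_model()` the path, invisibly; `read_model()` the model.
#' @export
write_model <- function(model, path) {
  writeLines(jsonlite::serializeJSON(model, digits = NA, pretty = FALSE),
             path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path), collapse = "\n"))
}
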