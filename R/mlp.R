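# Multilayer-perceptron internals: tanh hidden layers, linear output,
# full-batch mean-squared-error loss. Two trainers: plain gradient descent
# ("bp", fixed learning rate) and Polak-Ribiere conjugate gradients with
# Armijo backtracking line search ("cgd"). Both are deterministic given the
# weight-initialization seed.

mlp_init_params <- function(layer_sizes, seed) {
  set.seed(seed)
  L <- length(layer_sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- layer_sizes[l]
    W[[l]] <- matrix(stats::runif(fan_in * layer_sizes[l + 1], -1, 1) /
                       sqrt(fan_in),
                     nrow = fan_in)
    b[[l]] <- rep(0, layer_sizes[l + 1])
  }
  list(W = W, b = b)
}

mlp_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% par$W[[l]]
    Z <- sweep(Z, 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) tanh(Z) else Z
  }
  A
}

mlp_predict_raw <- function(par, X) {
  A <- mlp_forward(par, X)
  as.numeric(A[[length(A)]])
}

mlp_loss <- function(par, X, y) {
  mean((mlp_predict_raw(par, X) - y)^2)
}

mlp_grad <- function(par, X, y) {
  n <- nrow(X)
  L <- length(par$W)
  A <- mlp_forward(par, X)
  delta <- 2 * (A[[L + 1]] - matrix(y, ncol = 1)) / n
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(par$W[[l]])) * (1 - A[[l]]^2)
    }
  }
  list(W = gW, b = gb)
}

mlp_flatten <- function(par) {
  unlist(c(lapply(par$W, as.numeric), lapply(par$b, as.numeric)))
}

mlp_unflatten <- function(theta, template) {
  out <- template
  pos <- 0L
  for (l in seq_along(template$W)) {
    k <- length(template$W[[l]])
    out$W[[l]] <- matrix(theta[pos + seq_len(k)], nrow = nrow(template$W[[l]]))
    pos <- pos + k
  }
  for (l in seq_along(template$b)) {
    k <- length(template$b[[l]])
    out$b[[l]] <- theta[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}

# One training run. Returns best-verification parameters (early stopping as
# checkpoint restore) and the per-iteration train/verify RMSE log.
mlp_train_loop <- function(par, Xtr, ytr, Xv, yv, algorithm, max_iterations,
                           learning_rate, patience) {
  template <- par
  f <- function(theta) mlp_loss(mlp_unflatten(theta, template), Xtr, ytr)
  g <- function(theta) mlp_flatten(mlp_grad(mlp_unflatten(theta, template),
                                            Xtr, ytr))
  theta <- mlp_flatten(par)
  fx <- f(theta)
  grad <- g(theta)
  dir <- -grad
  alpha0 <- 1

  log <- data.frame(iteration = integer(max_iterations),
                    train_rmse = numeric(max_iterations),
                    verify_rmse = numeric(max_iterations))
  best <- list(verify_rmse = Inf, theta = theta, iteration = 0L)
  stale <- 0L
  n_iter <- 0L

  for (it in seq_len(max_iterations)) {
    if (algorithm == "bp") {
      theta <- theta - learning_rate * grad
      fx <- f(theta)
      grad <- g(theta)
    } else {
      gtd <- sum(grad * dir)
      if (!is.finite(gtd) || gtd >= 0) {
        dir <- -grad
        gtd <- sum(grad * dir)
      }
      alpha <- alpha0
      ok <- FALSE
      for (ls in 1:40) {
        fnew <- f(theta + alpha * dir)
        if (is.finite(fnew) && fnew <= fx + 1e-4 * alpha * gtd) {
          ok <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!ok) {
        # line search failed along this direction; restart from steepest
        # descent next iteration and keep the current point
        dir <- -grad
        alpha0 <- 1
        fnew <- fx
      } else {
        theta <- theta + alpha * dir
        gnew <- g(theta)
        beta <- max(0, sum(gnew * (gnew - grad)) / max(sum(grad^2), 1e-300))
        dir <- -gnew + beta * dir
        grad <- gnew
        fx <- fnew
        alpha0 <- min(alpha * 2, 1e3)
      }
    }
    if (!is.finite(fx)) {
      stop("training error: loss diverged to a non-finite value at iteration ",
           it, " (reduce the learning rate)", call. = FALSE)
    }
    vr <- sqrt(mean((mlp_predict_raw(mlp_unflatten(theta, template), Xv) -
                       yv)^2))
    n_iter <- it
    log$iteration[it] <- it
    log$train_rmse[it] <- sqrt(fx)
    log$verify_rmse[it] <- vr
    if (vr < best$verify_rmse) {
      best <- list(verify_rmse = vr, theta = theta, iteration = it)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  list(par = mlp_unflatten(best$theta, template),
       log = log[seq_len(n_iter), , drop = FALSE],
       best_iteration = best$iteration)
}
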