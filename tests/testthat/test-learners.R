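linear_fixture <- function(n = 200, noise_sd = 0, seed = 1) {
  fx <- make_linear_table(n, 3, c(0.5, -0.3), intercept = 1,
                          noise_sd = noise_sd, seed = seed)
  list(table = fx$table, split = even_split(fx$table, seed = seed))
}

test_that("an MLP drives training error down on a noiseless linear target", {
  fx <- linear_fixture(seed = 2)
  m <- train_mlp(fx$table, fx$split, mlp_spec(hidden = 8, seed = 1))
  expect_lt(tail(m$training_log$train_rmse, 1), 0.05)
  expect_lte(nrow(m$training_log), 100)
})

test_that("early stopping restores the minimum-verification checkpoint", {
  fx <- linear_fixture(noise_sd = 0.4, seed = 3)
  for (alg in c("cgd", "bp")) {
    m <- train_mlp(fx$table, fx$split,
                   mlp_spec(hidden = c(6, 4), algorithm = alg,
                            learning_rate = 0.1, seed = 2))
    ver <- subset_rows(fx$table, fx$split$verify_ids)
    restored <- sqrt(mean((predict(m, ver) - ver$logbcf)^2))
    expect_equal(restored, min(m$training_log$verify_rmse), tolerance = 1e-10)
    expect_lte(restored, tail(m$training_log$verify_rmse, 1) + 1e-12)
  }
})

test_that("MLP training is deterministic under its seed", {
  fx <- linear_fixture(noise_sd = 0.3, seed = 4)
  te <- subset_rows(fx$table, fx$split$test_ids)
  m1 <- train_mlp(fx$table, fx$split, mlp_spec(hidden = 6, seed = 9))
  m2 <- train_mlp(fx$table, fx$split, mlp_spec(hidden = 6, seed = 9))
  expect_identical(predict(m1, te), predict(m2, te))
})

test_that("RBF networks interpolate with one centre per training point", {
  set.seed(5)
  x <- runif(30, -2, 2)
  tbl <- dt_from_matrix(cbind(d1 = x), y = sin(x))
  sp <- split_dataset(tbl, c(30, 0, 0), seed = 1)
  m <- train_rbf(tbl, sp, centers = 30, ridge = 1e-10)
  expect_lt(sqrt(mean((predict(m, tbl) - tbl$logbcf)^2)), 0.01)

  # single centre: far-field prediction collapses to the output bias
  m1 <- train_rbf(tbl, sp, centers = 1)
  far <- dt_from_matrix(cbind(d1 = 1e3), y = 0, ids = "far")
  expect_equal(unname(predict(m1, far)), m1$params$beta[1], tolerance = 1e-8)

  expect_error(train_rbf(tbl, sp, centers = 31), "spec error")

  fx <- linear_fixture(noise_sd = 0.3, seed = 5)
  a <- train_rbf(fx$table, fx$split, centers = 10, seed = 3)
  b <- train_rbf(fx$table, fx$split, centers = 10, seed = 3)
  expect_identical(a$params, b$params)
})

test_that("closed-form baselines match independent oracles", {
  fx <- linear_fixture(noise_sd = 0.2, seed = 6)
  ols <- train_baseline(fx$table, fx$split, "linear")

  # naive normal-equations oracle and stats::lm agree with the QR fit
  tr <- subset_rows(fx$table, fx$split$train_ids)
  D <- cbind(1, tr$X)
  beta_naive <- solve(crossprod(D), crossprod(D, tr$logbcf))
  expect_equal(unname(ols$params$coef), as.numeric(beta_naive),
               tolerance = 1e-8)
  lm_fit <- lm(y ~ ., data = data.frame(y = tr$logbcf, tr$X))
  expect_equal(unname(ols$params$coef), unname(coef(lm_fit)),
               tolerance = 1e-8)

  # exact recovery of y = 2 d1 + 1
  tbl <- dt_from_matrix(cbind(d1 = c(0, 1, 2, 3, 4)),
                        y = 2 * c(0, 1, 2, 3, 4) + 1)
  sp <- split_dataset(tbl, c(5, 0, 0), seed = 1)
  fit <- train_baseline(tbl, sp, "linear")
  expect_equal(unname(fit$params$coef), c(1, 2), tolerance = 1e-8)

  # singular design is refused with a pointer to ridge
  sing <- dt_from_matrix(cbind(d1 = c(1, 2, 3, 4, 5), d2 = 2 * c(1, 2, 3, 4, 5)),
                         y = rnorm(5))
  sps <- split_dataset(sing, c(5, 0, 0), seed = 1)
  expect_error(train_baseline(sing, sps, "linear"), "ridge")
})

test_that("ridge shrinks the slope strictly between zero and least squares", {
  set.seed(7)
  x <- rnorm(50)
  tbl <- dt_from_matrix(cbind(d1 = x), y = 1.5 * x + rnorm(50, 0, 0.3))
  sp <- split_dataset(tbl, c(50, 0, 0), seed = 1)
  ols_slope <- train_baseline(tbl, sp, "linear")$params$coef["d1"]
  rr <- train_baseline(tbl, sp, "ridge", hyper = list(lambda = 10))
  # map the standardized ridge slope back to the raw scale
  slope_raw <- rr$params$beta["d1"] / rr$preprocessing$scale["d1"]
  expect_gt(unname(slope_raw), 0)
  expect_lt(unname(slope_raw), unname(ols_slope))
})

test_that("kNN matches caret at matched settings and degenerates to the mean", {
  fx <- linear_fixture(noise_sd = 0.3, seed = 8)
  te <- subset_rows(fx$table, fx$split$test_ids)
  knn <- train_baseline(fx$table, fx$split, "knn", hyper = list(k = 5))

  tr_std <- apply_standardization(subset_rows(fx$table, fx$split$train_ids),
                                  knn$preprocessing)
  te_std <- apply_standardization(te, knn$preprocessing)
  ref <- caret::knnreg(tr_std$X, fx$table$logbcf[fx$split$train_ids], k = 5)
  expect_equal(unname(predict(knn, te)),
               unname(predict(ref, as.data.frame(te_std$X))),
               tolerance = 1e-8)

  n_train <- length(fx$split$train_ids)
  all_k <- train_baseline(fx$table, fx$split, "knn",
                          hyper = list(k = n_train))
  expect_equal(unname(predict(all_k, te)),
               rep(mean(fx$table$logbcf[fx$split$train_ids]), n_compounds(te)),
               tolerance = 1e-10)
})

test_that("prediction aligns columns by name and handles empty tables", {
  fx <- linear_fixture(noise_sd = 0.2, seed = 9)
  m <- train_mlp(fx$table, fx$split, mlp_spec(hidden = 5, seed = 1))
  te <- subset_rows(fx$table, fx$split$test_ids)
  permuted <- subset_descriptors(te, rev(descriptor_names(te)))
  expect_identical(predict(m, te), predict(m, permuted))
  expect_length(predict(m, subset_rows(te, character(0))), 0)
  expect_error(predict(m, subset_descriptors(te, "d1")), "schema")
})

test_that("cross-species retraining tracks the new data, not the old weights", {
  fish <- make_linear_table(150, 2, c(1, -0.5), noise_sd = 0.2, seed = 10)
  invert <- make_linear_table(150, 2, c(-1, 0.8), noise_sd = 0.2, seed = 11)
  sp_f <- even_split(fish$table, seed = 10)
  sp_i <- even_split(invert$table, seed = 11)
  fish_model <- train_mlp(fish$table, sp_f, mlp_spec(hidden = 6, seed = 1))
  re <- retrain_cross_species(fish_model, invert$table, sp_i)

  te <- subset_rows(invert$table, sp_i$test_ids)
  pred <- predict(re, te)
  truth_new <- invert$truth[sp_i$test_ids]
  # old-species truth at the same descriptor values
  truth_old <- 1 * te$X[, "d1"] - 0.5 * te$X[, "d2"]
  expect_gt(cor(pred, truth_new)^2, cor(pred, truth_old)^2)

  # reinitialisation contract: identical data and seed give the same model
  direct <- train_mlp(invert$table, sp_i, fish_model$spec)
  expect_identical(predict(re, te), predict(direct, te))

  missing <- subset_descriptors(invert$table, "d1")
  expect_error(retrain_cross_species(fish_model, missing, sp_i), "schema")
})

test_that("models survive a JSON serialization round trip", {
  fx <- linear_fixture(noise_sd = 0.2, seed = 12)
  te <- subset_rows(fx$table, fx$split$test_ids)
  m <- train_mlp(fx$table, fx$split, mlp_spec(hidden = 5, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(predict(back, te), predict(m, te), tolerance = 1e-12)
})
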