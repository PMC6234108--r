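test_that("generation is byte-identical under a fixed seed", {
  spec <- synthetic_spec(50, seed = 42, outlier_fraction = 0.1)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$table$X, b$table$X)
  expect_identical(a$table$logbcf, b$table$logbcf)
  expect_identical(a$outlier_ids, b$outlier_ids)
})

test_that("planted collinearity is realized and absent collinearity stays absent", {
  spec <- synthetic_spec(6000, seed = 11)
  tbl <- generate_descriptors(spec)
  expect_equal(cor(tbl$X[, "MW"], tbl$X[, "SPI"]), 0.794, tolerance = 0.05 / 0.794)
  expect_equal(cor(tbl$X[, "STN"], tbl$X[, "HNar"]), 0.748, tolerance = 0.05 / 0.748)

  spec0 <- synthetic_spec(6000, descriptor_names = paste0("d", 1:6),
                          collinear_pairs = list(), effects = list(),
                          seed = 12)
  R <- cor(generate_descriptors(spec0)$X)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
})

test_that("an inconsistent correlation target is rejected", {
  expect_error(
    synthetic_spec(10, descriptor_names = c("a", "b", "c"),
                   collinear_pairs = list(list("a", "b", 0.9),
                                          list("b", "c", 0.9),
                                          list("a", "c", -0.9)),
                   effects = list()),
    "positive definite")
  expect_error(
    synthetic_spec(10, descriptor_names = c("a", "b"),
                   collinear_pairs = list(list("a", "b", 1.5)),
                   effects = list()),
    "correlation")
})

test_that("response noise matches the requested standard deviation", {
  spec <- synthetic_spec(10000, noise_sd = 0.6, seed = 21)
  tbl <- generate_response(generate_descriptors(spec), spec)
  resid <- tbl$logbcf - attr(tbl, "truth")
  expect_equal(sd(resid), 0.6, tolerance = 0.02 / 0.6)
})

test_that("linear effects are exact and the hydrophobicity term saturates", {
  # pure linear term: slope 0.5 at logD = 4 contributes 2 over the intercept
  lin <- synthetic_spec(4, descriptor_names = "logD", collinear_pairs = list(),
                        effects = list(logD = list(type = "linear", slope = 0.5)),
                        intercept = 0.5, noise_sd = 0)
  hand <- dt_from_matrix(cbind(logD = c(3, 4, 7, 8)))
  expect_equal(unname(generate_response(hand, lin)$logbcf[2]), 2.5)

  # saturating ramp: increment past the location is smaller than before it
  sat <- synthetic_spec(4, descriptor_names = "logD", collinear_pairs = list(),
                        effects = list(logD = list(type = "saturating",
                                                   slope = 0.6, location = 6,
                                                   scale = 1)),
                        intercept = 0, noise_sd = 0)
  y <- unname(generate_response(hand, sat)$logbcf)
  expect_lt(y[4] - y[3], y[2] - y[1])
  expect_gt(y[2] - y[1], 0) # still increasing below the threshold

  missing <- synthetic_spec(4, descriptor_names = "MW", collinear_pairs = list(),
                            effects = list(logD = list(type = "linear",
                                                       slope = 1)),
                            noise_sd = 0)
  expect_error(generate_response(dt_from_matrix(cbind(MW = 1:4)), missing),
               "absent")
})

test_that("noiseless linear tables let least squares recover the planted slopes", {
  fx <- make_linear_table(200, 4, c(0.5, -0.3, 0.8), intercept = 1,
                          noise_sd = 0, seed = 31)
  sp <- split_dataset(fx$table, c(200, 0, 0), seed = 1)
  fit <- train_baseline(fx$table, sp, "linear")
  coefs <- fit$params$coef
  expect_equal(unname(coefs[c("d1", "d2", "d3", "d4")]),
               c(0.5, -0.3, 0.8, 0), tolerance = 1e-6)
  expect_equal(unname(coefs["(Intercept)"]), 1, tolerance = 1e-6)
})

test_that("outlier injection returns the planted ids and moves them far out", {
  spec <- synthetic_spec(200, outlier_fraction = 0.05, outlier_shift = 10,
                         seed = 51)
  tbl <- generate_descriptors(spec)
  out <- inject_outliers(tbl, spec)
  expect_length(out$outlier_ids, 10)

  none <- synthetic_spec(200, outlier_fraction = 0, seed = 51)
  unchanged <- inject_outliers(tbl, none)
  expect_identical(unchanged$table$X, tbl$X)
  expect_identical(unchanged$outlier_ids, character(0))

  # shifted rows sit beyond every unshifted row in standardized distance
  Z <- scale(out$table$X, center = colMeans(tbl$X), scale = apply(tbl$X, 2, sd))
  d <- sqrt(rowSums(Z^2))
  shifted <- out$table$ids %in% out$outlier_ids
  expect_gt(min(d[shifted]), max(d[!shifted]))
})
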