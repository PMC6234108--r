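# shared planted-signal fixture: d1 strong, d2 moderate, d3..dp noise
planted_fixture <- function(n = 400, p = 6, noise_sd = 0.2, seed = 1) {
  nms <- paste0("d", seq_len(p))
  spec <- synthetic_spec(n, descriptor_names = nms, collinear_pairs = list(),
                        effects = list(d1 = list(type = "linear", slope = 1),
                                       d2 = list(type = "linear", slope = 0.8)),
                        noise_sd = noise_sd, seed = seed)
  ds <- generate_dataset(spec)
  list(table = ds$table,
       split = split_dataset(ds$table, c(round(n * 0.7), n - round(n * 0.7), 0),
                             seed = seed))
}

test_that("subset fitness tracks the information content of the subset", {
  # sole generative descriptor of a noiseless response: near-zero error
  uni <- synthetic_spec(1000, descriptor_names = c("d1", "d2"),
                        collinear_pairs = list(),
                        effects = list(d1 = list(type = "linear", slope = 1)),
                        noise_sd = 0, seed = 2)
  ds_uni <- generate_dataset(uni)
  sp_uni <- split_dataset(ds_uni$table, c(700, 300, 0), seed = 2)
  f_true <- subset_fitness(ds_uni$table, "d1", sp_uni)
  expect_lt(as.numeric(f_true), 0.05)

  fx <- planted_fixture(n = 500, p = 4, noise_sd = 0.5, seed = 3)
  yv <- fx$table$logbcf[fx$split$verify_ids]
  f_noise <- subset_fitness(fx$table, c("d3", "d4"), fx$split)
  expect_gte(as.numeric(f_noise), 0.9 * sd(yv))

  # adding an irrelevant descriptor perturbs the error by a bounded amount
  f_good <- subset_fitness(fx$table, c("d1", "d2"), fx$split)
  f_plus <- subset_fitness(fx$table, c("d1", "d2", "d3"), fx$split)
  expect_lt(abs(as.numeric(f_plus) - as.numeric(f_good)), 0.5 * sd(yv))

  expect_error(subset_fitness(fx$table, character(0), fx$split), "empty")
})

test_that("pure-noise subsets score near the response spread across seeds", {
  ratios <- vapply(1:20, function(s) {
    fx <- planted_fixture(n = 500, p = 4, noise_sd = 0.5, seed = 1000 + s)
    f <- subset_fitness(fx$table, c("d3", "d4"), fx$split)
    as.numeric(f) / sd(fx$table$logbcf[fx$split$verify_ids])
  }, numeric(1))
  expect_true(all(ratios >= 0.9))
})

test_that("the GA recovers planted descriptors with a non-increasing best fitness", {
  fx <- planted_fixture(n = 400, p = 8, noise_sd = 0.2, seed = 4)
  res <- ga_select(fx$table, fx$split, ga_config(population = 30,
                                                 generations = 15, seed = 4))
  expect_true(all(c("d1", "d2") %in% res$selected))
  expect_true(all(diff(res$history$best_fitness) <= 1e-12))
  expect_s3_class(res, "selection_result")
  expect_gt(res$evaluations, 0)
})

test_that("a minimal GA run returns the better of the masks it evaluated", {
  fx <- planted_fixture(n = 120, p = 2, noise_sd = 0.3, seed = 5)
  res <- ga_select(fx$table, fx$split,
                   ga_config(population = 2, generations = 1, elitism = 1,
                             seed = 5))
  # with 2 descriptors the best evaluated mask must be one of the 3 subsets
  fits <- c(subset_fitness(fx$table, "d1", fx$split),
            subset_fitness(fx$table, "d2", fx$split),
            subset_fitness(fx$table, c("d1", "d2"), fx$split))
  expect_true(res$fitness %in% as.numeric(fits))
})

test_that("GA agrees with exhaustive search on a two-descriptor table", {
  nms <- c("signal", "noise")
  spec <- synthetic_spec(200, descriptor_names = nms, collinear_pairs = list(),
                        effects = list(signal = list(type = "linear",
                                                     slope = 1)),
                        noise_sd = 0.2, seed = 6)
  ds <- generate_dataset(spec)
  sp <- split_dataset(ds$table, c(140, 60, 0), seed = 6)
  masks <- list("signal", "noise", c("signal", "noise"))
  fits <- vapply(masks, function(m) {
    as.numeric(subset_fitness(ds$table, m, sp))
  }, numeric(1))
  res <- ga_select(ds$table, sp, ga_config(population = 8, generations = 10,
                                           seed = 6))
  expect_equal(sort(res$selected), sort(masks[[which.min(fits)]]))
  expect_equal(res$fitness, min(fits))
})

test_that("stepwise search honours a dominant descriptor in both directions", {
  fx <- planted_fixture(n = 300, p = 3, noise_sd = 0, seed = 7)
  # make d1 the sole driver for this check
  nms <- paste0("d", 1:3)
  spec <- synthetic_spec(300, descriptor_names = nms, collinear_pairs = list(),
                        effects = list(d1 = list(type = "linear", slope = 1)),
                        noise_sd = 0, seed = 7)
  ds <- generate_dataset(spec)
  sp <- split_dataset(ds$table, c(210, 90, 0), seed = 7)

  fwd <- stepwise_select(ds$table, "forward", sp)
  expect_equal(fwd$path$descriptor[1], "d1") # first greedy addition
  expect_true("d1" %in% fwd$selected)

  bwd <- stepwise_select(ds$table, "backward", sp)
  expect_true("d1" %in% bwd$selected)
  expect_false("d1" %in% bwd$path$descriptor[bwd$path$action == "remove" &
                                             bwd$path$step <= 2])

  # forward and backward converge to the same subset here
  expect_setequal(fwd$selected, bwd$selected)
})

test_that("a single-descriptor table is returned by both directions", {
  spec <- synthetic_spec(100, descriptor_names = "d1", collinear_pairs = list(),
                        effects = list(d1 = list(type = "linear", slope = 1)),
                        noise_sd = 0.2, seed = 8)
  ds <- generate_dataset(spec)
  sp <- split_dataset(ds$table, c(70, 30, 0), seed = 8)
  expect_equal(stepwise_select(ds$table, "forward", sp)$selected, "d1")
  expect_equal(stepwise_select(ds$table, "backward", sp)$selected, "d1")
})

test_that("curation appends forced descriptors order-stably", {
  expect_equal(curate_subset(c("MW", "TPSA"), "logD"),
               c("MW", "TPSA", "logD"))
  expect_equal(curate_subset(c("MW", "TPSA"), "TPSA"), c("MW", "TPSA"))
  expect_equal(curate_subset(c("MW", "TPSA"), character(0)), c("MW", "TPSA"))
  tbl <- dt_from_matrix(cbind(MW = 1:3, TPSA = 4:6))
  expect_error(curate_subset("MW", "logD", tbl), "forced descriptor")
})
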