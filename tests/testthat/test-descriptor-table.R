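test_that("CSV ingestion types columns and enforces unique ids", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,MW,logD,logBCF",
               "a,100,1.2,2.0", "b,200,2.5,3.1", "c,300,3.8,4.2"), path)
  tbl <- read_descriptor_table(path)
  expect_equal(n_compounds(tbl), 3L)
  expect_equal(descriptor_names(tbl), c("MW", "logD"))
  expect_equal(unname(tbl$logbcf), c(2.0, 3.1, 4.2))

  writeLines(c("compound_id,MW,logD,logBCF",
               "a,100,1.2,2.0", "a,200,2.5,3.1"), path)
  expect_error(read_descriptor_table(path), "duplicate")

  writeLines(c("MW,logD,logBCF", "100,1.2,2.0"), path)
  expect_error(read_descriptor_table(path), "id column")
})

test_that("missing descriptor cells follow the strictness flag and tables round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,MW,logD,logBCF",
               "a,100,1.2,2.0", "b,NA,2.5,3.1", "c,300,3.8,4.2"), path)
  expect_error(read_descriptor_table(path, strict = TRUE), "non-finite")
  expect_warning(tbl <- read_descriptor_table(path, strict = FALSE),
                 "dropped")
  expect_equal(tbl$ids, c("a", "c"))

  # write/read round trip, including sidecar metadata
  tbl$meta$logd_ph <- 7.4
  out <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(tbl, out)
  back <- read_descriptor_table(out)
  expect_equal(back$X, tbl$X)
  expect_equal(back$logbcf, tbl$logbcf)
  expect_equal(back$meta$logd_ph, 7.4)
})

test_that("cleaning removes zero-variance and non-finite columns and is idempotent", {
  X <- cbind(c1 = c(1, 2, 3, 4), c2 = c(5, 6, 7, 8), c3 = rep(5, 4))
  tbl <- dt_from_matrix(X)
  cleaned <- clean_descriptors(tbl)
  expect_equal(descriptor_names(cleaned), c("c1", "c2"))
  expect_equal(attr(cleaned, "removed")$zero_variance, "c3")

  X2 <- X
  X2[2, "c2"] <- Inf
  tbl2 <- bcfqsar:::new_descriptor_table(tbl$ids, X2)
  cleaned2 <- clean_descriptors(tbl2)
  expect_equal(descriptor_names(cleaned2), "c1")
  expect_equal(attr(cleaned2, "removed")$non_finite, "c2")

  # idempotence and identity on unoffending tables
  again <- clean_descriptors(cleaned)
  expect_equal(again$X, cleaned$X)

  all_const <- dt_from_matrix(cbind(c1 = rep(1, 3)))
  expect_error(clean_descriptors(all_const), "empty-feature")
})

test_that("BCF log transform is log10 with a positivity domain", {
  expect_equal(log_transform_bcf(1000), 3)
  expect_equal(log_transform_bcf(1), 0)
  expect_equal(log_transform_bcf(2000), log10(2000))
  expect_error(log_transform_bcf(0), "domain")
  expect_error(log_transform_bcf(-5), "domain")
})

test_that("splits are exact, disjoint, exhaustive and seed-reproducible", {
  tbl <- make_linear_table(60, 2, c(1))$table
  sp <- split_dataset(tbl, c(42, 9, 9), seed = 7)
  expect_length(sp$train_ids, 42)
  expect_length(sp$verify_ids, 9)
  expect_length(sp$test_ids, 9)
  expect_identical(sp, split_dataset(tbl, c(42, 9, 9), seed = 7))
  expect_error(split_dataset(tbl, c(42, 9, 8)), "size error")

  # partition property over random valid size triples
  set.seed(99)
  for (i in 1:15) {
    n <- sample(5:80, 1)
    tb <- make_linear_table(n, 2, c(1), seed = i)$table
    cuts <- sort(sample(0:n, 2, replace = TRUE))
    sizes <- c(cuts[1], cuts[2] - cuts[1], n - cuts[2])
    spp <- split_dataset(tb, sizes, seed = i)
    all_ids <- c(spp$train_ids, spp$verify_ids, spp$test_ids)
    expect_equal(sort(all_ids), sort(tb$ids))
    expect_equal(anyDuplicated(all_ids), 0L)
    expect_equal(lengths(spp[1:3]), sizes, ignore_attr = TRUE)
  }
})

test_that("default split sizes floor the fractions and give the remainder to training", {
  expect_equal(unname(default_split_sizes(100)), c(70, 15, 15))
  expect_equal(unname(default_split_sizes(34)), c(24, 5, 5))
  expect_equal(sum(default_split_sizes(353)), 353)
})

test_that("standardization uses training statistics and inverts exactly", {
  X <- cbind(d1 = c(1, 2, 3, 4), d2 = c(10, 30, 20, 40))
  tbl <- dt_from_matrix(X)
  std <- standardize(tbl, train_ids = c("c001", "c002", "c003"))
  tr <- subset_rows(std$table, c("c001", "c002", "c003"))
  expect_lt(max(abs(colMeans(tr$X))), 1e-10)
  expect_lt(max(abs(apply(tr$X, 2, sd) - 1)), 1e-10)
  # held-out value with train mean 2, sd 1 maps to 2
  expect_equal(unname(std$table$X["c004", "d1"]), 2)
  back <- invert_standardization(std$table, std$record)
  expect_lt(max(abs(back$X - tbl$X)), 1e-12)

  const <- dt_from_matrix(cbind(d1 = c(1, 1, 1, 2)))
  expect_error(standardize(const, c("c001", "c002", "c003")),
               "degenerate-feature")
})

test_that("Topliss cases-to-descriptors ratio and its label", {
  r <- topliss_ratio(242, 14)
  expect_equal(as.numeric(r), 242 / 14, tolerance = 1e-12)
  expect_equal(attr(r, "label"), "17:1")
  expect_equal(as.numeric(topliss_ratio(70, 14)), 5)
  expect_equal(as.numeric(topliss_ratio(14, 14)), 1)
  expect_error(topliss_ratio(100, 0), "domain")
})

test_that("the packaged descriptor set is the 14-name 6/4/3/1 partition", {
  fds <- final_descriptor_set()
  expect_length(fds, 14)
  expect_equal(anyDuplicated(fds), 0L)
  expect_equal(as.integer(table(attr(fds, "group"))), c(6L, 4L, 3L, 1L))
  expect_true(all(c("TPSA", "MW", "logD", "MAXDN", "Me") %in% fds))
})
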