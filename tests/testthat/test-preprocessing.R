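# Block assembly, transformation/standardization, and loss weighting.

test_that("assemble_tensor places rows, masks absences, rejects bad input", {
  long <- data.frame(
    subject_id = c("s1", "s1", "s1", "s1", "s2", "s2", "s2"),
    variable = c("x", "x", "y", "y", "x", "x", "y"),
    time_months = c(1, 3, 1, 3, 1, 3, 1),
    value = 1:7
  )
  asm <- assemble_tensor(long, times = c(1, 3))
  expect_equal(dim(asm$tensor), c(2, 2, 2))
  expect_equal(sum(asm$mask), 7)
  expect_equal(sum(!asm$mask), 1)
  expect_false(asm$mask["s2", "y", "3"])
  expect_equal(asm$tensor["s1", "y", "3"], 4)
  # duplicated cell
  dup <- rbind(long, long[1, ])
  expect_error(assemble_tensor(dup, times = c(1, 3)), "duplicated cell")
  # unknown time / variable / empty subject
  bad_t <- long; bad_t$time_months[1] <- 2
  expect_error(assemble_tensor(bad_t, times = c(1, 3)), "outside the declared grid")
  expect_error(assemble_tensor(long, variables = c("x"), times = c(1, 3)),
               "unknown variable")
  expect_error(assemble_tensor(long, subjects = c("s1", "s2", "s3"),
                               times = c(1, 3)), "zero observations")
})

test_that("a full synthetic long table round-trips with an all-true mask", {
  co <- small_cohort(seed = 2, missing_rate = 0)
  long <- cmtf:::flatten_tensor(co$dataset$tensor, co$dataset$tensor_mask,
                                co$dataset$labels)
  asm <- assemble_tensor(long, subjects = co$dataset$labels$subjects,
                         variables = co$dataset$labels$biomarkers)
  expect_true(all(asm$mask))
  expect_equal(asm$tensor, co$dataset$tensor, tolerance = 1e-12)
})

test_that("standardization hits exact column moments and is idempotent", {
  co <- small_cohort(seed = 4)
  ds <- transform_and_scale(co$dataset)
  d <- dim(ds$tensor)
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    col <- ds$tensor[, j, k]
    obs <- !is.na(col)
    expect_lt(abs(mean(col[obs])), 1e-8)
    expect_lt(abs(sd(col[obs]) - 1), 1e-8)
  }
  expect_lt(max(abs(colMeans(ds$baseline))), 1e-8)
  expect_lt(max(abs(apply(ds$baseline, 2, sd) - 1)), 1e-8)
  # two observed values standardize to +-1/sqrt(2)
  toy <- array(NA_real_, c(2, 1, 2))
  toy[, 1, 1] <- c(1, 3); toy[, 1, 2] <- c(2, 5)
  toy_ds <- multiblock_dataset(toy, matrix(c(0, 1), 2, 1),
                               matrix(c(0, 2), 2, 1))
  std <- transform_and_scale(toy_ds)
  expect_equal(unname(std$tensor[, 1, 1]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # idempotence
  ds2 <- transform_and_scale(ds)
  expect_equal(ds2$tensor, ds$tensor, tolerance = 1e-10)
  expect_equal(ds2$baseline, ds$baseline, tolerance = 1e-10)
  expect_equal(ds2$gene, ds$gene, tolerance = 1e-10)
})

test_that("log transform applies before standardization and checks positivity", {
  co <- small_cohort(seed = 6)
  ds0 <- co$dataset
  ds0$tensor[, 1, ] <- exp(ds0$tensor[, 1, ])  # strictly positive variable
  v <- ds0$labels$biomarkers[1]
  logged <- transform_and_scale(ds0, log_vars = v)
  plain <- transform_and_scale(co$dataset)
  expect_equal(logged$tensor[, 1, ], plain$tensor[, 1, ], tolerance = 1e-10)
  ds_bad <- co$dataset  # values can be negative
  expect_error(transform_and_scale(ds_bad, log_vars = v), "non-positive value")
  expect_error(transform_and_scale(co$dataset, log_vars = "nope"),
               "not in the dataset")
})

test_that("constant columns are dropped (matrices) or masked (tensor) with warning", {
  co <- small_cohort(seed = 8)
  ds0 <- co$dataset
  ds0$gene[, 3] <- 1
  expect_warning(std <- transform_and_scale(ds0), "gene column")
  expect_equal(ncol(std$gene), ncol(co$dataset$gene) - 1)
  expect_false(co$dataset$labels$snps[3] %in% std$labels$snps)
  ds1 <- co$dataset
  ds1$tensor[, 2, 1] <- 7
  expect_warning(std1 <- transform_and_scale(ds1), "tensor column")
  expect_true(all(is.na(std1$tensor[, 2, 1])))
  expect_equal(dim(std1$tensor), dim(ds1$tensor))
})

test_that("block weights are reciprocal observed sums of squares", {
  toy <- array(NA_real_, c(2, 1, 2))
  toy[, 1, 1] <- c(1, 1); toy[, 1, 2] <- c(1, 1)
  ds <- multiblock_dataset(toy, matrix(c(2, 0), 2, 1), matrix(c(1, 1), 2, 1))
  ds$standardized <- TRUE
  w <- weight_blocks(ds)$block_weights
  expect_equal(unname(w), c(1 / 4, 1 / 4, 1 / 2))
  # weighted initial losses agree across standardized blocks
  co <- small_cohort(seed = 10)
  std <- preprocess(co$dataset)
  wl <- c(
    std$block_weights[1] * sum(std$tensor[std$tensor_mask]^2),
    std$block_weights[2] * sum(std$baseline[std$baseline_mask]^2),
    std$block_weights[3] * sum(std$gene[std$gene_mask]^2)
  )
  expect_equal(unname(wl), rep(1, 3), tolerance = 1e-9)
  # an all-masked block cannot be weighted
  ds_bad <- std
  ds_bad$gene[] <- NA_real_
  ds_bad$gene_mask[] <- FALSE
  expect_error(weight_blocks(ds_bad), "empty or all-masked")
})

test_that("every subject must keep at least one observed tensor entry", {
  toy <- array(NA_real_, c(2, 2, 2))
  toy[1, , ] <- 1
  expect_error(multiblock_dataset(toy, matrix(0, 2, 2), matrix(0, 2, 2)),
               "at least one observed")
})
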