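# The factorization engine: CP-ALS on masked tensors, the sparse coupled
# model, explained variation, and component alignment.

test_that("cp_als represents a noiseless rank-1 tensor exactly", {
  tc <- random_cp_tensor(12, 6, 4, rank = 1, seed = 11)
  m <- cp_als(tc$tensor, rank = 1, n_starts = 2, seed = 1)
  expect_equal(explained_variation(m, tc$tensor), 100, tolerance = 1e-6)
  expect_gt(abs(congruence_coefficient(m$biomarker_loadings[, 1], tc$B[, 1])),
            0.999)
  expect_gt(abs(congruence_coefficient(m$time_loadings[, 1], tc$C[, 1])), 0.999)
  expect_monotone_trace(m)
})

test_that("cp_als recovers rank-2 factors through 10% masking", {
  tc <- random_cp_tensor(20, 10, 4, rank = 2, seed = 21)
  set.seed(33)
  mask <- array(runif(length(tc$tensor)) >= 0.1, dim(tc$tensor))
  mask[rowSums(mask) == 0, 1, 1] <- TRUE
  X <- tc$tensor
  X[!mask] <- NA
  m <- cp_als(X, rank = 2, n_starts = 4, seed = 1)
  m <- align_components(m)
  # match columns by absolute congruence
  for (r in 1:2) {
    cb <- abs(c(congruence_coefficient(m$biomarker_loadings[, r], tc$B[, 1]),
                congruence_coefficient(m$biomarker_loadings[, r], tc$B[, 2])))
    expect_gt(max(cb), 0.999)
  }
  expect_monotone_trace(m)
})

test_that("cp_als agrees with the independent numpy reference on dense tensors", {
  # 5 tensors here; the acceptance suite runs the full 20-tensor battery
  fits <- cp_reference_fits(n_tensors = 5, I = 15, J = 8, K = 4, rank = 2,
                            noise_sd = 0.1, seed0 = 300)
  expect_true(all(is.finite(fits$reference)))
  expect_lt(max(abs(fits$package - fits$reference)), 1e-4)
})

test_that("dimension and mask preconditions are enforced", {
  tc <- random_cp_tensor(6, 5, 3, rank = 2, seed = 2)
  expect_error(cp_als(tc$tensor, rank = 4), "rank must be between")
  X <- tc$tensor
  X[2, , ] <- NA
  expect_error(cp_als(X, rank = 2), "at least one observation per subject")
})

test_that("cmtf_fit with negligible matrix blocks reduces to cp_als", {
  co <- small_cohort(seed = 31, noise_sd = c(0.1, 0.1, 0.1), missing_rate = 0)
  ds <- preprocess(co$dataset)
  # make the matrix blocks numerically irrelevant in the joint loss
  ds$block_weights[2:3] <- ds$block_weights[2:3] * 1e-8
  joint <- align_components(cmtf_fit(ds, rank = 2, lambda = 0, n_starts = 3,
                                     seed = 1, ridge_a = 0))
  alone <- align_components(cp_als(ds$tensor, rank = 2, n_starts = 3, seed = 1))
  mt <- match_components(
    structure(list(biomarker_loadings = joint$biomarker_loadings,
                   time_loadings = joint$time_loadings, rank = 2,
                   aligned = TRUE, baseline_loadings = NULL,
                   gene_loadings = NULL), class = "cmtf_model"),
    alone)
  expect_true(all(mt$overall >= 0.99))
})

test_that("noiseless coupled cohorts are recovered with exact gene zeros", {
  co <- small_cohort(seed = 41, noise_sd = c(0, 0, 0), missing_rate = 0,
                     dims = small_dims(subjects = 60),
                     sparsity = c(gene = 0.5))
  ds <- suppressWarnings(preprocess(co$dataset))
  m <- align_components(cmtf_fit(ds, rank = 2, lambda = 0.05, n_starts = 3,
                                 seed = 1))
  rc <- recovery_congruence(m, co)
  expect_gt(min(rc, na.rm = TRUE), 0.95)
  # true-zero gene loadings are estimated exactly zero
  tm <- truth_as_model(co)
  m <- cmtf:::expand_model_to_labels(m, co$dataset$labels)
  mt <- match_components(m, tm)
  for (r in 1:2) {
    true_zero <- tm$gene_loadings[, mt$pairing[r]] == 0
    expect_true(all(m$gene_loadings[true_zero, r] == 0))
  }
  expect_monotone_trace(m)
})

test_that("a saturating penalty empties the penalized modes", {
  co <- small_cohort(seed = 51)
  ds <- preprocess(co$dataset)
  m <- cmtf_fit(ds, rank = 2, lambda = 1.5, n_starts = 1, seed = 1,
                max_iter = 50)
  expect_true(all(m$biomarker_loadings == 0))
  expect_true(all(m$baseline_loadings == 0))
  expect_true(all(m$gene_loadings == 0))
  # with every penalized mode empty the loss is the total weighted SS
  total_ss <- sum(ds$block_weights * c(
    sum(ds$tensor[ds$tensor_mask]^2),
    sum(ds$baseline[ds$baseline_mask]^2),
    sum(ds$gene[ds$gene_mask]^2)))
  expect_equal(m$loss_trace[length(m$loss_trace)], total_ss, tolerance = 1e-6)
})

test_that("lambda and input validation errors are raised", {
  co <- small_cohort(seed = 61)
  ds <- preprocess(co$dataset)
  expect_error(cmtf_fit(ds, lambda = -0.1), "non-negative")
  expect_error(cmtf_fit(co$dataset), "standardized")
  expect_error(cmtf_fit(ds, rank = 0), "rank must be")
})

test_that("explained variation is 100% for perfect fits and 0% for null fits", {
  co <- small_cohort(seed = 71, noise_sd = c(0, 0, 0), missing_rate = 0,
                     discretize_genes = FALSE)
  tr <- co$truth
  perfect <- structure(list(
    subject_scores = tr$subject_scores,
    biomarker_loadings = tr$biomarker_loadings,
    time_loadings = tr$time_loadings,
    baseline_loadings = tr$baseline_loadings,
    gene_loadings = tr$gene_loadings,
    baseline_scale = NULL, gene_scale = NULL,
    rank = 2, aligned = FALSE, block_weights = c(1, 1, 1)),
    class = "cmtf_model")
  expect_equal(explained_variation(perfect, co$dataset, "tensor"), 100,
               tolerance = 1e-9)
  expect_equal(explained_variation(perfect, co$dataset, "baseline"), 100,
               tolerance = 1e-9)
  null_model <- perfect
  null_model$subject_scores <- 0 * perfect$subject_scores
  expect_equal(explained_variation(null_model, co$dataset, "tensor"), 0)
  expect_equal(explained_variation(null_model, co$dataset, "total"), 0)
})

test_that("alignment is idempotent, reconstruction-invariant, scale-invariant", {
  co <- small_cohort(seed = 81)
  ds <- preprocess(co$dataset)
  m <- cmtf_fit(ds, rank = 2, lambda = 0.05, n_starts = 2, seed = 1,
                max_iter = 150)
  a1 <- align_components(m)
  a2 <- align_components(a1)
  expect_equal(a1[names(a1) != "aligned"], a2[names(a2) != "aligned"],
               tolerance = 1e-12)
  for (bl in c("tensor", "baseline", "gene")) {
    expect_equal(cmtf:::model_recon(a1, bl), cmtf:::model_recon(m, bl),
                 tolerance = 1e-10)
  }
  # unit norms and sign convention
  expect_equal(unname(colSums(a1$biomarker_loadings^2)), rep(1, 2),
               tolerance = 1e-12)
  for (r in 1:2) {
    b <- a1$biomarker_loadings[, r]
    expect_gt(b[which.max(abs(b))], 0)
  }
  # rescaling a component by -3 pre-alignment (compensated across the
  # coupled modes so every reconstruction is unchanged) lands on the
  # same aligned model
  m2 <- m
  m2$subject_scores[, 1] <- m2$subject_scores[, 1] * -3
  m2$biomarker_loadings[, 1] <- m2$biomarker_loadings[, 1] / -3
  m2$baseline_loadings[, 1] <- m2$baseline_loadings[, 1] / -3
  m2$gene_loadings[, 1] <- m2$gene_loadings[, 1] / -3
  a3 <- align_components(m2)
  expect_equal(a3$subject_scores, a1$subject_scores, tolerance = 1e-9)
  expect_equal(a3$biomarker_loadings, a1$biomarker_loadings, tolerance = 1e-9)
  expect_equal(a3$baseline_scale, a1$baseline_scale, tolerance = 1e-9)
})

test_that("every fitted trace in a battery of random configs is monotone", {
  for (seed in 1:5) {
    co <- small_cohort(seed = seed, noise_sd = runif(3, 0.1, 0.5),
                       missing_rate = runif(1, 0, 0.3))
    ds <- preprocess(co$dataset)
    lam <- sample(c(0, 0.02, 0.1, 0.3), 1)
    m <- cmtf_fit(ds, rank = sample(1:3, 1), lambda = lam, n_starts = 2,
                  seed = seed, max_iter = 120)
    expect_monotone_trace(m)
  }
})
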