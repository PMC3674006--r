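# Shared fixtures: small coupled cohorts built in code.

small_dims <- function(subjects = 30, biomarkers = 8, timepoints = 4,
                       baseline_vars = 5, snps = 12) {
  list(subjects = subjects, biomarkers = biomarkers, timepoints = timepoints,
       baseline_vars = baseline_vars, snps = snps)
}

small_cohort <- function(seed = 1, noise_sd = c(0.2, 0.2, 0.2),
                         missing_rate = 0.1, dims = small_dims(), ...) {
  generate_cohort(dims = dims, rank = 2, noise_sd = noise_sd,
                  missing_rate = missing_rate, seed = seed, ...)
}

# rank-R tensor from seeded random factors, optional noise
random_cp_tensor <- function(I, J, K, rank, noise_sd = 0, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(I * rank), I, rank)
  B <- matrix(rnorm(J * rank), J, rank)
  C <- matrix(rnorm(K * rank), K, rank)
  X <- array(0, c(I, J, K))
  for (r in seq_len(rank)) {
    X <- X + outer(outer(A[, r], B[, r]), C[, r])
  }
  if (noise_sd > 0) X <- X + array(rnorm(I * J * K, sd = noise_sd), c(I, J, K))
  list(tensor = X, A = A, B = B, C = C)
}

expect_monotone_trace <- function(model, tol = 1e-9) {
  tr <- model$loss_trace
  expect_true(all(diff(tr) <= tol * (1 + abs(tr[-length(tr)]))),
              label = "loss trace non-increasing")
}
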