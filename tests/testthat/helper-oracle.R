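# Cross-check against the independent numpy CP-ALS reference
# (inst/reference/cp_reference.py): generates dense rank-`rank` tensors
# with noise, fits each with cp_als() and with the reference, and
# returns both relative fits (1 - RSS/TSS).

cp_reference_script <- function() {
  p <- system.file("reference", "cp_reference.py", package = "cmtf")
  if (p == "") p <- file.path("..", "..", "inst", "reference", "cp_reference.py")
  normalizePath(p)
}

cp_reference_fits <- function(n_tensors = 20, I = 15, J = 8, K = 4, rank = 2,
                              noise_sd = 0.1, seed0 = 1000, n_starts = 5) {
  dir <- tempfile("cpref")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  jobs <- character(n_tensors)
  pkg_fit <- numeric(n_tensors)
  for (t in seq_len(n_tensors)) {
    tc <- random_cp_tensor(I, J, K, rank = rank, noise_sd = noise_sd,
                           seed = seed0 + t)
    jobs[t] <- file.path(dir, sprintf("job%02d.txt", t))
    con <- file(jobs[t], "w")
    writeLines(paste(I, J, K, rank, n_starts), con)
    # column-major order matches the reference's Fortran-order reshape
    writeLines(format(as.vector(tc$tensor), digits = 17), con)
    close(con)
    m <- cp_als(tc$tensor, rank = rank, n_starts = n_starts, seed = 1,
                tol = 1e-12, max_iter = 2000)
    pkg_fit[t] <- explained_variation(m, tc$tensor) / 100
  }
  out <- system2("python", c(cp_reference_script(), jobs), stdout = TRUE)
  list(package = pkg_fit, reference = as.numeric(out))
}
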