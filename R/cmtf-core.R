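# Factorization engine: masked CP alternating least squares and its
# coupled, sparsity-penalized extension across three blocks sharing the
# subject mode.
#
# Objective (block weights w, L1 penalties lambda, scale ridge mu):
#   f = w1 |M  o (X  - [[A,B,C]])|^2            (biomarker tensor)
#     + w2 |Mb o (Xb - A D')|^2                 (baseline matrix)
#     + w3 |Mg o (Xg - A E')|^2                 (gene matrix)
#     + lamB |B|_1 + lamD |D|_1 + lamE |E|_1 + mu |A|_F^2
# Every ALS sweep performs exact block-coordinate minimization (ridge
# least squares for A and C; coordinate-descent lasso for B, D, E), so
# the recorded loss trace is non-increasing by construction.  The ridge
# on A pins down the scale indeterminacy that an L1 penalty on the
# loadings would otherwise drive to zero by inflating A.

cmtf_engine <- function(X, mask, Xb = NULL, Mb = NULL, Xg = NULL, Mg = NULL,
                        weights = c(1, 1, 1), rank = 2,
                        lambda = c(0, 0, 0), ridge = 0,
                        init, tol = 1e-8, max_iter = 500, support = NULL) {
  d <- dim(X)
  R <- rank
  pi <- pair_index(R)
  Xz <- X; Xz[!mask] <- 0
  M1 <- unfold3(mask * 1, 1); X1 <- unfold3(Xz, 1)
  M2 <- unfold3(mask * 1, 2); X2 <- unfold3(Xz, 2)
  M3 <- unfold3(mask * 1, 3); X3 <- unfold3(Xz, 3)
  has_b <- !is.null(Xb); has_g <- !is.null(Xg)
  if (has_b) { Mbn <- Mb * 1; Xbz <- Xb; Xbz[!Mb] <- 0 }
  if (has_g) { Mgn <- Mg * 1; Xgz <- Xg; Xgz[!Mg] <- 0 }
  w <- unname(weights)
  lamB <- lambda[1]; lamD <- lambda[2]; lamE <- lambda[3]

  A <- init$A; B <- init$B; C <- init$C
  D <- if (has_b) init$D else NULL
  E <- if (has_g) init$E else NULL

  loss <- function() {
    f <- w[1] * sum(M1 * (X1 - A %*% t(khatri_rao(C, B)))^2)
    if (has_b) f <- f + w[2] * sum(Mbn * (Xbz - A %*% t(D))^2)
    if (has_g) f <- f + w[3] * sum(Mgn * (Xgz - A %*% t(E))^2)
    f + lamB * sum(abs(B)) + (if (has_b) lamD * sum(abs(D)) else 0) +
      (if (has_g) lamE * sum(abs(E)) else 0) + ridge * sum(A^2)
  }

  trace <- loss()
  for (it in seq_len(max_iter)) {
    # shared subject scores: ridge LS pooling all blocks
    Z1 <- khatri_rao(C, B)
    G <- w[1] * (M1 %*% pair_products(Z1, pi))
    Rhs <- w[1] * (X1 %*% Z1)
    if (has_b) {
      G <- G + w[2] * (Mbn %*% pair_products(D, pi))
      Rhs <- Rhs + w[2] * (Xbz %*% D)
    }
    if (has_g) {
      G <- G + w[3] * (Mgn %*% pair_products(E, pi))
      Rhs <- Rhs + w[3] * (Xgz %*% E)
    }
    A <- solve_rows(G, Rhs, pi, ridge = ridge)

    # biomarker loadings (penalized)
    Z2 <- khatri_rao(C, A)
    G2 <- w[1] * (M2 %*% pair_products(Z2, pi))
    R2 <- w[1] * (X2 %*% Z2)
    B <- if (!is.null(support)) solve_rows_support(G2, R2, pi, support$B)
         else if (lamB > 0) cd_lasso_rows(G2, R2, B, pi, lamB)
         else solve_rows(G2, R2, pi)

    # time loadings (never penalized: visit profiles stay dense)
    Z3 <- khatri_rao(B, A)
    G3 <- w[1] * (M3 %*% pair_products(Z3, pi))
    R3 <- w[1] * (X3 %*% Z3)
    C <- solve_rows(G3, R3, pi)

    if (has_b) {
      GD <- w[2] * (t(Mbn) %*% pair_products(A, pi))
      RD <- w[2] * (t(Xbz) %*% A)
      D <- if (!is.null(support)) solve_rows_support(GD, RD, pi, support$D)
           else if (lamD > 0) cd_lasso_rows(GD, RD, D, pi, lamD)
           else solve_rows(GD, RD, pi)
    }
    if (has_g) {
      GE <- w[3] * (t(Mgn) %*% pair_products(A, pi))
      RE <- w[3] * (t(Xgz) %*% A)
      E <- if (!is.null(support)) solve_rows_support(GE, RE, pi, support$E)
           else if (lamE > 0) cd_lasso_rows(GE, RE, E, pi, lamE)
           else solve_rows(GE, RE, pi)
    }

    f <- loss()
    trace <- c(trace, f)
    prev <- trace[length(trace) - 1]
    if (is.finite(prev) && prev > 0 && abs(prev - f) / prev < tol) break
  }
  list(A = A, B = B, C = C, D = D, E = E,
       loss_trace = trace, converged = (it < max_iter))
}

# Spectral (slice-unfolding singular vector) initialization; masked
# entries enter as zeros, which is neutral on centered data.
init_spectral <- function(X, mask, Xb, Mb, Xg, Mg, rank, pi) {
  Xz <- X; Xz[!mask] <- 0
  B <- svd(unfold3(Xz, 2), nu = rank)$u[, seq_len(rank), drop = FALSE]
  C <- svd(unfold3(Xz, 3), nu = rank)$u[, seq_len(rank), drop = FALSE]
  A <- ls_subject_scores(X, mask, B, C, pi)
  finish_init(A, B, C, Xb, Mb, Xg, Mg, pi)
}

init_random <- function(X, mask, Xb, Mb, Xg, Mg, rank, pi) {
  d <- dim(X)
  B <- dense_loadings(d[2], rank)
  C <- dense_loadings(d[3], rank)
  A <- ls_subject_scores(X, mask, B, C, pi)
  finish_init(A, B, C, Xb, Mb, Xg, Mg, pi)
}

ls_subject_scores <- function(X, mask, B, C, pi) {
  Xz <- X; Xz[!mask] <- 0
  Z1 <- khatri_rao(C, B)
  M1 <- unfold3(mask * 1, 1)
  G <- M1 %*% pair_products(Z1, pi)
  solve_rows(G, unfold3(Xz, 1) %*% Z1, pi)
}

finish_init <- function(A, B, C, Xb, Mb, Xg, Mg, pi) {
  ls_mat <- function(Xm, Mm) {
    Xz <- Xm; Xz[!Mm] <- 0
    G <- t(Mm * 1) %*% pair_products(A, pi)
    solve_rows(G, t(Xz) %*% A, pi)
  }
  list(A = A, B = B, C = C,
       D = if (!is.null(Xb)) ls_mat(Xb, Mb) else NULL,
       E = if (!is.null(Xg)) ls_mat(Xg, Mg) else NULL)
}

new_cmtf_model <- function(fit, rank, lambda, ridge, weights, n_starts,
                           start_losses, seed, labels = NULL) {
  structure(list(
    subject_scores = fit$A,
    biomarker_loadings = fit$B,
    time_loadings = fit$C,
    baseline_loadings = fit$D,
    gene_loadings = fit$E,
    baseline_scale = if (!is.null(fit$D)) rep(1, rank) else NULL,
    gene_scale = if (!is.null(fit$E)) rep(1, rank) else NULL,
    rank = rank, lambda = lambda, ridge = ridge,
    block_weights = weights,
    loss_trace = fit$loss_trace,
    converged = fit$converged,
    n_starts = n_starts, start_losses = start_losses,
    seed = seed, labels = labels, aligned = FALSE,
    component_tensor_ss = NULL
  ), class = "cmtf_model")
}

#' Masked CP/PARAFAC decomposition by alternating least squares
#'
#' Fits a rank-`rank` CP model to a 3-way array on its observed entries
#' only, by alternating exact least-squares updates of the subject,
#' variable and time factor matrices.  The best of `n_starts` runs (one
#' spectral start from slice-unfolding singular vectors, the rest
#' random) by final loss is returned; each run's loss trace is
#' non-increasing.
#'
#' @param tensor 3-way numeric array; NA entries are treated as missing.
#' @param mask Optional logical array, TRUE = observed (defaults to
#'   `!is.na(tensor)`).
#' @param rank Number of components; must not exceed any mode dimension.
#' @param n_starts Number of initializations (default 10).
#' @param tol Relative loss-change convergence tolerance (default 1e-8).
#' @param max_iter Maximum ALS sweeps per start (default 500).
#' @param seed Integer seed controlling the random starts.
#' @return A `cmtf_model` with `subject_scores`, `biomarker_loadings`,
#'   `time_loadings`, the loss trace of the winning start, and a
#'   `converged` flag (FALSE if `max_iter` was exhausted).
#' @export
cp_als <- function(tensor, mask = NULL, rank = 2, n_starts = 10,
                   tol = 1e-8, max_iter = 500, seed = 1) {
  d <- dim(tensor)
  if (length(d) != 3) stop("tensor must be a 3-way array")
  if (rank < 1 || rank > min(d)) {
    stop("rank must be between 1 and the smallest mode dimension (", min(d), ")")
  }
  if (is.null(mask)) mask <- !is.na(tensor)
  if (!all(apply(mask, 1, any))) {
    stop("mask must leave at least one observation per subject")
  }
  pi <- pair_index(rank)
  with_seed(seed, {
    best <- NULL; losses <- numeric(n_starts)
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) init_spectral(tensor, mask, NULL, NULL, NULL, NULL, rank, pi)
              else init_random(tensor, mask, NULL, NULL, NULL, NULL, rank, pi)
      fit <- cmtf_engine(tensor, mask, rank = rank, lambda = c(0, 0, 0),
                         ridge = 0, init = init, tol = tol, max_iter = max_iter)
      losses[s] <- fit$loss_trace[length(fit$loss_trace)]
      if (is.null(best) || losses[s] < best$loss_trace[length(best$loss_trace)]) {
        best <- fit
      }
    }
    new_cmtf_model(best, rank, lambda = c(0, 0, 0), ridge = 0,
                   weights = c(1, NA, NA), n_starts = n_starts,
                   start_losses = losses, seed = seed)
  })
}

#' Sparse coupled matrix-tensor factorization
#'
#' Jointly factorizes the biomarker tensor, baseline matrix and gene
#' matrix of a standardized, weighted [multiblock_dataset] over a shared
#' subject-score matrix, minimizing the weighted observed-entry squared
#' reconstruction error plus an L1 penalty on the biomarker, baseline
#' and gene loadings.  Soft-thresholding sets small-contribution
#' loadings to exactly zero, so each component reflects a subset of the
#' variables; the time mode is never penalized.  A small ridge on the
#' subject scores (scaled to the block weights) pins down the scale
#' indeterminacy of the penalized objective.  Best of `n_starts`
#' initializations is returned.
#'
#' @param dataset A standardized [multiblock_dataset] with block weights
#'   (see [preprocess()]).
#' @param rank Number of shared components (default 2).
#' @param lambda Non-negative L1 penalties, named `biomarker`,
#'   `baseline`, `gene` (a single value is recycled).  Each is expressed
#'   as a fraction of that mode's `lambda_max` — the smallest absolute
#'   penalty that would zero the whole mode at the spectral
#'   initialization — so a given value has a comparable bite in every
#'   mode; `lambda >= 1` empties the penalized modes.  Default 0.05 each.
#' @param n_starts,tol,max_iter,seed As in [cp_als()].
#' @param ridge_a Relative ridge on the subject scores; the absolute
#'   ridge is `ridge_a * sum(block_weights)` (default 0.01).
#' @param relax After the penalized fit converges, refit by least
#'   squares restricted to the selected support (zeros stay zero),
#'   removing the soft-threshold shrinkage bias from the surviving
#'   loadings (the relaxed-lasso convention).  Off by default: at the
#'   moderate default penalties the shrinkage bias is small and
#'   relaxation mostly re-inflates noisy coefficients; it pays off at
#'   sparser penalties.
#' @return A `cmtf_model` with all five factor matrices, the penalized
#'   loss trace (`loss_trace`; the relaxed refit's own non-increasing
#'   trace is kept in `relax_trace`), block weights, and convergence
#'   flag.
#' @export
cmtf_fit <- function(dataset, rank = 2,
                     lambda = c(biomarker = 0.1, baseline = 0.1, gene = 0.3),
                     n_starts = 10, tol = 1e-8, max_iter = 500, seed = 1,
                     ridge_a = 0.01, relax = FALSE) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (!isTRUE(dataset$standardized) || is.null(dataset$block_weights)) {
    stop("cmtf_fit needs a standardized, weighted dataset; run preprocess() first")
  }
  lambda <- expand_lambda(lambda)
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (ridge_a < 0) stop("ridge_a must be non-negative")
  d <- dim(dataset$tensor)
  dims_all <- c(d, ncol(dataset$baseline), ncol(dataset$gene))
  if (rank < 1 || rank > min(dims_all)) {
    stop("rank must be between 1 and the smallest dimension (", min(dims_all), ")")
  }
  w <- dataset$block_weights
  mu <- ridge_a * sum(w)
  pi <- pair_index(rank)
  X <- dataset$tensor; mask <- dataset$tensor_mask
  Xb <- dataset$baseline; Mb <- dataset$baseline_mask
  Xg <- dataset$gene; Mg <- dataset$gene_mask
  # Penalties are specified as fractions of each mode's lambda_max (the
  # smallest absolute penalty that zeroes the whole mode at the spectral
  # initialization), so one value has a comparable bite in every mode.
  sp_init <- init_spectral(X, mask, Xb, Mb, Xg, Mg, rank, pi)
  lam_abs <- lambda * lambda_max_modes(X, mask, Xb, Mb, Xg, Mg, w, sp_init, pi)
  with_seed(seed, {
    best <- NULL; losses <- numeric(n_starts)
    for (s in seq_len(n_starts)) {
      init <- if (s == 1) sp_init
              else init_random(X, mask, Xb, Mb, Xg, Mg, rank, pi)
      fit <- cmtf_engine(X, mask, Xb, Mb, Xg, Mg, weights = w, rank = rank,
                         lambda = lam_abs, ridge = mu, init = init,
                         tol = tol, max_iter = max_iter)
      losses[s] <- fit$loss_trace[length(fit$loss_trace)]
      if (is.null(best) || losses[s] < best$loss_trace[length(best$loss_trace)]) {
        best <- fit
      }
    }
    relax_trace <- NULL
    if (relax && any(lam_abs > 0)) {
      # relaxed refit: freeze the selected support, drop the L1 penalty,
      # re-estimate by support-restricted least squares to remove the
      # soft-threshold shrinkage bias from the surviving loadings
      supp <- list(B = best$B != 0, D = if (!is.null(best$D)) best$D != 0,
                   E = if (!is.null(best$E)) best$E != 0)
      rel <- cmtf_engine(X, mask, Xb, Mb, Xg, Mg, weights = w, rank = rank,
                         lambda = c(0, 0, 0), ridge = mu, init = best,
                         tol = tol, max_iter = max_iter, support = supp)
      relax_trace <- rel$loss_trace
      rel$converged <- rel$converged && best$converged
      rel$loss_trace <- best$loss_trace
      best <- rel
    }
    mod <- new_cmtf_model(best, rank, lambda = lambda, ridge = mu, weights = w,
                          n_starts = n_starts, start_losses = losses,
                          seed = seed, labels = dataset$labels)
    mod$lambda_abs <- lam_abs
    mod$relax_trace <- relax_trace
    mod
  })
}

# Per-mode lambda_max: by the lasso subgradient condition a mode is
# entirely zeroed once the absolute penalty exceeds twice the largest
# (weighted) regression cross-product, evaluated at the spectral
# initialization.
lambda_max_modes <- function(X, mask, Xb, Mb, Xg, Mg, w, init, pi) {
  Xz <- X; Xz[!mask] <- 0
  R2 <- w[1] * (unfold3(Xz, 2) %*% khatri_rao(init$C, init$A))
  lam_B <- 2 * max(abs(R2))
  lam_D <- if (!is.null(Xb)) {
    Xbz <- Xb; Xbz[!Mb] <- 0
    2 * max(abs(w[2] * (t(Xbz) %*% init$A)))
  } else 0
  lam_E <- if (!is.null(Xg)) {
    Xgz <- Xg; Xgz[!Mg] <- 0
    2 * max(abs(w[3] * (t(Xgz) %*% init$A)))
  } else 0
  c(lam_B, lam_D, lam_E)
}

expand_lambda <- function(lambda) {
  if (length(lambda) == 1) lambda <- rep(lambda, 3)
  if (!is.null(names(lambda)) && all(c("biomarker", "baseline", "gene") %in% names(lambda))) {
    lambda <- lambda[c("biomarker", "baseline", "gene")]
  }
  if (length(lambda) != 3) stop("lambda must have length 1 or 3")
  unname(lambda)
}

#' @export
print.cmtf_model <- function(x, ...) {
  cat("cmtf_model: rank ", x$rank,
      if (x$aligned) " (aligned)" else "",
      ", converged = ", x$converged,
      ", final loss ", signif(x$loss_trace[length(x$loss_trace)], 6), "\n", sep = "")
  if (!is.null(x$biomarker_loadings)) {
    nz <- function(m) if (is.null(m)) NA_integer_ else sum(m != 0)
    cat("  nonzero loadings: biomarker ", nz(x$biomarker_loadings),
        if (!is.null(x$baseline_loadings)) paste0(", baseline ", nz(x$baseline_loadings)),
        if (!is.null(x$gene_loadings)) paste0(", gene ", nz(x$gene_loadings)),
        "\n", sep = "")
  }
  invisible(x)
}

# Reconstructions of each block from the (possibly aligned) model.
model_recon <- function(model, block) {
  switch(block,
    tensor = recon_tensor(model$subject_scores, model$biomarker_loadings,
                          model$time_loadings),
    baseline = recon_matrix(model$subject_scores, model$baseline_loadings,
                            model$baseline_scale),
    gene = recon_matrix(model$subject_scores, model$gene_loadings,
                        model$gene_scale),
    stop("unknown block: ", block)
  )
}

#' Percent of a block's variation explained by the model
#'
#' `100 * (1 - RSS / TSS)` over the observed entries of the named block;
#' `"total"` pools all blocks with the model's block weights so each
#' block enters on the same footing.
#'
#' @param model A fitted `cmtf_model`.
#' @param dataset The dataset the model was fitted on (for a tensor-only
#'   model a plain 3-way array is accepted).
#' @param block One of `"tensor"`, `"baseline"`, `"gene"`, `"total"`.
#' @return Percentage (scalar).
#' @export
explained_variation <- function(model, dataset, block = "tensor") {
  stopifnot(inherits(model, "cmtf_model"))
  if (is.array(dataset) && length(dim(dataset)) == 3) {
    if (block != "tensor") stop("a plain array only supports block = 'tensor'")
    dataset <- list(tensor = dataset, tensor_mask = !is.na(dataset))
  }
  rss_tss <- function(bl) {
    obj <- switch(bl, tensor = dataset$tensor, baseline = dataset$baseline,
                  gene = dataset$gene)
    msk <- switch(bl, tensor = dataset$tensor_mask, baseline = dataset$baseline_mask,
                  gene = dataset$gene_mask)
    if (is.null(obj)) stop("dataset has no ", bl, " block")
    hat <- model_recon(model, bl)
    if (!identical(dim(hat), dim(obj))) {
      stop("model/dataset dimension mismatch for block ", bl)
    }
    c(rss = sum((obj[msk] - hat[msk])^2), tss = sum(obj[msk]^2))
  }
  if (block == "total") {
    blocks <- c("tensor", "baseline", "gene")
    have <- blocks[c(TRUE, !is.null(model$baseline_loadings),
                     !is.null(model$gene_loadings))]
    w <- model$block_weights[match(have, blocks)]
    parts <- vapply(have, rss_tss, numeric(2))
    return(100 * (1 - sum(w * parts["rss", ]) / sum(w * parts["tss", ])))
  }
  p <- rss_tss(block)
  100 * (1 - p[["rss"]] / p[["tss"]])
}

#' Normalize, sign-fix and order the components of a fitted model
#'
#' Resolves the scale, sign and permutation indeterminacies of a CP /
#' coupled factorization into a canonical form: biomarker and time
#' loading columns are scaled to unit Euclidean norm with the tensor
#' scale absorbed into the subject scores; baseline and gene loading
#' columns are scaled to unit norm with their scale carried in
#' non-negative per-component weights (`baseline_scale`, `gene_scale`),
#' since one shared score matrix cannot absorb every block's scale at
#' once; the sign conventions make the largest-magnitude biomarker
#' loading and the largest-magnitude time loading of each component
#' positive (the latter flips the scores and matrix-block loadings with
#' it, so baseline/gene signs are read against the stated direction of
#' the time course); components are sorted by their
#' tensor-block explained sum of squares, descending.  All block
#' reconstructions are unchanged.  Idempotent.
#'
#' @param model A fitted `cmtf_model`.
#' @return The aligned model (`aligned = TRUE`, with
#'   `component_tensor_ss` filled in).
#' @export
align_components <- function(model) {
  stopifnot(inherits(model, "cmtf_model"))
  A <- model$subject_scores; B <- model$biomarker_loadings
  C <- model$time_loadings
  D <- model$baseline_loadings; E <- model$gene_loadings
  sD <- model$baseline_scale; sE <- model$gene_scale
  R <- model$rank
  for (r in seq_len(R)) {
    bn <- sqrt(sum(B[, r]^2)); cn <- sqrt(sum(C[, r]^2))
    sc <- bn * cn
    if (sc > 0) {
      B[, r] <- B[, r] / bn
      C[, r] <- C[, r] / cn
      A[, r] <- A[, r] * sc
    }
    an_scale <- if (sc > 0) sc else 1
    if (!is.null(D)) {
      dn <- sqrt(sum((sD[r] * D[, r])^2))
      sD[r] <- dn / an_scale
      if (dn > 0) D[, r] <- (D[, r] * sign(sD[r])) / sqrt(sum(D[, r]^2))
      sD[r] <- abs(sD[r])
    }
    if (!is.null(E)) {
      en <- sqrt(sum((sE[r] * E[, r])^2))
      sE[r] <- en / an_scale
      if (en > 0) E[, r] <- (E[, r] * sign(sE[r])) / sqrt(sum(E[, r]^2))
      sE[r] <- abs(sE[r])
    }
    # sign convention: dominant biomarker loading positive
    ref <- if (any(B[, r] != 0)) B[, r]
           else if (!is.null(D) && any(D[, r] != 0)) D[, r]
           else if (!is.null(E) && any(E[, r] != 0)) E[, r]
           else A[, r]
    sgn <- sign(ref[which.max(abs(ref))])
    if (length(sgn) && is.finite(sgn) && sgn < 0) {
      B[, r] <- -B[, r]; A[, r] <- -A[, r]
      if (!is.null(D)) D[, r] <- -D[, r]
      if (!is.null(E)) E[, r] <- -E[, r]
    }
    # second convention: dominant time loading positive; flipping the
    # time profile together with the scores (and hence the matrix-block
    # loadings) leaves every reconstruction unchanged and ties the
    # baseline/gene signs to the stated direction of the time course
    if (any(C[, r] != 0)) {
      sgn_c <- sign(C[which.max(abs(C[, r])), r])
      if (is.finite(sgn_c) && sgn_c < 0) {
        C[, r] <- -C[, r]; A[, r] <- -A[, r]
        if (!is.null(D)) D[, r] <- -D[, r]
        if (!is.null(E)) E[, r] <- -E[, r]
      }
    }
  }
  # order by tensor-block component SS (masked SS of each rank-1 term)
  comp_ss <- vapply(seq_len(R), function(r) {
    sum_sq(A[, r]) * sum_sq(B[, r]) * sum_sq(C[, r])
  }, numeric(1))
  ord <- order(comp_ss, decreasing = TRUE)
  model$subject_scores <- A[, ord, drop = FALSE]
  model$biomarker_loadings <- B[, ord, drop = FALSE]
  model$time_loadings <- C[, ord, drop = FALSE]
  if (!is.null(D)) {
    model$baseline_loadings <- D[, ord, drop = FALSE]
    model$baseline_scale <- sD[ord]
  }
  if (!is.null(E)) {
    model$gene_loadings <- E[, ord, drop = FALSE]
    model$gene_scale <- sE[ord]
  }
  model$component_tensor_ss <- comp_ss[ord]
  model$aligned <- TRUE
  model
}

#' One component's loading pattern across all modes
#'
#' Extracts component `r` of an aligned model as labelled per-mode
#' loading vectors plus its tensor-block explained-variation share — the
#' bar-chart-ready object for pattern figures.
#'
#' @param model An aligned `cmtf_model` (see [align_components()]).
#' @param r Component index.
#' @param dataset Optional dataset for the explained-variation share.
#' @return List of class `component_pattern`.
#' @export
component_pattern <- function(model, r, dataset = NULL) {
  stopifnot(inherits(model, "cmtf_model"), r >= 1, r <= model$rank)
  if (!model$aligned) model <- align_components(model)
  lb <- model$labels
  nm <- function(v, labs) {
    if (!is.null(labs) && length(labs) == length(v)) stats::setNames(v, labs) else v
  }
  ev <- if (!is.null(dataset)) {
    one <- model
    keep <- function(m) m[, r, drop = FALSE]
    one$subject_scores <- keep(model$subject_scores)
    one$biomarker_loadings <- keep(model$biomarker_loadings)
    one$time_loadings <- keep(model$time_loadings)
    if (!is.null(model$baseline_loadings)) {
      one$baseline_loadings <- keep(model$baseline_loadings)
      one$baseline_scale <- model$baseline_scale[r]
    }
    if (!is.null(model$gene_loadings)) {
      one$gene_loadings <- keep(model$gene_loadings)
      one$gene_scale <- model$gene_scale[r]
    }
    one$rank <- 1L
    explained_variation(one, dataset, "tensor")
  } else NA_real_
  structure(list(
    component = r,
    biomarker = nm(model$biomarker_loadings[, r], lb$biomarkers),
    time = nm(model$time_loadings[, r], lb$times),
    baseline = if (!is.null(model$baseline_loadings))
      nm(model$baseline_loadings[, r], lb$baseline_vars),
    baseline_scale = model$baseline_scale[r],
    gene = if (!is.null(model$gene_loadings))
      nm(model$gene_loadings[, r], lb$snps),
    gene_scale = model$gene_scale[r],
    explained_tensor_pct = ev
  ), class = "component_pattern")
}

#' @export
print.component_pattern <- function(x, ...) {
  cat("Component ", x$component, "\n", sep = "")
  if (is.finite(x$explained_tensor_pct)) {
    cat("  tensor variation explained: ",
        round(x$explained_tensor_pct, 1), "%\n", sep = "")
  }
  show <- function(v, what) {
    if (is.null(v)) return()
    nz <- v[v != 0]
    cat("  ", what, " (", length(nz), "/", length(v), " nonzero): ",
        paste(names(nz) %||% seq_along(nz), "=", signif(nz, 2),
              collapse = ", "), "\n", sep = "")
  }
  show(x$biomarker, "biomarkers")
  cat("  time profile: ", paste(signif(x$time, 3), collapse = ", "), "\n", sep = "")
  show(x$baseline, "baseline")
  show(x$gene, "genes")
  invisible(x)
}
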