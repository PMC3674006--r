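# Internal numerical helpers shared by the factorization engine.

#' Run code with a local, restorable RNG state
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so library functions never perturb user-level
#' reproducibility.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Column-wise Khatri-Rao product
#'
#' For U (n x R) and V (m x R) returns the (n*m) x R matrix whose r-th
#' column is kronecker(U[, r], V[, r]); rows are ordered with the V index
#' varying fastest, matching R's column-major array unfoldings.
#' @noRd
khatri_rao <- function(U, V) {
  R <- ncol(U)
  stopifnot(ncol(V) == R)
  n <- nrow(U); m <- nrow(V)
  out <- matrix(0, n * m, R)
  for (r in seq_len(R)) {
    out[, r] <- rep(U[, r], each = m) * V[, r]
  }
  out
}

# Mode-n unfoldings of a 3-way array X (I x J x K).  Columns of the
# unfolding are ordered so the *first* remaining mode varies fastest,
# consistent with khatri_rao() above:
#   mode 1: I x (J*K), column (j,k) at (k-1)*J + j, design khatri_rao(C, B)
#   mode 2: J x (I*K), column (i,k) at (k-1)*I + i, design khatri_rao(C, A)
#   mode 3: K x (I*J), column (i,j) at (j-1)*I + i, design khatri_rao(B, A)
unfold3 <- function(X, mode) {
  d <- dim(X)
  switch(mode,
    `1` = { dim(X) <- c(d[1], d[2] * d[3]); X },
    `2` = { X <- aperm(X, c(2, 1, 3)); dim(X) <- c(d[2], d[1] * d[3]); X },
    `3` = { X <- aperm(X, c(3, 1, 2)); dim(X) <- c(d[3], d[1] * d[2]); X },
    stop("mode must be 1, 2 or 3")
  )
}

# Index bookkeeping for packed symmetric R x R Gram matrices stored as
# n x npair matrices (one row per least-squares subproblem).
pair_index <- function(R) {
  idx <- matrix(0L, R, R)
  pairs <- list()
  p <- 0L
  for (r in seq_len(R)) for (s in r:R) {
    p <- p + 1L
    idx[r, s] <- idx[s, r] <- p
    pairs[[p]] <- c(r, s)
  }
  list(idx = idx, pairs = do.call(rbind, pairs), npair = p)
}

# Z (q x R) -> q x npair matrix of elementwise column products Z_r * Z_s.
pair_products <- function(Z, pi) {
  out <- matrix(0, nrow(Z), pi$npair)
  for (p in seq_len(pi$npair)) {
    rs <- pi$pairs[p, ]
    out[, p] <- Z[, rs[1]] * Z[, rs[2]]
  }
  out
}

# Solve n independent ridge least-squares systems (G_i + ridge I) b_i = rhs_i
# where G_i is the i-th row of the packed Gram matrix.  Vectorized closed
# forms for R = 1, 2; row loop otherwise.  Singular rows fall back to a
# pseudo-inverse so dead components yield zero coefficients.
solve_rows <- function(Gp, rhs, pi, ridge = 0) {
  R <- ncol(rhs)
  n <- nrow(rhs)
  eps <- 1e-12
  if (R == 1L) {
    den <- Gp[, 1] + ridge
    out <- rhs
    out[, 1] <- ifelse(den > eps, rhs[, 1] / den, 0)
    return(out)
  }
  if (R == 2L) {
    g11 <- Gp[, pi$idx[1, 1]] + ridge
    g22 <- Gp[, pi$idx[2, 2]] + ridge
    g12 <- Gp[, pi$idx[1, 2]]
    det <- g11 * g22 - g12 * g12
    ok <- det > eps * pmax(g11 * g22, eps)
    out <- matrix(0, n, 2)
    out[ok, 1] <- (g22[ok] * rhs[ok, 1] - g12[ok] * rhs[ok, 2]) / det[ok]
    out[ok, 2] <- (g11[ok] * rhs[ok, 2] - g12[ok] * rhs[ok, 1]) / det[ok]
    if (any(!ok)) {
      for (i in which(!ok)) out[i, ] <- solve_one(Gp[i, ], rhs[i, ], pi, ridge)
    }
    return(out)
  }
  out <- matrix(0, n, R)
  for (i in seq_len(n)) out[i, ] <- solve_one(Gp[i, ], rhs[i, ], pi, ridge)
  out
}

solve_one <- function(grow, r, pi, ridge) {
  R <- length(r)
  G <- matrix(grow[pi$idx], R, R) + diag(ridge, R)
  sv <- svd(G)
  pos <- sv$d > max(sv$d[1], 1e-300) * 1e-10
  if (!any(pos)) return(rep(0, R))
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], r)) / sv$d[pos])
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# Coordinate descent for n independent lasso subproblems sharing structure:
# minimize over row b_i of  b_i' G_i b_i - 2 rhs_i . b_i + lambda * |b_i|_1
# (G, rhs already carry the block weight).  Each half-update is an exact
# coordinate minimization, so the penalized objective never increases.
cd_lasso_rows <- function(Gp, rhs, B, pi, lambda, max_pass = 12, tol = 1e-11) {
  R <- ncol(B)
  thr <- lambda / 2
  dg <- vector("list", R)
  for (r in seq_len(R)) {
    d <- Gp[, pi$idx[r, r]]
    dead <- d <= 1e-12
    d[dead] <- 1
    dg[[r]] <- list(d = d, dead = dead)
  }
  for (pass in seq_len(max_pass)) {
    delta <- 0
    for (r in seq_len(R)) {
      rho <- rhs[, r]
      for (s in seq_len(R)) {
        if (s != r) rho <- rho - Gp[, pi$idx[r, s]] * B[, s]
      }
      st <- abs(rho) - thr
      st[st < 0] <- 0
      new <- sign(rho) * st / dg[[r]]$d
      new[dg[[r]]$dead] <- 0
      delta <- max(delta, abs(new - B[, r]))
      B[, r] <- new
    }
    if (delta < tol) break
  }
  B
}

# Exact per-row least squares restricted to a fixed support pattern
# (row-wise logical mask).  Used by the relaxed (debiasing) refit: the
# lasso-selected zeros stay zero, the surviving coefficients lose their
# soft-threshold shrinkage.
solve_rows_support <- function(Gp, rhs, pi, support) {
  R <- ncol(rhs)
  out <- matrix(0, nrow(rhs), R)
  for (i in seq_len(nrow(rhs))) {
    on <- which(support[i, ])
    if (!length(on)) next
    G <- matrix(Gp[i, pi$idx], R, R)[on, on, drop = FALSE]
    r <- rhs[i, on]
    sv <- svd(G)
    pos <- sv$d > max(sv$d[1], 1e-300) * 1e-10
    if (!any(pos)) next
    out[i, on] <- sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], r) / sv$d[pos])
  }
  out
}

# Rank-R CP reconstruction of a 3-way array from factor matrices.
recon_tensor <- function(A, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  X1 <- A %*% t(khatri_rao(C, B))
  array(X1, dim = c(I, J, K))
}

# Matrix-block reconstruction with optional per-component scale weights.
recon_matrix <- function(A, D, scale = NULL) {
  if (is.null(scale)) A %*% t(D) else A %*% (scale * t(D))
}

sum_sq <- function(x) sum(x * x)
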