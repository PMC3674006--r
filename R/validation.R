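# Internal (permutation) and external (split-half) validation of a
# coupled factor model: per-block subject scores, pattern-to-pattern
# permutation association, Tucker congruence matching of components
# across refits, split-half consistency, and gene-selection homogeneity.

#' Tucker congruence coefficient
#'
#' Cosine similarity `u'v / (|u||v|)` between two loading vectors, the
#' standard statistic for matching factors across models.
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Scalar in `[-1, 1]`.
#' @export
congruence_coefficient <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("congruence is undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Per-block subject scores under a fitted model
#'
#' Projects each subject's observed data in the named block onto that
#' block's loading structure by least squares, giving block-specific
#' subject scores: for the tensor block the design is the Khatri-Rao
#' structure of the time and biomarker loadings; for the matrix blocks it
#' is the (scale-weighted) loading matrix.  Subjects with no observed
#' entries in the block get NA scores.
#'
#' @param model A fitted (preferably aligned) `cmtf_model`.
#' @param dataset The [multiblock_dataset] to score.
#' @param block One of `"tensor"`, `"baseline"`, `"gene"`.
#' @return subjects x rank matrix of scores.
#' @export
block_scores <- function(model, dataset, block = "tensor") {
  stopifnot(inherits(model, "cmtf_model"))
  R <- model$rank
  pi <- pair_index(R)
  if (block == "tensor") {
    X <- dataset$tensor; mask <- dataset$tensor_mask
    Z <- khatri_rao(model$time_loadings, model$biomarker_loadings)
    Xz <- X; Xz[!mask] <- 0
    G <- unfold3(mask * 1, 1) %*% pair_products(Z, pi)
    S <- solve_rows(G, unfold3(Xz, 1) %*% Z, pi)
    none <- !apply(mask, 1, any)
  } else {
    Xm <- switch(block, baseline = dataset$baseline, gene = dataset$gene,
                 stop("unknown block: ", block))
    Mm <- switch(block, baseline = dataset$baseline_mask, gene = dataset$gene_mask)
    L <- switch(block, baseline = model$baseline_loadings,
                gene = model$gene_loadings)
    if (is.null(L)) stop("model has no loadings for block ", block)
    sc <- switch(block, baseline = model$baseline_scale, gene = model$gene_scale)
    if (!is.null(sc)) L <- sweep(L, 2, sc, "*")
    Xz <- Xm; Xz[!Mm] <- 0
    G <- (Mm * 1) %*% pair_products(L, pi)
    S <- solve_rows(G, Xz %*% L, pi)
    none <- !apply(Mm, 1, any)
  }
  # components with all-zero loadings carry no information: zero scores
  dead <- colSums(abs(switch(block,
    tensor = model$biomarker_loadings,
    baseline = model$baseline_loadings,
    gene = model$gene_loadings))) == 0
  S[, dead] <- 0
  if (any(none)) S[none, ] <- NA_real_
  rownames(S) <- dataset$labels$subjects
  S
}

# Least-squares re-estimate of one block's loadings given the model's
# subject scores; the scoring operator used inside the permutation test.
refit_block_loadings <- function(A, dataset, block, pi, model = NULL) {
  if (block == "tensor") {
    X <- dataset$tensor; mask <- dataset$tensor_mask
    Xz <- X; Xz[!mask] <- 0
    # one alternating pass from the model's loadings
    B <- model$biomarker_loadings; C <- model$time_loadings
    Z2 <- khatri_rao(C, A)
    B <- solve_rows(unfold3(mask * 1, 2) %*% pair_products(Z2, pi),
                    unfold3(Xz, 2) %*% Z2, pi)
    Z3 <- khatri_rao(B, A)
    C <- solve_rows(unfold3(mask * 1, 3) %*% pair_products(Z3, pi),
                    unfold3(Xz, 3) %*% Z3, pi)
    list(biomarker = B, time = C)
  } else {
    Xm <- switch(block, baseline = dataset$baseline, gene = dataset$gene)
    Mm <- switch(block, baseline = dataset$baseline_mask, gene = dataset$gene_mask)
    Xz <- Xm; Xz[!Mm] <- 0
    L <- solve_rows(t(Mm * 1) %*% pair_products(A, pi), t(Xz) %*% A, pi)
    list(loadings = L)
  }
}

score_block_rows <- function(Xm, Mm, L, pi) {
  Xz <- Xm; Xz[!Mm] <- 0
  S <- solve_rows((Mm * 1) %*% pair_products(L, pi), Xz %*% L, pi)
  S[!apply(Mm, 1, any), ] <- NA_real_
  S
}

score_tensor_rows <- function(X, mask, B, C, pi) {
  Xz <- X; Xz[!mask] <- 0
  Z <- khatri_rao(C, B)
  S <- solve_rows(unfold3(mask * 1, 1) %*% pair_products(Z, pi),
                  unfold3(Xz, 1) %*% Z, pi)
  S[!apply(mask, 1, any), ] <- NA_real_
  S
}

#' Permutation test of pattern-to-pattern association between two blocks
#'
#' Tests whether a component's subject-score pattern in one block is
#' associated with its pattern in another block.  The observed statistic
#' is the absolute Pearson correlation between the two blocks' subject
#' scores for the component.  The null is built by permuting the subject
#' order of the second block's rows.  Under the default
#' `scheme = "refit"` the test conditions on scores derived from the
#' first block alone (for the tensor, a short tensor-only ALS
#' refinement of the joint solution), and the second block's loadings
#' are re-estimated by least squares from those scores for the observed
#' statistic and for every permutation draw alike — so the mechanical
#' alignment of fitted loadings with in-sample noise, which would
#' otherwise make the test strongly anticonservative, is reproduced
#' under the null and the test is exact given the conditioning scores.
#' `scheme = "fixed"` keeps all loadings frozen and is provided for
#' comparison only.  The add-one rule
#' `p = (1 + #{null >= observed}) / (1 + N_perm)` avoids zero p-values.
#'
#' @param dataset A [multiblock_dataset].
#' @param model A fitted aligned `cmtf_model`.
#' @param block_pair Character length-2, e.g. `c("tensor", "baseline")`;
#'   the second block is permuted.
#' @param component Component index.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed.
#' @param scheme `"refit"` (calibrated, default) or `"fixed"`.
#' @return Object of class `permutation_result`: observed statistic, null
#'   vector, p-value, and the test's metadata.
#' @export
permutation_association_test <- function(dataset, model,
                                         block_pair = c("tensor", "baseline"),
                                         component = 1, n_perm = 9999,
                                         seed = 1, scheme = c("refit", "fixed")) {
  stopifnot(length(block_pair) == 2)
  scheme <- match.arg(scheme)
  if (n_perm < 99) stop("n_perm must be at least 99")
  pi <- pair_index(model$rank)
  A <- model$subject_scores
  I <- nrow(A)

  abs_cor <- function(sa, sb) {
    keep <- is.finite(sa) & is.finite(sb)
    if (sum(keep) < 3 || stats::sd(sa[keep]) == 0 ||
        stats::sd(sb[keep]) == 0) return(0)
    abs(stats::cor(sa[keep], sb[keep]))
  }

  if (scheme == "fixed") {
    s1 <- block_scores(model, dataset, block_pair[1])[, component]
    s2all <- block_scores(model, dataset, block_pair[2])[, component]
    ok <- is.finite(s1) & is.finite(s2all)
    if (sum(ok) < 3) stop("fewer than 3 complete subject pairs")
    if (stats::sd(s1[ok]) == 0 || stats::sd(s2all[ok]) == 0) {
      stop("degenerate (constant) score vector; association is undefined")
    }
    s1 <- s1[ok]; s2all <- s2all[ok]
    score2 <- function(perm) s2all[perm]
    n_used <- sum(ok)
  } else {
    # condition on the first block's component scores; everything that
    # depends on the permuted block is recomputed per draw.  For the
    # tensor block the conditioning scores are re-derived from the
    # tensor alone (a short unpenalized ALS refinement started at the
    # joint solution), so they carry no trace of the permuted block and
    # the permutation null is exact given the scores.
    S1 <- if (block_pair[1] == "tensor") {
      ref <- cmtf_engine(dataset$tensor, dataset$tensor_mask,
                         rank = model$rank, lambda = c(0, 0, 0), ridge = 0,
                         init = list(A = model$subject_scores,
                                     B = model$biomarker_loadings,
                                     C = model$time_loadings),
                         tol = 1e-9, max_iter = 100)
      ref$A
    } else {
      block_scores(model, dataset, block_pair[1])
    }
    if (block_pair[2] == "tensor") {
      X2 <- dataset$tensor; M2m <- dataset$tensor_mask
    } else {
      X2 <- switch(block_pair[2], baseline = dataset$baseline,
                   gene = dataset$gene, stop("unknown block: ", block_pair[2]))
      M2m <- switch(block_pair[2], baseline = dataset$baseline_mask,
                    gene = dataset$gene_mask)
    }
    ok <- apply(is.finite(S1), 1, all) & apply(M2m, 1, any)
    if (sum(ok) < 3) stop("fewer than 3 complete subject pairs")
    S1 <- S1[ok, , drop = FALSE]
    s1 <- S1[, component]
    if (stats::sd(s1) == 0) {
      stop("degenerate (constant) score vector; association is undefined")
    }
    score2 <- if (block_pair[2] == "tensor") {
      X2 <- X2[ok, , , drop = FALSE]; M2m <- M2m[ok, , , drop = FALSE]
      function(perm) {
        Xp <- X2[perm, , , drop = FALSE]; Mp <- M2m[perm, , , drop = FALSE]
        L <- refit_block_loadings(S1, list(tensor = Xp, tensor_mask = Mp),
                                  "tensor", pi, model)
        score_tensor_rows(Xp, Mp, L$biomarker, L$time, pi)[, component]
      }
    } else {
      X2 <- X2[ok, , drop = FALSE]; M2m <- M2m[ok, , drop = FALSE]
      function(perm) {
        Xp <- X2[perm, , drop = FALSE]; Mp <- M2m[perm, , drop = FALSE]
        Xz <- Xp; Xz[!Mp] <- 0
        L <- solve_rows(t(Mp * 1) %*% pair_products(S1, pi), t(Xz) %*% S1, pi)
        score_block_rows(Xp, Mp, L, pi)[, component]
      }
    }
    n_used <- sum(ok)
  }

  obs <- abs_cor(s1, score2(seq_len(n_used)))
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      abs_cor(s1, score2(sample.int(n_used)))
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_perm)
  structure(list(
    component = component, block_pair = block_pair,
    statistic = obs, null = null, p_value = p, scheme = scheme,
    n_perm = n_perm, n_subjects = sum(ok), seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Pattern association, component ", x$component, ": ",
      x$block_pair[1], " <-> ", x$block_pair[2],
      "\n  |r| = ", signif(x$statistic, 3),
      ", p = ", signif(x$p_value, 3),
      " (", x$n_perm, " permutations, ", x$n_subjects, " subjects)\n",
      sep = "")
  invisible(x)
}

# Unit-norm concatenation of the non-subject modes of component r, the
# vector on which cross-model matching congruence is computed.
concat_modes <- function(model, r) {
  parts <- list(model$biomarker_loadings[, r], model$time_loadings[, r])
  if (!is.null(model$baseline_loadings)) parts <- c(parts, list(model$baseline_loadings[, r]))
  if (!is.null(model$gene_loadings)) parts <- c(parts, list(model$gene_loadings[, r]))
  parts <- lapply(parts, function(v) {
    n <- sqrt(sum(v^2)); if (n > 0) v / n else v
  })
  unlist(parts)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Match components of two fitted models
#'
#' Resolves the permutation and sign indeterminacy between two fits of
#' equal rank: finds the one-to-one component pairing maximizing the
#' total absolute Tucker congruence of the concatenated (per-mode
#' unit-normalized) non-subject loading vectors, then reports per-mode
#' congruences for each matched pair with signs aligned to the match.
#'
#' @param model1,model2 Fitted `cmtf_model`s of equal rank and matching
#'   non-subject mode dimensions.
#' @return List of class `component_match`: `pairing` (component of
#'   `model2` matched to each component of `model1`), `signs`, `overall`
#'   (matched concatenated |congruence|), `modes` (per-mode congruence
#'   matrix: biomarker, time, and baseline/gene when present), and
#'   `correlations` (the Pearson analogue of `modes`, reported for
#'   reference; congruence drives the matching since loadings are only
#'   approximately mean-free).
#' @export
match_components <- function(model1, model2) {
  stopifnot(inherits(model1, "cmtf_model"), inherits(model2, "cmtf_model"))
  R <- model1$rank
  if (model2$rank != R) stop("models have different ranks")
  if (!model1$aligned) model1 <- align_components(model1)
  if (!model2$aligned) model2 <- align_components(model2)
  v1 <- lapply(seq_len(R), function(r) concat_modes(model1, r))
  v2 <- lapply(seq_len(R), function(r) concat_modes(model2, r))
  if (length(v1[[1]]) != length(v2[[1]])) {
    stop("non-subject mode dimensions differ between models")
  }
  cong <- matrix(0, R, R)
  for (r in seq_len(R)) for (s in seq_len(R)) {
    # a dead (all-zero) component matches nothing
    if (sum(v1[[r]]^2) == 0 || sum(v2[[s]]^2) == 0) next
    cong[r, s] <- congruence_coefficient(v1[[r]], v2[[s]])
  }
  perms <- all_permutations(R)
  tot <- apply(perms, 1, function(p) sum(abs(cong[cbind(seq_len(R), p)])))
  pairing <- unname(perms[which.max(tot), ])
  signs <- sign(cong[cbind(seq_len(R), pairing)])
  signs[signs == 0] <- 1
  mode_names <- c("biomarker", "time",
                  if (!is.null(model1$baseline_loadings)) "baseline",
                  if (!is.null(model1$gene_loadings)) "gene")
  modes <- matrix(NA_real_, R, length(mode_names),
                  dimnames = list(paste0("comp", seq_len(R)), mode_names))
  get_mode <- function(m, what, r) {
    switch(what, biomarker = m$biomarker_loadings[, r],
           time = m$time_loadings[, r],
           baseline = m$baseline_loadings[, r],
           gene = m$gene_loadings[, r])
  }
  safe_cong <- function(u, v) {
    if (sum(u^2) == 0 || sum(v^2) == 0) return(NA_real_)
    congruence_coefficient(u, v)
  }
  correlations <- modes
  for (r in seq_len(R)) for (w in seq_along(mode_names)) {
    u <- get_mode(model1, mode_names[w], r)
    v <- get_mode(model2, mode_names[w], pairing[r])
    modes[r, w] <- signs[r] * safe_cong(u, v)
    correlations[r, w] <- if (stats::sd(u) == 0 || stats::sd(v) == 0) NA_real_
                          else signs[r] * stats::cor(u, v)
  }
  structure(list(
    pairing = pairing, signs = signs,
    overall = abs(cong[cbind(seq_len(R), pairing)]),
    modes = modes, correlations = correlations, congruence_matrix = cong
  ), class = "component_match")
}

#' @export
print.component_match <- function(x, ...) {
  cat("Component matching: pairing ", paste(x$pairing, collapse = ", "),
      "; overall |congruence| ", paste(signif(x$overall, 3), collapse = ", "),
      "\n", sep = "")
  print(round(x$modes, 3))
  invisible(x)
}

# Re-standardize and re-weight a subset of subjects for an independent fit.
subset_dataset <- function(dataset, idx) {
  tensor <- dataset$tensor[idx, , , drop = FALSE]
  dimnames(tensor)[[1]] <- dataset$labels$subjects[idx]
  raw <- multiblock_dataset(tensor,
                            dataset$baseline[idx, , drop = FALSE],
                            dataset$gene[idx, , drop = FALSE],
                            labels = within_labels(dataset$labels, idx))
  suppressWarnings(preprocess(raw))
}

within_labels <- function(labels, idx) {
  labels$subjects <- labels$subjects[idx]
  labels
}

# Column-wise subject permutation of every variable in every block:
# destroys the latent structure while preserving marginals, the null for
# split-half consistency.
scramble_dataset <- function(dataset) {
  ds <- dataset
  d <- dim(ds$tensor)
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    ds$tensor[, j, k] <- ds$tensor[sample.int(d[1]), j, k]
  }
  for (m in seq_len(ncol(ds$baseline))) {
    ds$baseline[, m] <- ds$baseline[sample.int(d[1]), m]
  }
  for (p in seq_len(ncol(ds$gene))) {
    ds$gene[, p] <- ds$gene[sample.int(d[1]), p]
  }
  ds$tensor_mask <- !is.na(ds$tensor)
  ds$baseline_mask <- !is.na(ds$baseline)
  ds$gene_mask <- !is.na(ds$gene)
  # a scramble may leave a subject slice empty; redraw is the caller's job
  ds
}

#' Split-half consistency of the fitted patterns
#'
#' Randomly splits the subjects into two disjoint halves, refits the full
#' pipeline (re-standardization, re-weighting, sparse CMTF, alignment)
#' independently on each half, matches components across the halves, and
#' reports the matched per-mode congruences.  Consistency p-values for
#' the biomarker and baseline modes compare the observed matched
#' congruence against a null of congruences obtained by refitting one
#' half after independently permuting every variable column across
#' subjects (destroying the latent structure) and re-matching.  The gene
#' mode is summarized by the homogeneity of the two halves' selected SNP
#' sets ([gene_selection_homogeneity()]).  Repeated `n_splits` times and
#' aggregated.
#'
#' @param dataset A raw or standardized [multiblock_dataset] (halves are
#'   always re-standardized from the stored values).
#' @param rank,lambda,n_starts,max_iter,tol Passed to [cmtf_fit()].
#' @param n_splits Number of random splits (default 20).
#' @param n_null Null refits per split (default 19).
#' @param seed Integer seed.
#' @return Object of class `split_half_result`: per-split matched
#'   congruences (`splits`), per-split p-values (`p_values`), the last
#'   split's two half-models, and medians/worst cases (`summary`).
#' @export
split_half_consistency <- function(dataset, rank = 2, lambda = 0.01,
                                   n_splits = 20, n_null = 19, seed = 1,
                                   n_starts = 3, max_iter = 200, tol = 1e-7) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  I <- dim(dataset$tensor)[1]
  if (I < 8) stop("need at least 8 subjects for a split-half analysis")
  with_seed(seed, {
    splits <- vector("list", n_splits)
    pvals <- vector("list", n_splits)
    halves <- NULL
    for (s in seq_len(n_splits)) {
      idx <- sample.int(I)
      h1 <- sort(idx[seq_len(ceiling(I / 2))])
      h2 <- sort(idx[(ceiling(I / 2) + 1L):I])
      ds1 <- subset_dataset(dataset, h1)
      ds2 <- subset_dataset(dataset, h2)
      seed_s <- (seed * 1000L + s) %% .Machine$integer.max
      fit_half <- function(ds, sd) {
        align_components(cmtf_fit(ds, rank = rank, lambda = lambda,
                                  n_starts = n_starts, max_iter = max_iter,
                                  tol = tol, seed = sd))
      }
      m1 <- expand_model_to_labels(fit_half(ds1, seed_s), dataset$labels)
      m2 <- expand_model_to_labels(fit_half(ds2, seed_s + 1L), dataset$labels)
      mt <- match_components(m1, m2)
      null_bio <- matrix(NA_real_, max(n_null, 1), rank)
      null_base <- matrix(NA_real_, max(n_null, 1), rank)
      for (b in seq_len(n_null)) {
        ds2n <- scramble_dataset(ds2)
        if (!all(apply(ds2n$tensor_mask, 1, any))) next
        ds2n <- suppressWarnings(weight_blocks(ds2n))
        m2n <- expand_model_to_labels(
          fit_half_null(ds2n, rank, lambda, n_starts, max_iter, tol,
                        seed_s + 1L + b), dataset$labels)
        mtn <- match_components(m1, m2n)
        null_bio[b, ] <- abs(mtn$modes[, "biomarker"])
        null_base[b, ] <- abs(mtn$modes[, "baseline"])
      }
      p_mode <- function(null, obs_v) {
        vapply(seq_len(rank), function(r) {
          if (!is.finite(obs_v[r])) return(NA_real_)
          nn <- null[is.finite(null[, r]), r]
          if (!length(nn)) return(NA_real_)
          (1 + sum(nn >= abs(obs_v[r]))) / (1 + length(nn))
        }, numeric(1))
      }
      sel1 <- selected_genes(m1); sel2 <- selected_genes_matched(m2, mt$pairing)
      hom <- mapply(function(a, b) {
        gene_selection_homogeneity(a, b, dataset$labels$snps)$p_value
      }, sel1, sel2)
      splits[[s]] <- abs(mt$modes)
      pvals[[s]] <- list(
        biomarker = p_mode(null_bio, mt$modes[, "biomarker"]),
        baseline = p_mode(null_base, mt$modes[, "baseline"]),
        gene_homogeneity = hom
      )
      halves <- list(model1 = m1, model2 = m2, match = mt)
    }
    agg <- function(mode) {
      vals <- vapply(splits, function(m) m[, mode], numeric(rank))
      matrix(vals, nrow = rank)
    }
    bio <- agg("biomarker"); base <- agg("baseline")
    summary <- list(
      median_congruence = c(
        biomarker = stats::median(bio, na.rm = TRUE),
        baseline = stats::median(base, na.rm = TRUE),
        time = stats::median(vapply(splits, function(m) m[, "time"], numeric(rank)),
                             na.rm = TRUE),
        gene = stats::median(vapply(splits, function(m) m[, "gene"], numeric(rank)),
                             na.rm = TRUE)
      ),
      worst_p = c(
        biomarker = suppressWarnings(
          max(vapply(pvals, function(p) max(c(p$biomarker, -Inf), na.rm = TRUE),
                     numeric(1)))),
        baseline = suppressWarnings(
          max(vapply(pvals, function(p) max(c(p$baseline, -Inf), na.rm = TRUE),
                     numeric(1))))
      )
    )
    structure(list(
      splits = splits, p_values = pvals, summary = summary,
      last_halves = halves, rank = rank, n_splits = n_splits,
      n_null = n_null, seed = seed
    ), class = "split_half_result")
  })
}

fit_half_null <- function(ds, rank, lambda, n_starts, max_iter, tol, sd) {
  align_components(cmtf_fit(ds, rank = rank, lambda = lambda,
                            n_starts = n_starts, max_iter = max_iter,
                            tol = tol, seed = sd))
}

# Re-express a model fitted after column drops (constant columns removed
# during per-half standardization) on the full variable universe, with
# zero loadings for the dropped columns, so models remain comparable.
expand_model_to_labels <- function(model, full_labels) {
  expand <- function(L, have, want) {
    if (is.null(L)) return(NULL)
    out <- matrix(0, length(want), ncol(L))
    out[match(have, want), ] <- L
    out
  }
  lb <- model$labels
  model$biomarker_loadings <- expand(model$biomarker_loadings,
                                     lb$biomarkers, full_labels$biomarkers)
  model$baseline_loadings <- expand(model$baseline_loadings,
                                    lb$baseline_vars, full_labels$baseline_vars)
  model$gene_loadings <- expand(model$gene_loadings, lb$snps, full_labels$snps)
  model$labels$biomarkers <- full_labels$biomarkers
  model$labels$baseline_vars <- full_labels$baseline_vars
  model$labels$snps <- full_labels$snps
  model
}

selected_genes <- function(model) {
  lapply(seq_len(model$rank), function(r) {
    model$labels$snps[model$gene_loadings[, r] != 0]
  })
}

selected_genes_matched <- function(model, pairing) {
  sel <- selected_genes(model)
  sel[pairing]
}

#' @export
print.split_half_result <- function(x, ...) {
  cat("Split-half consistency over ", x$n_splits, " splits (rank ",
      x$rank, ")\n", sep = "")
  cat("  median matched |congruence|: ",
      paste(names(x$summary$median_congruence), "=",
            signif(x$summary$median_congruence, 3), collapse = ", "), "\n",
      "  worst-case consistency p: ",
      paste(names(x$summary$worst_p), "=",
            signif(x$summary$worst_p, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Homogeneity of two selected gene sets
#'
#' Tests whether two analyses selected SNPs consistently: the universe is
#' cross-classified by selection in each analysis and the 2x2 table is
#' tested by Fisher's exact conditional test.  Degenerate tables (a
#' selection that is empty or exhausts the universe) carry no information
#' and return p = 1 by convention.
#'
#' @param selected1,selected2 Character vectors of selected SNP names.
#' @param universe All candidate SNP names (non-empty).
#' @return List with `statistic` (odds ratio estimate), `p_value`, and
#'   the 2x2 `table`.
#' @export
gene_selection_homogeneity <- function(selected1, selected2, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  if (!all(selected1 %in% universe) || !all(selected2 %in% universe)) {
    stop("selections must be subsets of the universe")
  }
  in1 <- universe %in% selected1
  in2 <- universe %in% selected2
  tab <- table(factor(in1, c(TRUE, FALSE)), factor(in2, c(TRUE, FALSE)),
               dnn = c("selected1", "selected2"))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = NA_real_, p_value = 1, table = tab))
  }
  ft <- stats::fisher.test(tab, alternative = "greater")
  list(statistic = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
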