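#' Generate a coupled three-block synthetic cohort
#'
#' Emulates the structure of a remission-phase cohort: a longitudinal
#' biomarker tensor (subjects x biomarkers x visit months), a baseline
#' clinical matrix and a SNP genotype matrix, all driven by a shared
#' rank-`rank` latent subject structure with sparse variable-mode
#' loadings and Gaussian residual noise.  The planted factors are
#' returned alongside the data so recovery can be scored exactly.
#'
#' Subject scores are i.i.d. standard normal.  Non-subject loadings are
#' drawn normal, a stated fraction of entries per sparse mode is set to
#' exactly zero, and columns are renormalized to unit Euclidean norm (the
#' time mode stays dense).  The tensor is the CP reconstruction plus
#' noise, thinned completely at random subject to every subject keeping
#' at least one observed entry (mask redrawn up to 100 times, then an
#' error).  The baseline block is `scores %*% t(loadings)` plus noise.
#' The gene block is built the same way from a latent Gaussian matrix and
#' then discretized per SNP at its tertiles into genotype counts 0/1/2,
#' preserving a monotone association with the latent score while
#' producing legal genotypes; set `discretize_genes = FALSE` to keep the
#' continuous latent block.
#'
#' @param dims Named list/vector: `subjects`, `biomarkers`, `timepoints`,
#'   `baseline_vars`, `snps`.  Defaults are the cohort scale of the study
#'   design being emulated: 129, 20, 4, 10, 51.
#' @param rank Number of latent components (default 2).
#' @param sparsity Fraction of exact-zero loadings per sparse mode, named
#'   `biomarker`, `baseline`, `gene` (defaults 0.25, 0.30, 0.70).
#' @param noise_sd Residual standard deviation per block (tensor,
#'   baseline, gene latent), default `c(0.3, 0.3, 0.3)`.
#' @param missing_rate Fraction of tensor entries deleted completely at
#'   random, in `[0, 1)`; default 0.1.
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param discretize_genes Discretize the gene block to 0/1/2 (default TRUE).
#' @return List of class `cmtf_cohort` with elements `dataset` (a raw,
#'   unstandardized [multiblock_dataset]) and `truth` (class
#'   `cmtf_ground_truth`: the generating factor matrices, noise and
#'   missingness parameters, the latent gene block, and the seed).
#' @examples
#' cohort <- generate_cohort(dims = list(subjects = 30, biomarkers = 8,
#'   timepoints = 4, baseline_vars = 5, snps = 12), seed = 1)
#' dim(cohort$dataset$tensor)
#' @export
generate_cohort <- function(dims = list(subjects = 129, biomarkers = 20,
                                        timepoints = 4, baseline_vars = 10,
                                        snps = 51),
                            rank = 2,
                            sparsity = c(biomarker = 0.25, baseline = 0.30,
                                         gene = 0.70),
                            noise_sd = c(0.3, 0.3, 0.3),
                            missing_rate = 0.1,
                            seed = 1,
                            discretize_genes = TRUE) {
  dims <- as.list(dims)
  need <- c("subjects", "biomarkers", "timepoints", "baseline_vars", "snps")
  if (!all(need %in% names(dims))) {
    stop("dims must name ", paste(need, collapse = ", "))
  }
  I <- dims$subjects; J <- dims$biomarkers; K <- dims$timepoints
  M <- dims$baseline_vars; P <- dims$snps
  if (rank < 1) stop("rank must be >= 1")
  if (any(c(I, J, K, M, P) < rank)) stop("every dimension must be >= rank")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  noise_sd <- rep_len(noise_sd, 3)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  sp <- c(biomarker = 0.25, baseline = 0.30, gene = 0.70)
  sp[names(sparsity)] <- sparsity
  if (any(sp < 0 | sp >= 1)) stop("sparsity fractions must be in [0, 1)")

  with_seed(seed, {
    A <- matrix(stats::rnorm(I * rank), I, rank)
    B <- sparse_loadings(J, rank, sp[["biomarker"]])
    C <- dense_loadings(K, rank)
    D <- sparse_loadings(M, rank, sp[["baseline"]])
    E <- sparse_loadings(P, rank, sp[["gene"]])

    tensor <- recon_tensor(A, B, C)
    if (noise_sd[1] > 0) tensor <- tensor + array(stats::rnorm(I * J * K, sd = noise_sd[1]), dim(tensor))
    mask <- draw_mask(I, J, K, missing_rate)
    tensor[!mask] <- NA_real_

    baseline <- A %*% t(D)
    if (noise_sd[2] > 0) baseline <- baseline + matrix(stats::rnorm(I * M, sd = noise_sd[2]), I, M)

    gene_latent <- A %*% t(E)
    if (noise_sd[3] > 0) gene_latent <- gene_latent + matrix(stats::rnorm(I * P, sd = noise_sd[3]), I, P)
    gene <- if (discretize_genes) discretize_tertiles(gene_latent) else gene_latent

    labels <- list(
      subjects = sprintf("S%03d", seq_len(I)),
      biomarkers = sprintf("bm%02d", seq_len(J)),
      times = if (K == 4) c(1, 3, 6, 12) else seq_len(K),
      baseline_vars = sprintf("base%02d", seq_len(M)),
      snps = sprintf("snp%02d", seq_len(P))
    )
    dimnames(tensor) <- list(labels$subjects, labels$biomarkers, labels$times)
    dimnames(baseline) <- list(labels$subjects, labels$baseline_vars)
    dimnames(gene) <- list(labels$subjects, labels$snps)

    dataset <- multiblock_dataset(tensor, baseline, gene, labels = labels)
    truth <- structure(list(
      subject_scores = A, biomarker_loadings = B, time_loadings = C,
      baseline_loadings = D, gene_loadings = E,
      gene_latent = gene_latent,
      noise_sd_per_block = noise_sd, missing_rate = missing_rate,
      sparsity = sp, rank = rank, seed = seed
    ), class = "cmtf_ground_truth")
    structure(list(dataset = dataset, truth = truth), class = "cmtf_cohort")
  })
}

# Normal loadings with an exact fraction of zeros per column, columns
# renormalized to unit Euclidean norm.  At least `rank` entries stay
# nonzero so no component dies at birth.
sparse_loadings <- function(n, rank, frac_zero) {
  L <- matrix(stats::rnorm(n * rank), n, rank)
  nzero <- min(floor(frac_zero * n), n - 1L)
  if (nzero > 0) {
    for (r in seq_len(rank)) {
      L[sample.int(n, nzero), r] <- 0
    }
  }
  sweep(L, 2, sqrt(colSums(L^2)), "/")
}

dense_loadings <- function(n, rank) {
  L <- matrix(stats::rnorm(n * rank), n, rank)
  sweep(L, 2, sqrt(colSums(L^2)), "/")
}

# Entry-level MCAR mask with rejection resampling so every subject keeps
# at least one observed tensor entry.
draw_mask <- function(I, J, K, missing_rate, max_tries = 100) {
  if (missing_rate == 0) return(array(TRUE, c(I, J, K)))
  for (try in seq_len(max_tries)) {
    mask <- array(stats::runif(I * J * K) >= missing_rate, c(I, J, K))
    per_subject <- apply(mask, 1, any)
    if (all(per_subject)) return(mask)
  }
  stop("could not draw a mask keeping >= 1 observation per subject in ",
       max_tries, " tries; lower missing_rate")
}

# Per-column tertile cut of a latent Gaussian matrix into counts 0/1/2.
# Constant columns (zero latent signal and zero noise) collapse to the
# heterozygote count 1.
discretize_tertiles <- function(Z) {
  G <- Z
  for (j in seq_len(ncol(Z))) {
    q <- stats::quantile(Z[, j], probs = c(1 / 3, 2 / 3), names = FALSE)
    if (q[1] == q[2]) {
      G[, j] <- 1
    } else {
      G[, j] <- findInterval(Z[, j], q, left.open = TRUE)
    }
  }
  G
}

#' Generate a cohort with a named, interpretable planted component
#'
#' Builds a coupled cohort whose first component is the canonical
#' remission-phase pattern: C-peptide-like and proinsulin-like markers
#' (`cpep`, `proins`) declining while glucose-like and insulin-dose-like
#' markers (`gluc`, `dose`) rise over the visit grid, an age-linked
#' baseline variable (`age`) loading with the C-peptide sign, and five
#' risk SNPs (`rs01`-`rs05`) carrying the genetic signal.  A clearly
#' weaker second component lives on other markers and SNPs.  Returns the
#' three blocks as CSV-ready tables plus the planted structure, for
#' end-to-end pipeline demonstrations and recovery checks.
#'
#' @param subjects Number of subjects (default 129).
#' @param seed Integer seed.
#' @param noise_sd Residual standard deviation for all blocks
#'   (default 0.3).
#' @param missing_rate Tensor missingness (default 0.05).
#' @return List with `long` (biomarker long table), `baseline`,
#'   `genotypes` (wide tables with `subject_id`), `cohort` (the
#'   underlying `cmtf_cohort`), `risk_snps`, and `planted` (the named
#'   loading vectors).
#' @export
generate_planted_cohort <- function(subjects = 129, seed = 1,
                                    noise_sd = 0.3, missing_rate = 0.05) {
  biomarkers <- c("cpep", "proins", "gluc", "dose", sprintf("bm%02d", 5:10))
  snps <- sprintf("rs%02d", 1:20)
  base_vars <- c("age", sprintf("base%02d", 2:5))
  unit <- function(v) v / sqrt(sum(v^2))
  # component 1 (dominant): residual beta-cell function declining while
  # glucose and insulin need rise; the wider biomarker footprint keeps
  # it the strongest component in standardized coordinates
  B <- cbind(unit(c(-0.6, -0.45, 0.45, 0.4, rep(0, 6))),
             unit(c(0, 0, 0, 0, 0.6, -0.5, 0.45, rep(0, 3))))
  C <- cbind(unit(c(0.25, 0.45, 0.7, 0.9)),
             unit(c(0.6, 0.55, 0.45, 0.35)))
  D <- cbind(unit(c(-0.8, 0.4, 0, 0, 0)),
             unit(c(0, 0, 0.7, -0.5, 0)))
  E <- cbind(unit(c(rep(0.45, 5), rep(0, 15))),
             unit(c(rep(0, 10), 0.5, -0.5, 0.45, rep(0, 7))))
  with_seed(seed, {
    A <- cbind(stats::rnorm(subjects), 0.55 * stats::rnorm(subjects))
    tensor <- recon_tensor(A, B, C) +
      array(stats::rnorm(subjects * 10 * 4, sd = noise_sd), c(subjects, 10, 4))
    mask <- draw_mask(subjects, 10, 4, missing_rate)
    tensor[!mask] <- NA_real_
    baseline <- A %*% t(D) +
      matrix(stats::rnorm(subjects * 5, sd = noise_sd), subjects, 5)
    gene_latent <- A %*% t(E) +
      matrix(stats::rnorm(subjects * 20, sd = noise_sd), subjects, 20)
    gene <- discretize_tertiles(gene_latent)
    labels <- list(subjects = sprintf("S%03d", seq_len(subjects)),
                   biomarkers = biomarkers, times = c(1, 3, 6, 12),
                   baseline_vars = base_vars, snps = snps)
    dimnames(tensor) <- list(labels$subjects, biomarkers, labels$times)
    dimnames(baseline) <- list(labels$subjects, base_vars)
    dimnames(gene) <- list(labels$subjects, snps)
    dataset <- multiblock_dataset(tensor, baseline, gene, labels = labels)
    truth <- structure(list(
      subject_scores = A, biomarker_loadings = B, time_loadings = C,
      baseline_loadings = D, gene_loadings = E, gene_latent = gene_latent,
      noise_sd_per_block = rep(noise_sd, 3), missing_rate = missing_rate,
      sparsity = c(biomarker = NA, baseline = NA, gene = NA),
      rank = 2L, seed = seed
    ), class = "cmtf_ground_truth")
    cohort <- structure(list(dataset = dataset, truth = truth),
                        class = "cmtf_cohort")
    list(
      long = flatten_tensor(tensor, dataset$tensor_mask, labels),
      baseline = cbind(subject_id = labels$subjects,
                       as.data.frame(baseline), stringsAsFactors = FALSE),
      genotypes = cbind(subject_id = labels$subjects,
                        as.data.frame(gene), stringsAsFactors = FALSE),
      cohort = cohort,
      risk_snps = snps[1:5],
      planted = list(biomarker = stats::setNames(B[, 1], biomarkers),
                     time = stats::setNames(C[, 1], labels$times),
                     baseline = stats::setNames(D[, 1], base_vars),
                     gene = stats::setNames(E[, 1], snps))
    )
  })
}

#' Ground-truth loadings on the standardized scale
#'
#' The factorization is fitted to column-standardized blocks, so the
#' planted loadings must be expressed in the same coordinates before
#' recovery can be scored: each variable's loading is divided by the
#' column scale actually applied during standardization, and genotype
#' columns are additionally multiplied by their empirical
#' discretization attenuation (the regression of the genotype on its
#' generating latent column).  Tensor-mode scales, which act jointly on
#' (variable, time) columns, are separated by a rank-1 approximation of
#' the column-scale matrix.  Columns are renormalized to unit norm;
#' subject scores are centered (standardization centers each column).
#'
#' @param cohort A `cmtf_cohort` from [generate_cohort()].
#' @return List with `subject_scores`, `biomarker_loadings`,
#'   `time_loadings`, `baseline_loadings`, `gene_loadings` on the
#'   standardized scale.
#' @export
standardized_truth <- function(cohort) {
  stopifnot(inherits(cohort, "cmtf_cohort"))
  tr <- cohort$truth
  ds <- cohort$dataset
  unit <- function(M) {
    n <- sqrt(colSums(M^2))
    n[n == 0] <- 1
    sweep(M, 2, n, "/")
  }
  # tensor: per (variable, time) column sd, separated as s_jk ~ u_j v_k
  d <- dim(ds$tensor)
  S <- matrix(1, d[2], d[3])
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    col <- ds$tensor[, j, k]
    s <- stats::sd(col[!is.na(col)])
    if (is.finite(s) && s > 0) S[j, k] <- s
  }
  sv <- svd(S, nu = 1, nv = 1)
  u <- abs(sv$u[, 1]) * sqrt(sv$d[1]); v <- abs(sv$v[, 1]) * sqrt(sv$d[1])
  B <- unit(tr$biomarker_loadings / u)
  C <- unit(tr$time_loadings / v)
  # baseline: divide by the column sd
  sb <- apply(ds$baseline, 2, function(x) stats::sd(x[!is.na(x)]))
  sb[!is.finite(sb) | sb == 0] <- 1
  D <- unit(tr$baseline_loadings / sb)
  # gene: discretization attenuation x column sd
  kap <- vapply(seq_len(ncol(ds$gene)), function(p) {
    g <- ds$gene[, p]; l <- tr$gene_latent[, p]
    ok <- !is.na(g)
    vl <- stats::var(l[ok]); sg <- stats::sd(g[ok])
    if (!is.finite(vl) || vl == 0 || !is.finite(sg) || sg == 0) return(0)
    stats::cov(g[ok], l[ok]) / (vl * sg)
  }, numeric(1))
  E <- unit(tr$gene_loadings * kap)
  A <- scale(tr$subject_scores, center = TRUE, scale = FALSE)
  list(subject_scores = A, biomarker_loadings = B, time_loadings = C,
       baseline_loadings = D, gene_loadings = E)
}

#' The planted structure as a canonically aligned model object
#'
#' Wraps [standardized_truth()] in a `cmtf_model` and passes it through
#' [align_components()], so the truth obeys the same sign and ordering
#' conventions as any fitted model.  Canonicalizing both sides is
#' essential before cross-model matching: the generator's loading signs
#' are arbitrary, and a valid CP representation may differ from another
#' by coordinated per-mode sign flips that would otherwise cancel in
#' concatenated congruences.
#'
#' @param cohort A `cmtf_cohort`.
#' @return An aligned `cmtf_model` holding the planted factors.
#' @export
truth_as_model <- function(cohort) {
  stopifnot(inherits(cohort, "cmtf_cohort"))
  tt <- standardized_truth(cohort)
  R <- cohort$truth$rank
  tm <- structure(list(
    subject_scores = tt$subject_scores,
    biomarker_loadings = tt$biomarker_loadings,
    time_loadings = tt$time_loadings,
    baseline_loadings = tt$baseline_loadings,
    gene_loadings = tt$gene_loadings,
    baseline_scale = rep(1, R),
    gene_scale = rep(1, R),
    rank = R, aligned = FALSE,
    labels = cohort$dataset$labels
  ), class = "cmtf_model")
  align_components(tm)
}

#' Score factor recovery of a fitted model against the planted truth
#'
#' Matches the aligned model's components one-to-one to the planted
#' components (maximizing total absolute congruence of concatenated
#' modes, both sides canonicalized via [truth_as_model()]) and returns
#' the per-mode absolute Tucker congruences.
#'
#' @param model A fitted `cmtf_model` on the cohort's preprocessed data.
#' @param cohort The generating `cmtf_cohort`.
#' @return Matrix components x modes (subject, biomarker, time,
#'   baseline, gene) of absolute congruences.
#' @export
recovery_congruence <- function(model, cohort) {
  if (!model$aligned) model <- align_components(model)
  tm <- truth_as_model(cohort)
  # the fitted model may have dropped constant columns; re-expand
  model <- expand_model_to_labels(model, cohort$dataset$labels)
  mt <- match_components(model, tm)
  pairing <- mt$pairing
  cong <- function(u, v) {
    nu <- sum(u^2); nv <- sum(v^2)
    if (nu == 0 || nv == 0) return(NA_real_)
    abs(sum(u * v)) / sqrt(nu * nv)
  }
  out <- t(vapply(seq_len(model$rank), function(r) {
    s <- pairing[r]
    c(subject = cong(model$subject_scores[, r], tm$subject_scores[, s]),
      biomarker = cong(model$biomarker_loadings[, r], tm$biomarker_loadings[, s]),
      time = cong(model$time_loadings[, r], tm$time_loadings[, s]),
      baseline = cong(model$baseline_loadings[, r], tm$baseline_loadings[, s]),
      gene = cong(model$gene_loadings[, r], tm$gene_loadings[, s]))
  }, numeric(5)))
  rownames(out) <- paste0("comp", seq_len(model$rank))
  out
}

#' @export
print.cmtf_cohort <- function(x, ...) {
  d <- dim(x$dataset$tensor)
  cat("Synthetic coupled cohort: ", d[1], " subjects, ",
      d[2], " biomarkers x ", d[3], " visits, ",
      ncol(x$dataset$baseline), " baseline vars, ",
      ncol(x$dataset$gene), " SNPs; rank ", x$truth$rank,
      ", seed ", x$truth$seed, "\n", sep = "")
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes the three blocks of a cohort as plain-text tables: the tensor in
#' long format (`subject_id`, `variable`, `time_months`, `value`; masked
#' entries omitted), the baseline and genotype blocks wide, and the ground
#' truth as a YAML sidecar of factor matrices and generator parameters.
#'
#' @param cohort A `cmtf_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cmtf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- cohort$dataset
  long <- flatten_tensor(ds$tensor, ds$tensor_mask, ds$labels)
  paths <- c(
    biomarkers = file.path(dir, "biomarkers_long.csv"),
    baseline = file.path(dir, "baseline.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    truth = file.path(dir, "ground_truth.yaml")
  )
  utils::write.csv(long, paths[["biomarkers"]], row.names = FALSE)
  utils::write.csv(cbind(subject_id = ds$labels$subjects,
                         as.data.frame(ds$baseline)),
                   paths[["baseline"]], row.names = FALSE)
  utils::write.csv(cbind(subject_id = ds$labels$subjects,
                         as.data.frame(ds$gene)),
                   paths[["genotypes"]], row.names = FALSE)
  tr <- cohort$truth
  yaml::write_yaml(list(
    rank = tr$rank, seed = tr$seed,
    noise_sd_per_block = as.numeric(tr$noise_sd_per_block),
    missing_rate = tr$missing_rate,
    sparsity = as.list(tr$sparsity),
    subject_scores = as.list(as.data.frame(tr$subject_scores)),
    biomarker_loadings = as.list(as.data.frame(tr$biomarker_loadings)),
    time_loadings = as.list(as.data.frame(tr$time_loadings)),
    baseline_loadings = as.list(as.data.frame(tr$baseline_loadings)),
    gene_loadings = as.list(as.data.frame(tr$gene_loadings))
  ), paths[["truth"]])
  invisible(paths)
}

# Long-format view of the observed tensor entries (assemble_tensor's inverse).
flatten_tensor <- function(tensor, mask, labels) {
  idx <- which(mask, arr.ind = TRUE)
  data.frame(
    subject_id = labels$subjects[idx[, 1]],
    variable = labels$biomarkers[idx[, 2]],
    time_months = labels$times[idx[, 3]],
    value = tensor[mask],
    stringsAsFactors = FALSE
  )
}
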