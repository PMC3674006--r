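# End-to-end orchestration: read tables -> derive clinical codings ->
# assemble and standardize blocks -> fit the sparse coupled model ->
# validate -> write pattern tables and reports.

#' Stability-based selection of the sparsity penalty
#'
#' Fits the model on random split halves for every candidate penalty and
#' scores each candidate by the mean matched absolute congruence of the
#' concatenated loading patterns across halves.  Among candidates within
#' `tol_band` of the best stability, the largest (sparsest) penalty wins.
#'
#' @param dataset A raw or standardized [multiblock_dataset].
#' @param rank Model rank.
#' @param lambda_grid Candidate penalties (applied to all three sparse
#'   modes, as fractions of each mode's lambda_max); default
#'   `10^seq(-3, log10(0.5), length.out = 7)`, spanning nearly
#'   unpenalized to half the mode-emptying penalty.
#' @param n_rep Split replicates per candidate (default 3).
#' @param seed Integer seed.
#' @param tol_band Stability tolerance for the parsimony tie-break
#'   (default 0.02).
#' @param ... Passed to [cmtf_fit()] (e.g. `n_starts`, `max_iter`).
#' @return List with `lambda` (the selection), `stability` (per
#'   candidate), and `grid`.
#' @export
select_lambda <- function(dataset, rank = 2,
                          lambda_grid = 10^seq(-3, log10(0.5), length.out = 7),
                          n_rep = 3, seed = 1, tol_band = 0.02, ...) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  I <- dim(dataset$tensor)[1]
  stab <- vapply(seq_along(lambda_grid), function(g) {
    lam <- lambda_grid[g]
    reps <- with_seed(seed + g, {
      vapply(seq_len(n_rep), function(rep) {
        idx <- sample.int(I)
        h1 <- sort(idx[seq_len(ceiling(I / 2))])
        h2 <- sort(idx[(ceiling(I / 2) + 1L):I])
        m1 <- expand_model_to_labels(align_components(
          cmtf_fit(subset_dataset(dataset, h1), rank = rank, lambda = lam,
                   seed = seed + g, ...)), dataset$labels)
        m2 <- expand_model_to_labels(align_components(
          cmtf_fit(subset_dataset(dataset, h2), rank = rank, lambda = lam,
                   seed = seed + g + 1L, ...)), dataset$labels)
        mean(match_components(m1, m2)$overall)
      }, numeric(1))
    })
    mean(reps)
  }, numeric(1))
  ok <- which(stab >= max(stab) - tol_band)
  list(lambda = lambda_grid[max(ok)], stability = stab, grid = lambda_grid)
}

#' Read and validate a pipeline run configuration
#'
#' A configuration names the three input tables and the modelling
#' choices.  YAML fields: `biomarkers`, `baseline`, `genotypes` (CSV
#' paths), `rank` (default 2), `lambda` (number, or `"select"` to use
#' [select_lambda()]), `lambda_grid`, `log_vars`, `risk_alleles` (named
#' map for allele-pair genotype tables), `times` (visit grid, default
#' 1,3,6,12), `n_perm`, `n_splits`, `seed`, `out_dir`.  All referenced
#' files must exist; validation happens before any computation.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(rank = 2,
                   lambda = c(biomarker = 0.1, baseline = 0.1, gene = 0.3),
                   log_vars = character(),
                   times = c(1, 3, 6, 12), n_perm = 9999, n_splits = 20,
                   n_null = 19, seed = 1, n_starts = 10,
                   lambda_grid = 10^seq(-3, log10(0.5), length.out = 7),
                   out_dir = "cmtf_run")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (f in c("biomarkers", "baseline", "genotypes")) {
    if (is.null(config[[f]])) stop("config error: missing input path '", f, "'")
    if (!file.exists(config[[f]])) {
      stop("config error: ", f, " file not found: ", config[[f]])
    }
  }
  if (config$rank < 1) stop("config error: rank must be >= 1")
  config
}

# Numeric encoding of a derived baseline table: numerics kept, logicals
# 0/1, characters/factors expanded to dummy indicators (first level as
# reference).  The subject id column is excluded.
numeric_baseline <- function(baseline, id_col = "subject_id") {
  cols <- setdiff(names(baseline), id_col)
  out <- list()
  for (v in cols) {
    x <- baseline[[v]]
    if (is.numeric(x)) {
      out[[v]] <- x
    } else if (is.logical(x)) {
      out[[v]] <- as.numeric(x)
    } else {
      x <- as.factor(x)
      for (lv in levels(x)[-1]) {
        out[[paste0(v, "_", lv)]] <- as.numeric(x == lv)
      }
    }
  }
  as.matrix(as.data.frame(out, check.names = FALSE))
}

#' Run the full multi-block analysis pipeline
#'
#' Executes the analysis end to end, deterministically given the config's
#' seeds: derive clinical features, assemble and standardize the three
#' blocks, fit the rank-`rank` sparse coupled factorization, align the
#' components, run the permutation association tests (tensor vs baseline
#' and tensor vs gene patterns, per component) and the split-half
#' consistency analysis, and write the report tables to `out_dir`:
#' per-component loading patterns (`component_loadings.csv`, zero
#' loadings omitted), explained variation per block
#' (`explained_variation.csv`), permutation results
#' (`permutation_tests.csv`) and the split-half summary
#' (`split_half.csv`).
#'
#' @param config Path to a YAML config or a named list
#'   (see [read_run_config()]).
#' @return Invisibly, a list with the dataset, aligned model, permutation
#'   results, split-half result, and output paths.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)

  long <- utils::read.csv(cfg$biomarkers, stringsAsFactors = FALSE)
  baseline_raw <- utils::read.csv(cfg$baseline, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  geno_raw <- utils::read.csv(cfg$genotypes, stringsAsFactors = FALSE,
                              check.names = FALSE)

  baseline_raw <- derive_baseline_features(baseline_raw)
  bl_mat <- numeric_baseline(baseline_raw)
  id_col <- if ("subject_id" %in% names(baseline_raw)) baseline_raw$subject_id else NULL

  if (!is.null(cfg$risk_alleles)) {
    geno <- encode_genotype_table(geno_raw, unlist(cfg$risk_alleles))
  } else {
    geno <- geno_raw[, setdiff(names(geno_raw), "subject_id"), drop = FALSE]
  }
  geno_mat <- as.matrix(geno)

  asm <- assemble_tensor(long, subjects = id_col, times = cfg$times)
  subjects <- dimnames(asm$tensor)[[1]]
  if (!is.null(id_col)) {
    ord <- match(subjects, id_col)
    if (anyNA(ord)) stop("baseline table lacks subject(s): ",
                         paste(subjects[is.na(ord)], collapse = ", "))
    bl_mat <- bl_mat[ord, , drop = FALSE]
    geno_mat <- geno_mat[ord, , drop = FALSE]
  }
  rownames(bl_mat) <- rownames(geno_mat) <- subjects

  raw <- multiblock_dataset(asm$tensor, bl_mat, geno_mat)
  ds <- preprocess(raw, log_vars = cfg$log_vars)

  lambda <- cfg$lambda
  lambda_info <- NULL
  if (identical(lambda, "select")) {
    lambda_info <- select_lambda(ds, rank = cfg$rank,
                                 lambda_grid = cfg$lambda_grid,
                                 seed = cfg$seed, n_starts = 2, max_iter = 200)
    lambda <- lambda_info$lambda
  }

  model <- align_components(cmtf_fit(ds, rank = cfg$rank, lambda = lambda,
                                     n_starts = cfg$n_starts, seed = cfg$seed))

  perms <- list()
  for (r in seq_len(cfg$rank)) {
    for (pair in list(c("tensor", "baseline"), c("tensor", "gene"))) {
      key <- paste0("comp", r, "_", pair[1], "_", pair[2])
      perms[[key]] <- permutation_association_test(
        ds, model, block_pair = pair, component = r,
        n_perm = cfg$n_perm, seed = cfg$seed + r)
    }
  }

  sh <- split_half_consistency(ds, rank = cfg$rank, lambda = lambda,
                               n_splits = cfg$n_splits, n_null = cfg$n_null,
                               seed = cfg$seed)

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_report(cfg$out_dir, ds, model, perms, sh, lambda)

  invisible(list(dataset = ds, model = model, permutation = perms,
                 split_half = sh, lambda = lambda,
                 lambda_selection = lambda_info, paths = paths))
}

write_report <- function(out_dir, ds, model, perms, sh, lambda) {
  lb <- model$labels %||% ds$labels
  load_rows <- list()
  for (r in seq_len(model$rank)) {
    add <- function(mode, labels, values) {
      keep <- values != 0
      if (!any(keep)) return(NULL)
      data.frame(component = r, mode = mode, label = as.character(labels[keep]),
                 loading = values[keep], stringsAsFactors = FALSE)
    }
    load_rows[[length(load_rows) + 1]] <- add("biomarker", lb$biomarkers,
                                              model$biomarker_loadings[, r])
    load_rows[[length(load_rows) + 1]] <- add("time", lb$times,
                                              model$time_loadings[, r])
    if (!is.null(model$baseline_loadings)) {
      load_rows[[length(load_rows) + 1]] <- add("baseline", lb$baseline_vars,
                                                model$baseline_loadings[, r])
    }
    if (!is.null(model$gene_loadings)) {
      load_rows[[length(load_rows) + 1]] <- add("gene", lb$snps,
                                                model$gene_loadings[, r])
    }
  }
  loadings <- do.call(rbind, load_rows)

  ev <- data.frame(
    block = c("tensor", "baseline", "gene", "total"),
    explained_pct = vapply(c("tensor", "baseline", "gene", "total"),
                           function(b) explained_variation(model, ds, b),
                           numeric(1))
  )
  pt <- do.call(rbind, lapply(names(perms), function(k) {
    p <- perms[[k]]
    data.frame(component = p$component, block1 = p$block_pair[1],
               block2 = p$block_pair[2], statistic = p$statistic,
               p_value = p$p_value, n_perm = p$n_perm)
  }))
  shs <- data.frame(
    mode = names(sh$summary$median_congruence),
    median_congruence = as.numeric(sh$summary$median_congruence),
    worst_p = as.numeric(sh$summary$worst_p[
      match(names(sh$summary$median_congruence), names(sh$summary$worst_p))])
  )
  paths <- c(
    loadings = file.path(out_dir, "component_loadings.csv"),
    explained = file.path(out_dir, "explained_variation.csv"),
    permutation = file.path(out_dir, "permutation_tests.csv"),
    split_half = file.path(out_dir, "split_half.csv"),
    summary = file.path(out_dir, "run_summary.yaml")
  )
  utils::write.csv(loadings, paths[["loadings"]], row.names = FALSE)
  utils::write.csv(ev, paths[["explained"]], row.names = FALSE)
  utils::write.csv(pt, paths[["permutation"]], row.names = FALSE)
  utils::write.csv(shs, paths[["split_half"]], row.names = FALSE)
  yaml::write_yaml(list(
    rank = model$rank, lambda = as.numeric(lambda),
    converged = model$converged,
    explained_tensor_pct = ev$explained_pct[ev$block == "tensor"],
    nonzero = list(
      biomarker = sum(model$biomarker_loadings != 0),
      baseline = sum(model$baseline_loadings != 0),
      gene = sum(model$gene_loadings != 0)
    )
  ), paths[["summary"]])
  paths
}
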