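#' Multi-block dataset container
#'
#' Bundles the three coupled blocks sharing a subject mode: the
#' longitudinal biomarker tensor (subjects x biomarkers x visits) with
#' its observation mask, the baseline clinical matrix and the genotype
#' matrix (masked where genotypes are missing), plus axis labels and the
#' per-block weights used in the joint factorization loss.  Missing
#' entries are carried as NA in the arrays and as FALSE in the masks.
#'
#' @param tensor 3-way numeric array, NA = unobserved.
#' @param baseline Numeric matrix subjects x baseline variables.
#' @param gene Numeric matrix subjects x SNPs, NA = missing genotype.
#' @param labels Optional list with `subjects`, `biomarkers`, `times`,
#'   `baseline_vars`, `snps`; taken from dimnames when absent.
#' @param block_weights Optional positive weights (tensor, baseline, gene).
#' @return Object of class `multiblock_dataset`.
#' @export
multiblock_dataset <- function(tensor, baseline, gene, labels = NULL,
                               block_weights = NULL) {
  stopifnot(length(dim(tensor)) == 3, is.matrix(baseline), is.matrix(gene))
  I <- dim(tensor)[1]
  if (nrow(baseline) != I || nrow(gene) != I) {
    stop("all blocks must share the subject mode (", I, " rows)")
  }
  mask <- !is.na(tensor)
  if (!all(apply(mask, 1, any))) {
    stop("every subject needs at least one observed tensor entry")
  }
  if (is.null(labels)) {
    dn <- dimnames(tensor)
    labels <- list(
      subjects = dn[[1]] %||% sprintf("S%03d", seq_len(I)),
      biomarkers = dn[[2]] %||% sprintf("bm%02d", seq_len(dim(tensor)[2])),
      times = suppressWarnings(as.numeric(dn[[3]])) %||% seq_len(dim(tensor)[3]),
      baseline_vars = colnames(baseline) %||% sprintf("base%02d", seq_len(ncol(baseline))),
      snps = colnames(gene) %||% sprintf("snp%02d", seq_len(ncol(gene)))
    )
  }
  if (!is.null(block_weights) && any(block_weights <= 0)) {
    stop("block_weights must be positive")
  }
  structure(list(
    tensor = tensor, tensor_mask = mask,
    baseline = baseline, baseline_mask = !is.na(baseline),
    gene = gene, gene_mask = !is.na(gene),
    labels = labels, block_weights = block_weights,
    standardized = FALSE
  ), class = "multiblock_dataset")
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  d <- dim(x$tensor)
  cat("multiblock_dataset: ", d[1], " subjects\n",
      "  tensor:   ", d[2], " biomarkers x ", d[3], " visits (",
      round(100 * mean(x$tensor_mask), 1), "% observed)\n",
      "  baseline: ", ncol(x$baseline), " variables\n",
      "  gene:     ", ncol(x$gene), " SNPs (",
      round(100 * mean(x$gene_mask), 1), "% observed)\n",
      "  standardized: ", x$standardized,
      if (!is.null(x$block_weights)) paste0("; block weights ",
        paste(signif(x$block_weights, 3), collapse = ", ")) else "",
      "\n", sep = "")
  invisible(x)
}

#' Assemble the biomarker tensor from a long table
#'
#' Builds the subjects x variables x times array (and observation mask)
#' from rows of `(subject, variable, time, value)`.  The visit grid is
#' fixed in advance (months 1, 3, 6 and 12 by default); rows at times
#' outside the grid or for undeclared variables are an error, as are
#' duplicated cells.  Absent cells become masked entries; a declared
#' subject with no rows at all is rejected.
#'
#' @param long_table data.frame with columns `subject_id`, `variable`,
#'   `time_months`, `value` (aliases `subject`/`time` accepted).
#' @param subjects,variables Optional declared orderings; defaults to
#'   order of first appearance.
#' @param times Numeric visit grid, default `c(1, 3, 6, 12)`.
#' @return List with `tensor` (NA = unobserved) and `mask`.
#' @export
assemble_tensor <- function(long_table, subjects = NULL, variables = NULL,
                            times = c(1, 3, 6, 12)) {
  lt <- as.data.frame(long_table)
  nm <- names(lt)
  pick <- function(...) {
    for (cand in c(...)) if (cand %in% nm) return(lt[[cand]])
    stop("long table lacks a column named one of: ", paste(c(...), collapse = ", "))
  }
  subj <- as.character(pick("subject_id", "subject"))
  var <- as.character(pick("variable", "biomarker"))
  tim <- as.numeric(pick("time_months", "time"))
  val <- as.numeric(pick("value"))

  if (is.null(subjects)) subjects <- unique(subj)
  if (is.null(variables)) variables <- unique(var)
  if (!all(subj %in% subjects)) {
    stop("unknown subject id(s): ", paste(unique(setdiff(subj, subjects)), collapse = ", "))
  }
  if (!all(var %in% variables)) {
    stop("unknown variable(s): ", paste(unique(setdiff(var, variables)), collapse = ", "))
  }
  if (!all(tim %in% times)) {
    stop("time value(s) outside the declared grid: ",
         paste(unique(setdiff(tim, times)), collapse = ", "))
  }
  missing_subj <- setdiff(subjects, subj)
  if (length(missing_subj)) {
    stop("subject(s) with zero observations: ", paste(missing_subj, collapse = ", "))
  }

  i <- match(subj, subjects); j <- match(var, variables); k <- match(tim, times)
  cell <- (k - 1L) * length(subjects) * length(variables) +
    (j - 1L) * length(subjects) + i
  if (anyDuplicated(cell)) {
    d <- which(duplicated(cell))[1]
    stop("duplicated cell: subject ", subj[d], ", variable ", var[d],
         ", time ", tim[d])
  }
  tensor <- array(NA_real_, c(length(subjects), length(variables), length(times)),
                  dimnames = list(subjects, variables, times))
  tensor[cell] <- val
  list(tensor = tensor, mask = !is.na(tensor))
}

#' Log-transform, center and scale the blocks
#'
#' Applies the standard multiway preprocessing ahead of a coupled
#' factorization: designated biomarker or baseline variables are
#' log-transformed (they must be strictly positive where observed), then
#' every biomarker-by-time column of the tensor, every baseline column
#' and every SNP column is centered and scaled to unit variance across
#' the subjects on which it is observed.  Constant observed columns
#' cannot be scaled; they are dropped with a warning (tensor columns are
#' masked out instead of dropped, to keep the visit grid regular).
#' Masks are preserved.  The operation is idempotent.
#'
#' @param dataset A [multiblock_dataset].
#' @param log_vars Character names of variables (biomarker or baseline)
#'   to log-transform.
#' @return A standardized `multiblock_dataset`.
#' @export
transform_and_scale <- function(dataset, log_vars = character()) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  ds <- dataset
  lb <- ds$labels

  unknown <- setdiff(log_vars, c(lb$biomarkers, lb$baseline_vars))
  if (length(unknown)) stop("log_vars not in the dataset: ", paste(unknown, collapse = ", "))

  for (v in intersect(log_vars, lb$biomarkers)) {
    j <- match(v, lb$biomarkers)
    slab <- ds$tensor[, j, , drop = FALSE]
    bad <- which(!is.na(slab) & slab <= 0, arr.ind = TRUE)
    if (nrow(bad)) {
      stop("non-positive value in log variable '", v, "' at subject ",
           lb$subjects[bad[1, 1]], ", time ", lb$times[bad[1, 3]])
    }
    ds$tensor[, j, ] <- log(ds$tensor[, j, ])
  }
  for (v in intersect(log_vars, lb$baseline_vars)) {
    m <- match(v, lb$baseline_vars)
    col <- ds$baseline[, m]
    if (any(!is.na(col) & col <= 0)) {
      bad <- which(!is.na(col) & col <= 0)[1]
      stop("non-positive value in log variable '", v, "' at subject ",
           lb$subjects[bad])
    }
    ds$baseline[, m] <- log(col)
  }

  # tensor: standardize each variable-by-time column over observed subjects
  d <- dim(ds$tensor)
  dropped <- character()
  for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    col <- ds$tensor[, j, k]
    obs <- !is.na(col)
    if (!any(obs)) next
    s <- stats::sd(col[obs])
    if (!is.finite(s) || s == 0) {
      ds$tensor[, j, k] <- NA_real_
      dropped <- c(dropped, paste0(lb$biomarkers[j], "@", lb$times[k], "mo"))
      next
    }
    ds$tensor[, j, k] <- (col - mean(col[obs])) / s
  }
  if (length(dropped)) {
    warning("constant tensor column(s) masked out: ", paste(dropped, collapse = ", "))
  }
  ds$tensor_mask <- !is.na(ds$tensor)
  if (!all(apply(ds$tensor_mask, 1, any))) {
    stop("standardization left a subject with no observed tensor entries")
  }

  std_matrix <- function(X, mask, what, labels) {
    keep <- rep(TRUE, ncol(X))
    for (m in seq_len(ncol(X))) {
      col <- X[, m]; obs <- mask[, m]
      if (!any(obs)) { keep[m] <- FALSE; next }
      s <- stats::sd(col[obs])
      if (!is.finite(s) || s == 0) { keep[m] <- FALSE; next }
      X[, m] <- (col - mean(col[obs])) / s
    }
    if (any(!keep)) {
      warning("constant ", what, " column(s) dropped: ",
              paste(labels[!keep], collapse = ", "))
    }
    list(X = X[, keep, drop = FALSE], keep = keep)
  }
  b <- std_matrix(ds$baseline, ds$baseline_mask, "baseline", lb$baseline_vars)
  g <- std_matrix(ds$gene, ds$gene_mask, "gene", lb$snps)
  ds$baseline <- b$X
  ds$baseline_mask <- ds$baseline_mask[, b$keep, drop = FALSE]
  ds$labels$baseline_vars <- lb$baseline_vars[b$keep]
  ds$gene <- g$X
  ds$gene_mask <- ds$gene_mask[, g$keep, drop = FALSE]
  ds$labels$snps <- lb$snps[g$keep]

  ds$standardized <- TRUE
  ds
}

#' Equalize block contributions to the joint loss
#'
#' Sets each block's weight to the reciprocal of its total observed sum
#' of squares, so that on entry to the factorization every block
#' contributes exactly 1 to the joint weighted loss and no block
#' dominates by size alone.
#'
#' @param dataset A standardized [multiblock_dataset].
#' @return The dataset with `block_weights` filled in (tensor, baseline,
#'   gene order).
#' @export
weight_blocks <- function(dataset) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  ss <- c(
    tensor = sum(dataset$tensor[dataset$tensor_mask]^2),
    baseline = sum(dataset$baseline[dataset$baseline_mask]^2),
    gene = sum(dataset$gene[dataset$gene_mask]^2)
  )
  if (any(!is.finite(ss)) || any(ss == 0)) {
    stop("cannot weight an empty or all-masked block (observed SS: ",
         paste(signif(ss, 3), collapse = ", "), ")")
  }
  dataset$block_weights <- 1 / ss
  dataset
}

#' Standard preprocessing pipeline
#'
#' Convenience wrapper: [transform_and_scale()] then [weight_blocks()].
#' @inheritParams transform_and_scale
#' @return A standardized, weighted `multiblock_dataset`.
#' @export
preprocess <- function(dataset, log_vars = character()) {
  weight_blocks(transform_and_scale(dataset, log_vars))
}
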