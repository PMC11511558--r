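#' Compute a module eigengene
#'
#' The eigengene of a module is the first principal component of its
#' gene-by-sample expression submatrix: a one-dimensional summary of module
#' activity per sample. Genes are standardized (centered, unit variance)
#' before extraction so that no single high-variance gene dominates, and the
#' eigengene is the first right singular vector rescaled to unit variance.
#'
#' The sign of a principal component is arbitrary; for reproducibility the
#' eigengene is flipped so that its Pearson correlation with the per-sample
#' mean of the standardized module genes is non-negative. If that
#' correlation is exactly zero, the sign is set so that the loading of the
#' alphabetically first gene is non-negative.
#'
#' @param submatrix numeric gene-by-sample matrix for one module's measured
#'   genes (>= 2 samples).
#' @param min_genes minimum number of usable (non-constant) genes.
#' @return List with `eigengene` (named numeric vector, one value per
#'   sample, mean 0, variance 1), `variance_explained` (fraction in `[0,1]`),
#'   and `loadings` (named per-gene first-left-singular-vector entries).
#' @export
compute_eigengene <- function(submatrix, min_genes = 1L) {
  if (!is.matrix(submatrix) || !is.numeric(submatrix)) {
    stop("submatrix must be a numeric matrix")
  }
  if (ncol(submatrix) < 2L) stop("need >= 2 samples to extract an eigengene")
  sds <- apply(submatrix, 1, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) stop("degenerate module: all genes constant")
  if (length(keep) < nrow(submatrix)) {
    warning(sprintf("dropping %d constant gene(s) before eigengene extraction",
                    nrow(submatrix) - length(keep)))
  }
  if (length(keep) < min_genes) {
    stop(sprintf("fewer than min_genes = %d usable genes", min_genes))
  }
  x <- submatrix[keep, , drop = FALSE]
  xs <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  sv <- svd(xs)
  v1 <- sv$v[, 1]
  u1 <- sv$u[, 1]
  ve <- sv$d[1]^2 / sum(sv$d^2)
  # sign convention: align with the module mean profile
  mean_profile <- colMeans(xs)
  al <- sum(v1 * (mean_profile - mean(mean_profile)))
  if (al < 0) {
    v1 <- -v1
    u1 <- -u1
  } else if (al == 0) {
    first_gene <- order(rownames(x))[1]
    if (u1[first_gene] < 0) {
      v1 <- -v1
      u1 <- -u1
    }
  }
  eig <- v1 / stats::sd(v1)
  names(eig) <- colnames(submatrix)
  names(u1) <- rownames(x)
  list(eigengene = eig, variance_explained = ve, loadings = u1)
}

#' Compute the eigengene matrix of a study
#'
#' Extracts one eigengene per module over a chosen set of samples. Modules
#' whose gene sets intersect the measured genes in fewer than `min_genes`
#' genes, or whose measured genes are all constant, are dropped with a
#' warning and listed in the result.
#'
#' @param study an [expression_study()].
#' @param btms a [btm_collection()].
#' @param samples optional character vector of sample ids defining the
#'   extraction scope (default: all samples). Group-level analyses extract
#'   per group; single-subject networks reuse the group-extracted values
#'   restricted to the subject's samples rather than re-fitting a PCA on
#'   four points.
#' @param min_genes minimum measured genes per retained module.
#' @return Object of class `EigengeneMatrix`: list with `values`
#'   (module-by-sample matrix), `variance_explained`, `dropped`
#'   (data.frame of module, reason), `scope`, and `sign_convention`.
#' @export
eigengene_matrix <- function(study, btms, samples = NULL, min_genes = 1L) {
  samples <- samples %||% study$metadata$sample_id
  expr <- study$expr[, samples, drop = FALSE]
  genes <- rownames(expr)
  vals <- list()
  ve <- c()
  dropped <- data.frame(module = character(), reason = character())
  for (id in names(btms$modules)) {
    present <- intersect(btms$modules[[id]], genes)
    if (length(present) < min_genes || length(present) == 0L) {
      dropped <- rbind(dropped, data.frame(module = id, reason = "no measured genes"))
      next
    }
    res <- tryCatch(
      suppressWarnings(compute_eigengene(expr[present, , drop = FALSE], min_genes)),
      error = function(e) NULL)
    if (is.null(res)) {
      dropped <- rbind(dropped, data.frame(module = id, reason = "degenerate (constant) module"))
      next
    }
    vals[[id]] <- res$eigengene
    ve[id] <- res$variance_explained
  }
  if (!length(vals)) stop("no module has measured genes in this study")
  if (nrow(dropped)) {
    warning(sprintf("%d module(s) dropped: %s", nrow(dropped),
                    paste(dropped$module, collapse = ", ")))
  }
  structure(list(
    values = do.call(rbind, vals),
    variance_explained = ve,
    dropped = dropped,
    scope = if (is.null(samples)) "all" else "subset",
    sign_convention = "align with per-sample mean of standardized module genes; ties by alphabetically first gene loading"
  ), class = "EigengeneMatrix")
}

#' Per-group eigengene matrices
#'
#' Convenience wrapper extracting eigengenes separately within each subject
#' group (the default scope for group and single-subject networks) or once
#' over the pooled samples.
#'
#' @param study an [expression_study()].
#' @param btms a [btm_collection()].
#' @param scope `"group"` (one extraction per group) or `"pooled"`.
#' @param min_genes passed to [eigengene_matrix()].
#' @return Named list of `EigengeneMatrix`, one per group (or one element
#'   `"pooled"`). Only modules retained in every group are kept, so all
#'   matrices share a module order.
#' @export
eigengenes_by_group <- function(study, btms, scope = c("group", "pooled"),
                                min_genes = 1L) {
  scope <- match.arg(scope)
  if (scope == "pooled") {
    return(list(pooled = eigengene_matrix(study, btms, min_genes = min_genes)))
  }
  groups <- sort(unique(study$metadata$group))
  out <- lapply(groups, function(g) {
    s <- study$metadata$sample_id[study$metadata$group == g]
    eigengene_matrix(study, btms, samples = s, min_genes = min_genes)
  })
  names(out) <- groups
  shared <- Reduce(intersect, lapply(out, function(e) rownames(e$values)))
  if (!length(shared)) stop("no module retained in every group")
  lapply(out, function(e) {
    e$values <- e$values[shared, , drop = FALSE]
    e$variance_explained <- e$variance_explained[shared]
    e
  })
}

#' Combine per-group eigengene matrices into one module-by-sample matrix
#'
#' Each sample's eigengene value comes from its own group's extraction.
#' Used by the timepoint ANOVA, which models all samples jointly.
#'
#' @param eig_list named list from [eigengenes_by_group()].
#' @param metadata study metadata (defines the output sample order).
#' @return Module-by-sample numeric matrix.
#' @export
combine_group_eigengenes <- function(eig_list, metadata) {
  m <- do.call(cbind, lapply(eig_list, function(e) e$values))
  m[, metadata$sample_id, drop = FALSE]
}
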