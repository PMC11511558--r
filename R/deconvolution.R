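#' Build a cell-type signature matrix from a labeled reference
#'
#' For each cell type, genes are ranked by the log2 fold change (with
#' pseudocount 1) of the type's mean expression versus the mean over all
#' other cells, and the top `markers_per_type` genes are taken as markers.
#' The signature value of a gene in a type is the mean expression of that
#' gene within the type, over the union of all selected markers.
#'
#' @param reference_expr non-negative gene-by-cell matrix (e.g. single-cell
#'   reference counts or normalized expression).
#' @param labels character/factor of cell-type labels, one per column.
#' @param markers_per_type markers selected per type (default 50).
#' @return `SignatureMatrix`: list with `values` (marker-gene-by-type
#'   matrix), `celltypes`, `markers` (named list per type),
#'   `markers_per_type`.
#' @export
build_signature <- function(reference_expr, labels, markers_per_type = 50L) {
  labels <- as.character(labels)
  if (length(labels) != ncol(reference_expr)) stop("one label per reference cell required")
  types <- sort(unique(labels))
  if (length(types) < 2L) stop("need >= 2 cell types")
  counts <- table(labels)
  if (any(counts < 3L)) stop("each cell type needs >= 3 cells: ",
                             paste(names(counts)[counts < 3L], collapse = ", "))
  if (any(reference_expr < 0)) stop("reference expression must be non-negative")
  means <- vapply(types, function(t) rowMeans(reference_expr[, labels == t, drop = FALSE]),
                  numeric(nrow(reference_expr)))
  if (any(colSums(means) == 0)) {
    stop("cell type with all-zero expression: ",
         paste(types[colSums(means) == 0], collapse = ", "))
  }
  markers <- lapply(seq_along(types), function(i) {
    other <- rowMeans(means[, -i, drop = FALSE])
    lfc <- log2((means[, i] + 1) / (other + 1))
    rownames(reference_expr)[order(-lfc, rownames(reference_expr))][seq_len(min(markers_per_type, nrow(reference_expr)))]
  })
  names(markers) <- types
  sel <- sort(unique(unlist(markers)))
  structure(list(values = means[sel, , drop = FALSE], celltypes = types,
                 markers = markers, markers_per_type = markers_per_type),
            class = "SignatureMatrix")
}

#' @export
print.SignatureMatrix <- function(x, ...) {
  cat("SignatureMatrix:", nrow(x$values), "marker genes x",
      length(x$celltypes), "cell types\n")
  invisible(x)
}

#' Estimate cell-type proportions from bulk expression
#'
#' Solves `bulk ~ signature %*% w` by non-negative least squares on the
#' genes shared between bulk and signature, then normalizes `w` to sum
#' to 1. This constrained least-squares estimator is a deliberately simple,
#' clearly-documented solver; it recovers exact mixtures of the signature
#' columns and is adequate when only relative proportions feed downstream
#' rank tests.
#'
#' @param bulk numeric vector (named by gene) or gene-by-sample matrix.
#' @param sig a [build_signature()] result, or a non-negative gene-by-type
#'   matrix.
#' @return Sample-by-celltype proportion matrix (rows sum to 1). If the
#'   NNLS solution is identically zero the row is uniform and flagged in
#'   `attr(, "degenerate")`.
#' @export
estimate_proportions <- function(bulk, sig) {
  S <- if (inherits(sig, "SignatureMatrix")) sig$values else sig
  if (any(S < 0)) stop("signature must be non-negative")
  if (is.null(dim(bulk))) bulk <- matrix(bulk, ncol = 1, dimnames = list(names(bulk), "sample_1"))
  shared <- intersect(rownames(S), rownames(bulk))
  if (!length(shared)) stop("no overlapping genes between bulk and signature")
  S <- S[shared, , drop = FALSE]
  B <- bulk[shared, , drop = FALSE]
  degenerate <- logical(ncol(B))
  props <- t(vapply(seq_len(ncol(B)), function(j) {
    w <- pracma::lsqnonneg(S, B[, j])$x
    if (sum(w) == 0) {
      degenerate[j] <<- TRUE
      rep(1 / ncol(S), ncol(S))
    } else {
      w / sum(w)
    }
  }, numeric(ncol(S))))
  dimnames(props) <- list(colnames(B), colnames(S))
  attr(props, "degenerate") <- colnames(B)[degenerate]
  props
}

wilcox_p <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(list(W = length(x) * length(y) / 2, p = 1))
  exact <- length(x) <= 20L && length(y) <= 20L &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}

stars_for <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

#' Compare estimated cell-type proportions between groups and timepoints
#'
#' Two-sided Wilcoxon rank-sum tests per cell type: HD versus HC at each
#' timepoint, and (within each group) between consecutive-dose timepoint
#' pairs. Exact p for small tie-free samples, normal approximation with
#' tie correction otherwise. Raw p-values are reported with significance
#' stars at 0.05 / 0.01; set `fdr = TRUE` to add BH q-values.
#'
#' @param proportions sample-by-celltype matrix ([estimate_proportions()]).
#' @param metadata study metadata aligned by `sample_id` to the rows.
#' @param groups the two group labels to contrast, HD-like first.
#' @param timepoint_pairs list of 2-vectors of timepoints to compare within
#'   groups (default `V1D0~V1D7` and `V2D0~V2D7`).
#' @param fdr add BH-adjusted q column (default FALSE, matching the
#'   raw-p annotation convention).
#' @return data.frame: celltype, comparison, n_a, n_b, W, p, stars (and q).
#' @export
compare_proportions <- function(proportions, metadata, groups = c("HD", "HC"),
                                timepoint_pairs = list(c("V1D0", "V1D7"), c("V2D0", "V2D7")),
                                fdr = FALSE) {
  meta <- metadata[match(rownames(proportions), metadata$sample_id), , drop = FALSE]
  rows <- list()
  add <- function(ct, label, x, y) {
    if (length(x) < 2L || length(y) < 2L) return()
    ht <- wilcox_p(x, y)
    rows[[length(rows) + 1L]] <<- data.frame(
      celltype = ct, comparison = label, n_a = length(x), n_b = length(y),
      W = ht$W, p = ht$p)
  }
  for (ct in colnames(proportions)) {
    v <- proportions[, ct]
    for (tp in sort(unique(meta$timepoint))) {
      sel_a <- meta$timepoint == tp & meta$group == groups[1]
      sel_b <- meta$timepoint == tp & meta$group == groups[2]
      add(ct, sprintf("%s_vs_%s@%s", groups[1], groups[2], tp), v[sel_a], v[sel_b])
    }
    for (pair in timepoint_pairs) {
      for (g in groups) {
        sel_a <- meta$timepoint == pair[1] & meta$group == g
        sel_b <- meta$timepoint == pair[2] & meta$group == g
        add(ct, sprintf("%s:%s_vs_%s", g, pair[1], pair[2]), v[sel_a], v[sel_b])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- stars_for(out$p)
  if (fdr) out$q <- fdr_adjust(out$p)
  rownames(out) <- NULL
  out
}
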