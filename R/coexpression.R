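new_coexpression_network <- function(r, n_samples, scope) {
  structure(list(r = r, n_samples = n_samples, scope = scope,
                 module_order = rownames(r)), class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat("CoexpressionNetwork [", x$scope, "]: ", nrow(x$r), " modules, n = ",
      x$n_samples, " samples per edge\n", sep = "")
  invisible(x)
}

pearson_network <- function(values, scope) {
  sds <- apply(values, 1, stats::sd)
  r <- suppressWarnings(stats::cor(t(values)))
  if (any(sds == 0)) {
    warning("zero-variance eigengene(s): ",
            paste(rownames(values)[sds == 0], collapse = ", "),
            "; their edges are NaN and excluded downstream")
  }
  diag(r) <- 1
  new_coexpression_network(r, ncol(values), scope)
}

#' Group-level co-expression network
#'
#' Pairwise Pearson correlations between all module eigengenes across the
#' group's samples, pooled over subjects and timepoints (e.g. 19 subjects x
#' 4 timepoints = 76 samples per edge).
#'
#' @param eig an `EigengeneMatrix` extracted over (at least) the group's
#'   samples, or a plain module-by-sample matrix.
#' @param metadata study metadata.
#' @param group_id group label to select.
#' @return A `CoexpressionNetwork` (symmetric correlation matrix `r`,
#'   `n_samples`, `scope = group_id`).
#' @export
group_network <- function(eig, metadata, group_id) {
  values <- if (inherits(eig, "EigengeneMatrix")) eig$values else eig
  samples <- metadata$sample_id[metadata$group == group_id]
  samples <- intersect(colnames(values), samples)
  if (length(samples) < 4L) stop("group '", group_id, "' has fewer than 4 samples")
  pearson_network(values[, samples, drop = FALSE], scope = group_id)
}

#' Single-subject co-expression network
#'
#' Pearson correlations between module eigengenes across one subject's four
#' timepoint samples. Eigengene values are the group-extracted ones
#' restricted to the subject; no PCA is re-fit on four points.
#'
#' @param eig an `EigengeneMatrix` (or matrix) covering the subject's
#'   samples.
#' @param metadata study metadata.
#' @param subject_id subject label.
#' @param timepoints required timepoints (default `V1D0, V1D7, V2D0, V2D7`).
#' @return A `CoexpressionNetwork` with `n_samples = 4`.
#' @export
subject_network <- function(eig, metadata, subject_id,
                            timepoints = c("V1D0", "V1D7", "V2D0", "V2D7")) {
  values <- if (inherits(eig, "EigengeneMatrix")) eig$values else eig
  meta <- metadata[metadata$subject == subject_id, , drop = FALSE]
  if (!nrow(meta)) stop("unknown subject: ", subject_id)
  if (!setequal(meta$timepoint, timepoints) || nrow(meta) != length(timepoints)) {
    stop("incomplete subject: '", subject_id, "' lacks one of ",
         paste(timepoints, collapse = ", "))
  }
  samples <- meta$sample_id[match(timepoints, meta$timepoint)]
  if (!all(samples %in% colnames(values))) {
    stop("incomplete subject: samples missing from eigengene matrix")
  }
  pearson_network(values[, samples, drop = FALSE], scope = subject_id)
}

#' Long-form edge list of a network
#'
#' @param net a `CoexpressionNetwork`.
#' @return data.frame with `module_a`, `module_b` (a < b), `r`, `n`.
#' @export
as_edge_list <- function(net) {
  idx <- which(upper.tri(net$r), arr.ind = TRUE)
  data.frame(module_a = rownames(net$r)[idx[, 1]],
             module_b = colnames(net$r)[idx[, 2]],
             r = net$r[idx], n = net$n_samples)
}

#' Write a network as a square TSV matrix and an edge list
#'
#' @param net a `CoexpressionNetwork`.
#' @param matrix_path,edges_path output paths (either may be NULL to skip).
#' @return Invisibly, `matrix_path`.
#' @export
write_network <- function(net, matrix_path = NULL, edges_path = NULL) {
  if (!is.null(matrix_path)) write_tsv_matrix(net$r, matrix_path, row_label = "module")
  if (!is.null(edges_path)) {
    utils::write.table(as_edge_list(net), edges_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(matrix_path)
}
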