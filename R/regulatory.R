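#' Construct a RegulatoryNetwork
#'
#' A TF-by-gene matrix of regulatory edge weights, e.g. the output of a
#' message-passing network reconstruction run externally. Consumed, not
#' produced, by this package.
#'
#' @param weights numeric matrix, TFs in rows, genes in columns, finite.
#' @return Object of class `RegulatoryNetwork`.
#' @export
regulatory_network <- function(weights) {
  if (!is.matrix(weights) || !is.numeric(weights)) stop("weights must be a numeric matrix")
  if (any(!is.finite(weights))) stop("non-finite regulatory weights")
  if (is.null(rownames(weights)) || is.null(colnames(weights))) {
    stop("weights must have TF rownames and gene colnames")
  }
  if (anyDuplicated(rownames(weights))) stop("duplicate TF names")
  if (anyDuplicated(colnames(weights))) stop("duplicate gene names")
  structure(list(weights = weights, tf_names = rownames(weights),
                 gene_names = colnames(weights)), class = "RegulatoryNetwork")
}

#' @export
print.RegulatoryNetwork <- function(x, ...) {
  cat("RegulatoryNetwork:", length(x$tf_names), "TFs x",
      length(x$gene_names), "genes\n")
  invisible(x)
}

#' Read a TF-by-gene regulatory network from TSV
#'
#' @param path rectangular numeric TSV, TF rows, gene columns.
#' @return A [regulatory_network()].
#' @export
read_regulatory_network <- function(path) {
  m <- read_tsv_matrix(path)
  regulatory_network(m)
}

#' Write a regulatory network to TSV
#'
#' @param net a `RegulatoryNetwork`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_regulatory_network <- function(net, path) {
  write_tsv_matrix(net$weights, path, row_label = "tf")
  invisible(path)
}

#' Simple prior-plus-correlation regulatory network builder
#'
#' A deliberately simple builder for self-contained synthetic runs:
#' `weight(tf, gene) = prior(tf, gene) + Pearson(expr_tf, expr_gene)` over
#' the study's samples. This is NOT a message-passing reconstruction (no
#' protein-interaction integration, no iterative refinement); real analyses
#' should supply externally computed networks via
#' [read_regulatory_network()].
#'
#' @param motif_prior TF-by-gene 0/1 (or weighted) matrix.
#' @param study an [expression_study()] containing both the TFs and genes
#'   as expression rows.
#' @return A [regulatory_network()].
#' @export
build_prior_network <- function(motif_prior, study) {
  tfs <- rownames(motif_prior)
  genes <- colnames(motif_prior)
  miss_tf <- setdiff(toupper(tfs), rownames(study$expr))
  if (length(miss_tf)) stop("TFs absent from expression matrix: ",
                            paste(miss_tf, collapse = ", "))
  miss_g <- setdiff(toupper(genes), rownames(study$expr))
  if (length(miss_g)) stop("genes absent from expression matrix: ",
                           paste(miss_g, collapse = ", "))
  r <- stats::cor(t(study$expr[toupper(tfs), , drop = FALSE]),
                  t(study$expr[toupper(genes), , drop = FALSE]))
  w <- motif_prior + r
  rownames(w) <- tfs
  colnames(w) <- genes
  regulatory_network(w)
}

#' Regulatory difference network
#'
#' Elementwise HD minus HC edge weights, after normalizing TF and gene
#' order. The result highlights edges whose regulatory strength differs
#' between the groups.
#'
#' @param net_hd,net_hc `RegulatoryNetwork`s on identical TF and gene sets.
#' @return TF-by-gene numeric difference matrix.
#' @export
regulatory_difference <- function(net_hd, net_hc) {
  if (!setequal(net_hd$tf_names, net_hc$tf_names) ||
      !setequal(net_hd$gene_names, net_hc$gene_names)) {
    stop("TF or gene sets differ between networks")
  }
  tfs <- sort(net_hd$tf_names)
  genes <- sort(net_hd$gene_names)
  net_hd$weights[tfs, genes, drop = FALSE] - net_hc$weights[tfs, genes, drop = FALSE]
}

#' Rank gene targets by regulatory difference
#'
#' Aggregates each gene's column of the TF-by-gene difference matrix into
#' one score and sorts genes by it, descending. The default
#' `signed_extreme` takes the entry of maximal absolute value (the gene's
#' most dysregulated edge, keeping its sign; ties resolved toward the
#' lexicographically larger TF name); `sum` takes the column sum. Ties in
#' the final score are ordered by gene name for determinism.
#'
#' @param diff TF-by-gene numeric matrix (from [regulatory_difference()]).
#' @param aggregation `"signed_extreme"` or `"sum"`.
#' @return data.frame `gene`, `score`, sorted by decreasing score; suitable
#'   as the ranked list of [preranked_gsea()].
#' @export
rank_gene_targets <- function(diff, aggregation = c("signed_extreme", "sum")) {
  aggregation <- match.arg(aggregation)
  if (!length(diff)) stop("empty difference matrix")
  score <- if (aggregation == "sum") {
    colSums(diff)
  } else {
    apply(diff, 2, function(col) {
      m <- max(abs(col))
      cand <- which(abs(col) == m)
      # tie: larger TF-name-lexicographic wins
      col[cand[order(rownames(diff)[cand], decreasing = TRUE)[1]]]
    })
  }
  out <- data.frame(gene = colnames(diff), score = unname(score))
  out[order(-out$score, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Top dysregulated edges involving a gene set
#'
#' Reporting helper: the `n_top` edges of largest absolute difference whose
#' target gene belongs to `genes` (e.g. the leading-edge genes of an
#' enriched module).
#'
#' @param diff TF-by-gene difference matrix.
#' @param genes character vector of target genes.
#' @param n_top number of edges to report (default 150).
#' @return data.frame `tf`, `gene`, `difference`, sorted by `|difference|`.
#' @export
top_dysregulated_edges <- function(diff, genes, n_top = 150L) {
  sel <- intersect(colnames(diff), genes)
  if (!length(sel)) stop("none of the genes are in the difference matrix")
  sub <- diff[, sel, drop = FALSE]
  idx <- which(matrix(TRUE, nrow(sub), ncol(sub)), arr.ind = TRUE)
  out <- data.frame(tf = rownames(sub)[idx[, 1]], gene = colnames(sub)[idx[, 2]],
                    difference = sub[idx])
  out <- out[order(-abs(out$difference), out$tf, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n_top)
}
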