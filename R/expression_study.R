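#' Construct an ExpressionStudy
#'
#' An `ExpressionStudy` couples a variance-stabilized gene-by-sample
#' expression matrix with per-sample metadata (subject, group, timepoint).
#' It is the universal input of the pipeline: eigengene extraction, node
#' selection, network construction and deconvolution all start from it.
#'
#' @param expr numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param metadata data.frame with columns `sample_id`, `subject`, `group`,
#'   `timepoint`; one row per column of `expr`, in any order.
#' @return An object of class `ExpressionStudy`: a list with elements
#'   `expr` (matrix, metadata-ordered columns) and `metadata` (data.frame).
#' @export
expression_study <- function(expr, metadata) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("expr must be a numeric matrix")
  req <- c("sample_id", "subject", "group", "timepoint")
  miss <- setdiff(req, colnames(metadata))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  metadata$sample_id <- as.character(metadata$sample_id)
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id in metadata")
  if (is.null(colnames(expr))) stop("expr must have sample ids as colnames")
  if (!setequal(colnames(expr), metadata$sample_id)) {
    stop("expr colnames and metadata sample_id do not match")
  }
  expr <- expr[, metadata$sample_id, drop = FALSE]
  rownames(expr) <- toupper(rownames(expr))
  structure(list(expr = expr, metadata = metadata), class = "ExpressionStudy")
}

#' @export
print.ExpressionStudy <- function(x, ...) {
  cat("ExpressionStudy:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$metadata$group)),
                                 as.integer(table(x$metadata$group))), collapse = ", "), "\n")
  cat("  timepoints:", paste(sort(unique(x$metadata$timepoint)), collapse = ", "), "\n")
  invisible(x)
}

#' Read an ExpressionStudy from TSV files
#'
#' @param expr_path TSV with a leading gene-id column and one column per sample.
#' @param metadata_path TSV with columns sample_id, subject, group, timepoint.
#' @return An [expression_study()] object.
#' @export
read_expression_study <- function(expr_path, metadata_path) {
  expr <- read_tsv_matrix(expr_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_study(expr, meta)
}

#' Write an ExpressionStudy to TSV files
#'
#' @param study an `ExpressionStudy`.
#' @param expr_path,metadata_path output file paths.
#' @return Invisibly, the expression path.
#' @export
write_expression_study <- function(study, expr_path, metadata_path) {
  write_tsv_matrix(study$expr, expr_path, row_label = "gene")
  utils::write.table(study$metadata, metadata_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(expr_path)
}
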