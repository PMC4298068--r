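# Input/output helpers shared across the pipeline. All matrices are plain
# numeric matrices of log2 intensities with feature rownames and sample
# colnames; class labels are a factor named by sample id.

#' Read a feature-by-sample expression matrix from TSV
#'
#' First column = feature id (probe, exon or gene), remaining columns =
#' samples; values are log2 intensities (use `log2_transform = TRUE` for
#' linear-scale input).
#'
#' @param path TSV file path.
#' @param log2_transform apply `log2()` on read.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  if (log2_transform) m <- log2(m)
  .check_matrix(m)
  m
}

#' Write an expression or residual matrix to TSV
#' @param m matrix with rownames and colnames.
#' @param path output file.
#' @param id_column header for the feature-id column.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature_id") {
  tab <- data.frame(rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1L] <- id_column
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample class labels
#'
#' Two-column TSV: `sample_id`, `class`.
#' @param path TSV file path.
#' @return factor of classes, named by sample id.
#' @export
read_class_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(tab)))
    stop("labels file needs columns sample_id, class")
  stats::setNames(factor(tab$class), tab$sample_id)
}

#' Read a probe-to-exon/gene mapping table
#'
#' TSV with columns `probe_id`, `gene_id`, `exon_id` and optionally
#' `ambiguous` (0/1). Ambiguous probes (cross-hybridizing to several loci)
#' are retained in the table but excluded from every computation.
#'
#' @param path TSV file path.
#' @return data.frame with a logical `ambiguous` column.
#' @export
read_probe_mapping <- function(path) {
  .check_mapping(utils::read.delim(path, stringsAsFactors = FALSE))
}

.check_mapping <- function(mapping) {
  stopifnot(is.data.frame(mapping))
  req <- c("probe_id", "gene_id", "exon_id")
  missing_cols <- setdiff(req, names(mapping))
  if (length(missing_cols))
    stop("probe mapping lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(mapping$ambiguous)) mapping$ambiguous <- FALSE
  mapping$ambiguous <- as.logical(mapping$ambiguous)
  mapping
}

.check_matrix <- function(m, what = "expression matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop(what, " has duplicated feature ids")
  if (!all(is.finite(m)))
    stop(what, " contains non-finite values")
  invisible(m)
}

.check_classes <- function(classes, sample_ids) {
  if (is.null(names(classes)))
    stop("class labels must be named by sample id")
  missing_s <- setdiff(sample_ids, names(classes))
  if (length(missing_s))
    stop("samples without class label: ", paste(missing_s, collapse = ", "))
  factor(classes[sample_ids])
}

# exon -> gene map as a named character vector, from a vector or a
# data.frame with columns exon_id, gene_id
.check_exon_genes <- function(exon_genes) {
  if (is.data.frame(exon_genes)) {
    if (!all(c("exon_id", "gene_id") %in% names(exon_genes)))
      stop("exon-gene map needs columns exon_id, gene_id")
    exon_genes <- stats::setNames(as.character(exon_genes$gene_id),
                                  exon_genes$exon_id)
  }
  if (is.null(names(exon_genes)))
    stop("exon-gene map must be named by exon id")
  exon_genes
}
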