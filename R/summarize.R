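#' Quantile normalization of a log2 expression matrix
#'
#' Makes the empirical distribution of every sample identical: each column's
#' sorted values are replaced by the row-wise mean of all columns' sorted
#' values, preserving within-column ranks (ties receive the mean of the
#' values they span). This is the normalization step of the RMA procedure;
#' the transform is idempotent.
#'
#' @param m numeric matrix (features x samples), log2 scale.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m) {
  .check_matrix(m)
  if (ncol(m) < 2L) return(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

# Tukey median polish of one probes-x-samples block: value =
# overall + probe_effect + sample_effect. Returns the per-sample signal
# overall + sample_effect. Sweeps rows then columns, to convergence of the
# sum of absolute residuals (relative eps) or maxiter sweeps; single-probe
# blocks pass through unchanged.
.medpolish_signal <- function(x, eps = 1e-6, maxiter = 10L) {
  if (nrow(x) == 1L) return(x[1L, ])
  # the iteration cap is deliberate (standard RMA practice); reaching it is
  # not worth a per-feature warning
  mp <- withCallingHandlers(
    stats::medpolish(x, eps = eps, maxiter = maxiter, trace.iter = FALSE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mp$overall + mp$col
}

.summarize_groups <- function(probe_matrix, groups, eps = 1e-6,
                              maxiter = 10L) {
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(probe_matrix),
                dimnames = list(names(groups), colnames(probe_matrix)))
  for (i in seq_along(groups)) {
    out[i, ] <- .medpolish_signal(
      probe_matrix[groups[[i]], , drop = FALSE], eps = eps,
      maxiter = maxiter)
  }
  out
}

#' Summarize probe-level signals into exon-level signals
#'
#' Fits, per exon, the additive model
#' `signal = overall + probe_effect + sample_effect` by Tukey median polish
#' on the exon's probes-by-samples block (the summarization step of RMA;
#' probe effects -- probe-specific affinity biases -- are absorbed by the
#' row effects). Ambiguous probes are excluded; exons left without any
#' probe are dropped with a warning.
#'
#' @param probe_matrix probes x samples log2 matrix.
#' @param mapping probe mapping (see [read_probe_mapping()]).
#' @return exon x samples matrix; attribute `"gene_id"` carries the
#'   exon-to-gene map as a named character vector.
#' @export
summarize_exons <- function(probe_matrix, mapping) {
  .check_matrix(probe_matrix, "probe matrix")
  mapping <- .check_mapping(mapping)
  m <- mapping[!mapping$ambiguous, , drop = FALSE]
  dropped <- setdiff(unique(mapping$exon_id), unique(m$exon_id))
  if (length(dropped))
    warning(length(dropped), " exon(s) without unambiguous probes dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "))
  m <- m[m$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  groups <- lapply(split(m$probe_id, m$exon_id), unique)
  exon_gene <- vapply(split(m$gene_id, m$exon_id), `[`, character(1), 1L)
  out <- .summarize_groups(probe_matrix, groups)
  attr(out, "gene_id") <- exon_gene[rownames(out)]
  out
}

#' Summarize probe-level signals into whole-gene signals
#'
#' As [summarize_exons()], but per gene, using only the probes that map to
#' the gene's selected exons (its core selection, see
#' [select_core_exons()]). Genes whose selection is empty
#' (`measurable = FALSE`) are absent from the output, with a warning: their
#' gene signal is not measurable under the chosen rule.
#'
#' @param probe_matrix probes x samples log2 matrix.
#' @param mapping probe mapping (see [read_probe_mapping()]).
#' @param core_selections named list of `core_selection` objects (one per
#'   gene), or `NULL` to use all probes of each gene.
#' @return gene x samples matrix.
#' @export
summarize_genes <- function(probe_matrix, mapping, core_selections = NULL) {
  .check_matrix(probe_matrix, "probe matrix")
  mapping <- .check_mapping(mapping)
  m <- mapping[!mapping$ambiguous, , drop = FALSE]
  m <- m[m$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (!is.null(core_selections)) {
    if (is.null(names(core_selections)))
      names(core_selections) <- vapply(core_selections, `[[`, character(1),
                                       "gene_id")
    unmeasurable <- names(core_selections)[!vapply(core_selections, `[[`,
                                                   logical(1), "measurable")]
    if (length(unmeasurable))
      warning("gene signal not measurable (empty exon selection) for: ",
              paste(utils::head(unmeasurable, 5L), collapse = ", "))
    keep <- vapply(seq_len(nrow(m)), function(i) {
      cs <- core_selections[[m$gene_id[i]]]
      !is.null(cs) && m$exon_id[i] %in% cs$selected_exon_ids
    }, logical(1))
    m <- m[keep, , drop = FALSE]
  }
  no_probe <- setdiff(unique(mapping$gene_id), unique(m$gene_id))
  no_probe <- setdiff(no_probe,
                      if (is.null(core_selections)) character() else
                        names(core_selections)[!vapply(core_selections, `[[`,
                                                       logical(1),
                                                       "measurable")])
  if (length(no_probe))
    warning(length(no_probe), " gene(s) without usable probes dropped: ",
            paste(utils::head(no_probe, 5L), collapse = ", "))
  groups <- lapply(split(m$probe_id, m$gene_id), unique)
  .summarize_groups(probe_matrix, groups)
}
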