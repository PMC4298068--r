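#' Fit the gene-exon linear regression model
#'
#' The core model: for every (gene, exon) pair the exon's log2 signal is
#' regressed on its gene's log2 signal across *all* samples,
#' `e_k = b + s * g_k + r_k`. The fit is unsupervised -- class labels play
#' no role -- so each per-sample residual `r_k` measures how far that
#' sample's exon signal deviates from the level expected given the gene's
#' overall expression. Class-coherent shifts in these residuals are the
#' signature of an alternative splicing event and are tested downstream by
#' [eslim_test()].
#'
#' The slope absorbs the accumulated response characteristics of the exon's
#' probes; the intercept (fitted by default) absorbs exon-specific affinity
#' offsets. `intercept = FALSE` forces the regression through the origin.
#'
#' @param exon_matrix exons x samples log2 matrix (e.g. from
#'   [summarize_exons()]).
#' @param gene_matrix genes x samples log2 matrix (e.g. from
#'   [summarize_genes()]); columns are matched to `exon_matrix` by sample
#'   id.
#' @param exon_genes exon-to-gene map: named character vector
#'   (names = exon ids) or data.frame with columns `exon_id`, `gene_id`.
#'   Defaults to the `"gene_id"` attribute of `exon_matrix` if present.
#' @param classes optional factor of sample classes named by sample id;
#'   stored for downstream testing and plotting.
#' @param intercept fit an intercept (default) or regress through the
#'   origin.
#' @return an object of class `"eslim"` with components
#'   \describe{
#'     \item{fits}{data.frame per (gene, exon) pair: `gene_id`, `exon_id`,
#'       `slope`, `intercept`, `r_squared`, `n`, `degenerate`
#'       (constant gene signal: no regression possible),
#'       `self_regression` (exon signal identical to gene signal, as for
#'       single-exon genes; excluded from testing by default).}
#'     \item{residuals}{exons x samples matrix of residuals (degenerate
#'       pairs omitted).}
#'     \item{skipped}{data.frame of exons skipped and why (missing gene,
#'       degenerate fit).}
#'   }
#'   plus the input matrices, map, classes and call. Methods: `print`,
#'   `summary`, `coef`, `residuals`, `fitted`, `predict`, `plot`.
#' @examples
#' sim <- simulate_splicing_dataset(simulation_config(n_genes = 20, seed = 1))
#' fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
#'              classes = sim$classes)
#' fit
#' head(coef(fit))
#' @export
eslim <- function(exon_matrix, gene_matrix, exon_genes = NULL,
                  classes = NULL, intercept = TRUE) {
  .check_matrix(exon_matrix, "exon matrix")
  .check_matrix(gene_matrix, "gene matrix")
  if (is.null(exon_genes)) exon_genes <- attr(exon_matrix, "gene_id")
  if (is.null(exon_genes))
    stop("exon_genes map is required (or an exon matrix carrying a ",
         "'gene_id' attribute)")
  exon_genes <- .check_exon_genes(exon_genes)

  samples <- colnames(exon_matrix)
  if (!setequal(samples, colnames(gene_matrix)))
    stop("exon and gene matrices must cover the same samples")
  gene_matrix <- gene_matrix[, samples, drop = FALSE]
  n <- length(samples)
  if (n < 3L)
    stop("at least 3 samples are required to fit the regression")
  if (n < 20L)
    warning("only ", n, " samples: the regression-based method is designed ",
            "for datasets of at least 20-30 samples")
  if (!is.null(classes)) {
    classes <- .check_classes(classes, samples)
    names(classes) <- samples
    if (nlevels(classes) == 2L && any(table(classes) < 10L))
      warning("two-class design with fewer than 10 samples in a class; ",
              "power will be limited")
  }

  exons <- rownames(exon_matrix)
  gene_of <- exon_genes[exons]
  missing_map <- exons[is.na(gene_of)]
  missing_gene <- exons[!is.na(gene_of) & !(gene_of %in%
                                              rownames(gene_matrix))]
  skipped <- data.frame(
    exon_id = c(missing_map, missing_gene),
    reason = c(rep("no gene mapping", length(missing_map)),
               rep("gene not in gene matrix", length(missing_gene))),
    stringsAsFactors = FALSE)
  keep <- setdiff(exons, skipped$exon_id)
  if (length(keep) == 0L) stop("no exon could be paired with a gene signal")
  if (nrow(skipped))
    warning(nrow(skipped), " exon(s) skipped (no usable gene signal)")

  E <- exon_matrix[keep, , drop = FALSE]
  G <- gene_matrix[gene_of[keep], , drop = FALSE]

  # vectorized per-row OLS of exon on gene
  if (intercept) {
    Ec <- E - rowMeans(E)
    Gc <- G - rowMeans(G)
    sxx <- rowSums(Gc * Gc)
    sxy <- rowSums(Gc * Ec)
    slope <- sxy / sxx
    b <- rowMeans(E) - slope * rowMeans(G)
  } else {
    sxx <- rowSums(G * G)
    sxy <- rowSums(G * E)
    slope <- sxy / sxx
    b <- rep(0, length(slope))
  }
  degenerate <- sxx < n * 1e-12 | !is.finite(slope)
  slope[degenerate] <- NA_real_
  b[degenerate] <- NA_real_
  fitted <- b + slope * G
  res <- E - fitted
  sse <- rowSums(res * res)
  sst <- rowSums((E - rowMeans(E))^2)
  r2 <- ifelse(sst > 0, 1 - sse / sst, NA_real_)
  self_reg <- vapply(seq_len(nrow(E)), function(i)
    isTRUE(all.equal(unname(E[i, ]), unname(G[i, ]), tolerance = 1e-12)),
    logical(1))

  fits <- data.frame(gene_id = unname(gene_of[keep]), exon_id = keep,
                     slope = unname(slope), intercept = unname(b),
                     r_squared = unname(r2), n = n,
                     degenerate = unname(degenerate),
                     self_regression = self_reg,
                     stringsAsFactors = FALSE)
  if (any(degenerate)) {
    warning(sum(degenerate), " degenerate pair(s) (constant gene signal) ",
            "omitted from the residual matrix")
    skipped <- rbind(skipped,
                     data.frame(exon_id = keep[degenerate],
                                reason = "degenerate fit (constant gene)",
                                stringsAsFactors = FALSE))
  }
  ok <- !degenerate
  rownames(fitted) <- keep
  rownames(res) <- keep
  structure(list(fits = fits,
                 residuals = res[ok, , drop = FALSE],
                 fitted = fitted[ok, , drop = FALSE],
                 skipped = skipped,
                 exon_matrix = exon_matrix,
                 gene_matrix = gene_matrix,
                 exon_genes = gene_of[keep],
                 classes = classes,
                 intercept = intercept,
                 call = match.call()),
            class = "eslim")
}

#' Ordinary least squares for one gene-exon pair
#'
#' Scalar form of the regression fitted en masse by [eslim()]:
#' `slope = cov(e, g) / var(g)` with (optionally) an intercept.
#'
#' @param exon_values,gene_values numeric vectors over the same samples,
#'   length >= 3.
#' @param intercept fit an intercept (default TRUE).
#' @return list with `slope`, `intercept`, `r_squared`, `n`, `degenerate`,
#'   `residuals`.
#' @export
fit_gene_exon <- function(exon_values, gene_values, intercept = TRUE) {
  if (length(exon_values) != length(gene_values))
    stop("exon and gene vectors differ in length")
  n <- length(exon_values)
  if (n < 3L) stop("at least 3 samples are required")
  if (!all(is.finite(exon_values)) || !all(is.finite(gene_values)))
    stop("non-finite values in input")
  if (intercept) {
    vg <- stats::var(gene_values)
    if (vg < 1e-12)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, n = n, degenerate = TRUE,
                  residuals = rep(NA_real_, n)))
    s <- stats::cov(exon_values, gene_values) / vg
    b <- mean(exon_values) - s * mean(gene_values)
  } else {
    sxx <- sum(gene_values^2)
    if (sxx < 1e-12)
      return(list(slope = NA_real_, intercept = NA_real_,
                  r_squared = NA_real_, n = n, degenerate = TRUE,
                  residuals = rep(NA_real_, n)))
    s <- sum(gene_values * exon_values) / sxx
    b <- 0
  }
  r <- exon_values - (b + s * gene_values)
  sst <- sum((exon_values - mean(exon_values))^2)
  list(slope = s, intercept = b,
       r_squared = if (sst > 0) 1 - sum(r^2) / sst else NA_real_,
       n = n, degenerate = FALSE, residuals = r)
}

#' Compute a residual matrix from exon and gene matrices
#'
#' Convenience wrapper around [eslim()] returning only the residual matrix
#' (exons x samples), with class labels attached as attribute `"classes"`.
#'
#' @inheritParams eslim
#' @return residual matrix.
#' @export
residual_matrix <- function(exon_matrix, gene_matrix, exon_genes = NULL,
                            classes = NULL, intercept = TRUE) {
  fit <- eslim(exon_matrix, gene_matrix, exon_genes, classes = classes,
               intercept = intercept)
  out <- fit$residuals
  attr(out, "classes") <- fit$classes
  out
}

#' @export
print.eslim <- function(x, ...) {
  cat("Gene-exon regression model\n")
  cat(sprintf("  %d exon(s) across %d gene(s), %d samples%s\n",
              nrow(x$fits), length(unique(x$fits$gene_id)),
              x$fits$n[1L],
              if (x$intercept) "" else " (no intercept)"))
  if (any(x$fits$degenerate))
    cat("  ", sum(x$fits$degenerate), "degenerate pair(s)\n")
  if (any(x$fits$self_regression))
    cat("  ", sum(x$fits$self_regression),
        "self-regression pair(s) (exon signal == gene signal)\n")
  if (nrow(x$skipped)) cat("  ", nrow(x$skipped), "exon(s) skipped\n")
  if (!is.null(x$classes))
    cat("  classes:", paste(levels(x$classes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.eslim <- function(object, ...) {
  f <- object$fits[!object$fits$degenerate, , drop = FALSE]
  out <- list(n_pairs = nrow(object$fits), n_genes =
                length(unique(object$fits$gene_id)),
              n_samples = object$fits$n[1L],
              slope_summary = summary(f$slope),
              r_squared_summary = summary(f$r_squared),
              n_degenerate = sum(object$fits$degenerate),
              n_self = sum(object$fits$self_regression),
              skipped = object$skipped)
  class(out) <- "summary.eslim"
  out
}

#' @export
print.summary.eslim <- function(x, ...) {
  cat(sprintf("Gene-exon regression model: %d pairs, %d genes, %d samples\n",
              x$n_pairs, x$n_genes, x$n_samples))
  cat("Slopes:\n"); print(x$slope_summary)
  cat("R-squared:\n"); print(x$r_squared_summary)
  if (x$n_degenerate) cat(x$n_degenerate, "degenerate pair(s)\n")
  if (x$n_self) cat(x$n_self, "self-regression pair(s)\n")
  invisible(x)
}

#' @export
coef.eslim <- function(object, ...) {
  f <- object$fits
  m <- cbind(intercept = f$intercept, slope = f$slope)
  rownames(m) <- f$exon_id
  m
}

#' @export
residuals.eslim <- function(object, ...) object$residuals

#' @export
fitted.eslim <- function(object, ...) object$fitted

#' Predict exon signals from gene signals
#'
#' @param object an `eslim` fit.
#' @param gene_matrix optional genes x samples matrix; defaults to the
#'   training gene matrix.
#' @param ... unused.
#' @return predicted exons x samples matrix for all non-degenerate pairs.
#' @export
predict.eslim <- function(object, gene_matrix = NULL, ...) {
  if (is.null(gene_matrix)) return(object$fitted)
  .check_matrix(gene_matrix, "gene matrix")
  f <- object$fits[!object$fits$degenerate, , drop = FALSE]
  f <- f[f$gene_id %in% rownames(gene_matrix), , drop = FALSE]
  G <- gene_matrix[f$gene_id, , drop = FALSE]
  out <- f$intercept + f$slope * G
  rownames(out) <- f$exon_id
  out
}

#' Plot one gene-exon regression
#'
#' Scatter of exon signal against gene signal across samples with the
#' fitted regression line; points are colored by class when labels are
#' available. Class-coherent vertical deviation from the line is the visual
#' signature of a splicing event.
#'
#' @param x an `eslim` fit.
#' @param exon_id the exon to plot.
#' @param ... passed to [graphics::plot()].
#' @export
plot.eslim <- function(x, exon_id, ...) {
  if (missing(exon_id)) exon_id <- x$fits$exon_id[1L]
  f <- x$fits[x$fits$exon_id == exon_id, , drop = FALSE]
  if (nrow(f) == 0L) stop("unknown exon ", exon_id)
  e <- x$exon_matrix[exon_id, ]
  g <- x$gene_matrix[f$gene_id, ]
  col <- if (!is.null(x$classes)) as.integer(x$classes) else 1L
  graphics::plot(g, e, col = col, pch = 19,
                 xlab = sprintf("gene signal (%s, log2)", f$gene_id),
                 ylab = sprintf("exon signal (%s, log2)", exon_id), ...)
  if (!f$degenerate) graphics::abline(f$intercept, f$slope, lty = 2)
  if (!is.null(x$classes))
    graphics::legend("topleft", legend = levels(x$classes), pch = 19,
                     col = seq_len(nlevels(x$classes)), bty = "n")
  invisible(x)
}
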