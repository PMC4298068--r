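#' Supervised test for splicing: moderated t on regression residuals
#'
#' Second stage of the method: the gene-exon regression ([eslim()]) is
#' unsupervised, so a supervised two-class contrast on its residuals is
#' needed to call splicing between two biological categories. Per exon, the
#' difference in mean residual between the classes is tested with an
#' empirical-Bayes moderated t-statistic: each exon's variance is shrunk
#' toward a prior estimated from the distribution of all exon variances
#' (the limma model), which stabilizes the statistic when per-exon variance
#' estimates are noisy.
#'
#' @param object an `eslim` fit, or a residual matrix (exons x samples).
#' @param class_a,class_b the two class labels to contrast (`class_a` minus
#'   `class_b`).
#' @param classes factor of sample classes named by sample id; taken from
#'   the fit (or the matrix's `"classes"` attribute) when omitted.
#' @param moderated use empirical-Bayes variance moderation (default); with
#'   `FALSE` an unmoderated Welch t-test is run instead.
#' @param include_self_regression also test exons whose signal is identical
#'   to their gene signal (single-exon genes); excluded by default since
#'   their residuals are zero by construction.
#' @return data.frame of class `"eslim_test"`, one row per exon:
#'   `gene_id`, `exon_id`, `slope`, `mean_residual_a`, `mean_residual_b`,
#'   `t_statistic`, `p_value`, `fdr` (Benjamini-Hochberg adjusted p),
#'   `r_fold` (`2^(mean_residual_a - mean_residual_b)`, the fold change of
#'   the exon relative to its expected level) and `splicing_index` (when
#'   exon/gene matrices are available). Sorted by p-value.
#' @examples
#' sim <- simulate_splicing_dataset(simulation_config(n_genes = 30, seed = 2))
#' fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
#'              classes = sim$classes)
#' res <- eslim_test(fit, "class1", "class2")
#' head(res)
#' @export
eslim_test <- function(object, class_a, class_b, classes = NULL,
                       moderated = TRUE, include_self_regression = FALSE) {
  if (inherits(object, "eslim")) {
    resid <- object$residuals
    if (is.null(classes)) classes <- object$classes
    fits <- object$fits
  } else {
    resid <- object
    .check_matrix(resid, "residual matrix")
    if (is.null(classes)) classes <- attr(resid, "classes")
    fits <- NULL
  }
  if (is.null(classes)) stop("class labels are required")
  classes <- .check_classes(classes, colnames(resid))

  if (!is.null(fits) && !include_self_regression) {
    self_ex <- fits$exon_id[fits$self_regression]
    resid <- resid[setdiff(rownames(resid), self_ex), , drop = FALSE]
  }
  res <- moderated_t_test(resid, classes, class_a, class_b,
                          moderated = moderated)
  if (!is.null(fits)) {
    idx <- match(res$exon_id, fits$exon_id)
    res$gene_id <- fits$gene_id[idx]
    res$slope <- fits$slope[idx]
  } else {
    res$gene_id <- NA_character_
    res$slope <- NA_real_
  }
  if (inherits(object, "eslim")) {
    si <- splicing_index(object$exon_matrix, object$gene_matrix,
                         object$exon_genes, classes, class_a, class_b)
    res$splicing_index <- si$splicing_index[match(res$exon_id, si$exon_id)]
  } else {
    res$splicing_index <- NA_real_
  }
  res <- res[order(res$p_value, -abs(res$t_statistic), res$exon_id),
             c("gene_id", "exon_id", "slope", "mean_residual_a",
               "mean_residual_b", "t_statistic", "p_value", "fdr", "r_fold",
               "splicing_index")]
  rownames(res) <- NULL
  attr(res, "contrast") <- c(class_a, class_b)
  class(res) <- c("eslim_test", "data.frame")
  res
}

#' Moderated (or plain Welch) two-class t-test on a residual matrix
#'
#' The statistical engine behind [eslim_test()], usable on any
#' features x samples matrix. Variance moderation and p-values follow the
#' limma empirical-Bayes model: per-row pooled variances are shrunk toward
#' a prior variance `s0^2` with `d0` prior degrees of freedom estimated by
#' moment matching on the log variances, and the moderated t is referred to
#' a t distribution with `d + d0` degrees of freedom (two-sided). With
#' fewer than 10 rows the prior cannot be estimated reliably and the
#' function falls back to the unmoderated test with a warning.
#'
#' @param residuals features x samples numeric matrix.
#' @param classes factor named by sample id.
#' @param class_a,class_b the contrasted labels (`class_a` minus `class_b`).
#' @param moderated moderate variances (default) or run Welch's t-test.
#' @return data.frame: `exon_id`, `mean_residual_a`, `mean_residual_b`,
#'   `t_statistic`, `p_value`, `fdr`, `r_fold`.
#' @export
moderated_t_test <- function(residuals, classes, class_a, class_b,
                             moderated = TRUE) {
  .check_matrix(residuals, "residual matrix")
  classes <- .check_classes(classes, colnames(residuals))
  for (cl in c(class_a, class_b))
    if (!cl %in% levels(classes) || sum(classes == cl, na.rm = TRUE) < 2L)
      stop("class ", cl, " absent or has fewer than 2 samples")
  sel <- !is.na(classes) & classes %in% c(class_a, class_b)
  m <- residuals[, sel, drop = FALSE]
  grp <- factor(ifelse(classes[sel] == class_a, "A", "B"),
                levels = c("A", "B"))
  mean_a <- rowMeans(m[, grp == "A", drop = FALSE])
  mean_b <- rowMeans(m[, grp == "B", drop = FALSE])

  if (moderated && nrow(m) < 10L) {
    warning("fewer than 10 rows: prior degrees of freedom cannot be ",
            "estimated; falling back to the unmoderated t-test")
    moderated <- FALSE
  }
  if (moderated) {
    design <- stats::model.matrix(~ 0 + grp)
    colnames(design) <- c("A", "B")
    eb <- tryCatch({
      fit <- limma::lmFit(m, design)
      cfit <- limma::contrasts.fit(fit, c(1, -1))
      limma::eBayes(cfit)
    }, error = function(e) NULL)
    if (is.null(eb)) {
      warning("empirical-Bayes moderation failed; ",
              "falling back to the unmoderated t-test")
      moderated <- FALSE
    } else {
      tstat <- eb$t[, 1L]
      pval <- eb$p.value[, 1L]
    }
  }
  if (!moderated) {
    wt <- .welch_t(m, grp)
    tstat <- wt$t
    pval <- wt$p
  }
  data.frame(exon_id = rownames(m),
             mean_residual_a = unname(mean_a),
             mean_residual_b = unname(mean_b),
             t_statistic = unname(tstat),
             p_value = unname(pval),
             fdr = stats::p.adjust(unname(pval), method = "BH"),
             r_fold = 2^(unname(mean_a) - unname(mean_b)),
             stringsAsFactors = FALSE)
}

# vectorized Welch two-sample t-test over matrix rows
.welch_t <- function(m, grp) {
  a <- m[, grp == "A", drop = FALSE]
  b <- m[, grp == "B", drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  va <- apply(a, 1L, stats::var)
  vb <- apply(b, 1L, stats::var)
  d <- rowMeans(a) - rowMeans(b)
  se2 <- va / na + vb / nb
  t <- ifelse(se2 > 0, d / sqrt(se2), ifelse(d == 0, 0, sign(d) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- 2 * stats::pt(-abs(t), df)
  p[t == 0] <- 1
  list(t = t, p = p)
}

#' Splicing index between two classes
#'
#' The classical baseline: the log-ratio of exon intensity between two
#' sample types after normalization to the gene intensity in each sample
#' type. On the log2 scale,
#' `SI = (mean_a(e) - mean_a(g)) - (mean_b(e) - mean_b(g))`,
#' which equals `log2((E_a/G_a) / (E_b/G_b))` on raw intensities. An exon
#' whose exon/gene ratio is the same in both classes has SI = 0 (no
#' splicing signal).
#'
#' @param exon_matrix exons x samples log2 matrix.
#' @param gene_matrix genes x samples log2 matrix.
#' @param exon_genes exon-to-gene map (named vector or data.frame).
#' @param classes factor named by sample id.
#' @param class_a,class_b the contrasted labels.
#' @return data.frame: `exon_id`, `gene_id`, `splicing_index`.
#' @export
splicing_index <- function(exon_matrix, gene_matrix, exon_genes, classes,
                           class_a, class_b) {
  .check_matrix(exon_matrix, "exon matrix")
  .check_matrix(gene_matrix, "gene matrix")
  exon_genes <- .check_exon_genes(exon_genes)
  classes <- .check_classes(classes, colnames(exon_matrix))
  gene_matrix <- gene_matrix[, colnames(exon_matrix), drop = FALSE]
  exons <- rownames(exon_matrix)
  gene_of <- exon_genes[exons]
  ok <- !is.na(gene_of) & gene_of %in% rownames(gene_matrix)
  if (any(!ok))
    warning(sum(!ok), " exon(s) without gene signal skipped")
  exons <- exons[ok]; gene_of <- gene_of[ok]
  ia <- !is.na(classes) & classes == class_a
  ib <- !is.na(classes) & classes == class_b
  if (!any(ia) || !any(ib)) stop("both classes need at least one sample")
  ea <- rowMeans(exon_matrix[exons, ia, drop = FALSE])
  eb <- rowMeans(exon_matrix[exons, ib, drop = FALSE])
  ga <- rowMeans(gene_matrix[gene_of, ia, drop = FALSE])
  gb <- rowMeans(gene_matrix[gene_of, ib, drop = FALSE])
  data.frame(exon_id = exons, gene_id = unname(gene_of),
             splicing_index = unname((ea - ga) - (eb - gb)),
             stringsAsFactors = FALSE)
}

#' Filter test results at significance and effect-size cutoffs
#'
#' Keeps exons passing all three criteria used to call significant exon
#' alterations in a two-class analysis: BH-adjusted p below `fdr_max` and
#' below `p_adj_max` (two independently configurable cutoffs on the
#' adjusted p-value), and an R-fold outside the dead zone
#' `[rfold_down, rfold_up]` (above `rfold_up` = relative overexpression of
#' the exon, below `rfold_down` = relative repression; the defaults 1.5 and
#' 0.65 are roughly symmetric on the log scale).
#'
#' @param results an `eslim_test` data.frame (needs columns `fdr` and
#'   `r_fold`).
#' @param fdr_max FDR cutoff (default 0.01).
#' @param p_adj_max adjusted-p cutoff (default 1e-7).
#' @param rfold_up,rfold_down effect-size cutoffs (defaults 1.5 and 0.65).
#' @return the surviving rows.
#' @export
apply_thresholds <- function(results, fdr_max = 0.01, p_adj_max = 1e-7,
                             rfold_up = 1.5, rfold_down = 0.65) {
  stopifnot(all(c("fdr", "r_fold") %in% names(results)))
  keep <- results$fdr < fdr_max & results$fdr < p_adj_max &
    (results$r_fold > rfold_up | results$r_fold < rfold_down)
  results[keep, , drop = FALSE]
}

#' Rank genes by their best exon p-value
#'
#' Aggregates exon-level test results to the gene level: each gene is
#' scored by the smallest p-value over its exons, and genes are ranked
#' ascending by that best p (ties broken by larger |t|, then gene id).
#' This ranking is what the ROC evaluation consumes.
#'
#' @param results an `eslim_test` data.frame (columns `gene_id`, `exon_id`,
#'   `p_value`, `t_statistic`).
#' @return data.frame: `gene_id`, `best_p`, `best_exon_id`, `best_t`,
#'   `rank`.
#' @export
gene_ranking <- function(results) {
  stopifnot(all(c("gene_id", "exon_id", "p_value") %in% names(results)))
  if (nrow(results) == 0L) stop("empty results table")
  tcol <- if ("t_statistic" %in% names(results)) results$t_statistic
          else rep(0, nrow(results))
  best <- do.call(rbind, lapply(split(seq_len(nrow(results)),
                                      results$gene_id), function(i) {
    o <- i[order(results$p_value[i], -abs(tcol[i]))][1L]
    data.frame(gene_id = results$gene_id[o], best_p = results$p_value[o],
               best_exon_id = results$exon_id[o], best_t = tcol[o],
               stringsAsFactors = FALSE)
  }))
  best <- best[order(best$best_p, -abs(best$best_t), best$gene_id), ,
               drop = FALSE]
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  best
}
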