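#' All pairwise class contrasts
#'
#' Enumerates the unordered pairs of class labels, e.g. 6 tissues give
#' choose(6, 2) = 15 tissue-pair contrasts.
#'
#' @param classes character vector or factor of class labels (duplicates
#'   allowed).
#' @return data.frame with columns `class_a`, `class_b`, sorted
#'   deterministically.
#' @export
pairwise_contrasts <- function(classes) {
  cls <- sort(unique(as.character(classes)))
  if (length(cls) < 2L) stop("at least 2 classes are required")
  pairs <- t(utils::combn(cls, 2L))
  data.frame(class_a = pairs[, 1L], class_b = pairs[, 2L],
             stringsAsFactors = FALSE)
}

.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Load a reference truth set of splicing events
#'
#' A truth set lists genes known to undergo alternative splicing between
#' pairs of sample classes (e.g. tissue pairs), used as positives when
#' benchmarking a ranking. Class pairs are unordered and duplicate entries
#' are removed.
#'
#' @param x path to a TSV with columns `gene_id`, `class_a`, `class_b`, or
#'   a data.frame in that layout.
#' @return object of class `"truth_set"`: list with `entries` (deduplicated
#'   data.frame carrying a normalized `pair` key) and `n_events` (named
#'   vector of events per class pair).
#' @export
load_truth_set <- function(x) {
  tab <- if (is.data.frame(x)) x
         else utils::read.delim(x, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) {
    entries <- data.frame(gene_id = character(), class_a = character(),
                          class_b = character(), pair = character(),
                          stringsAsFactors = FALSE)
    return(structure(list(entries = entries,
                          n_events = integer()), class = "truth_set"))
  }
  req <- c("gene_id", "class_a", "class_b")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("truth table lacks column(s): ", paste(missing_cols, collapse = ", "))
  tab$pair <- .pair_key(tab$class_a, tab$class_b)
  tab <- tab[!duplicated(tab[, c("gene_id", "pair")]), req <- c(req, "pair"),
             drop = FALSE]
  tab <- tab[order(tab$pair, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(entries = tab,
                 n_events = c(table(tab$pair))),
            class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("Truth set: %d events, %d distinct genes, %d class pair(s)\n",
              nrow(x$entries), length(unique(x$entries$gene_id)),
              length(x$n_events)))
  invisible(x)
}

#' ROC curve and AUC of a gene ranking against a truth set
#'
#' Sweeps a ranked gene list from the top, counting reference splicing
#' genes of the given class pair as positives and all other ranked genes as
#' negatives: TPR = TP/(TP+FN), FPR = FP/(FP+TN), AUC by the trapezoid
#' rule. Truth genes absent from the ranking (e.g. genes whose signal is
#' not measurable under a given gene-signal rule) are appended after the
#' last ranked gene, so a method is penalized for the genes it cannot test.
#'
#' @param ranking a [gene_ranking()] data.frame, or a character vector of
#'   gene ids in rank order (best first).
#' @param truth a `truth_set` (or anything [load_truth_set()] accepts).
#' @param class_pair length-2 character vector of the contrasted classes.
#' @param top_n cutoffs at which to count recovered truth genes
#'   (default 100, 500, 1000).
#' @return object of class `"roc_result"`: list with `class_pair`, `points`
#'   (data.frame `fpr`, `tpr`), `auc` (NA when the pair has no truth
#'   genes), `n_positive`, `n_negative` and `tp_at_n`.
#' @export
roc_and_auc <- function(ranking, truth, class_pair,
                        top_n = c(100L, 500L, 1000L)) {
  if (is.data.frame(ranking)) {
    stopifnot("gene_id" %in% names(ranking))
    ranked <- ranking$gene_id
  } else ranked <- as.character(ranking)
  if (length(ranked) == 0L) stop("empty ranking")
  if (anyDuplicated(ranked)) stop("ranking contains duplicated gene ids")
  if (!inherits(truth, "truth_set")) truth <- load_truth_set(truth)
  stopifnot(length(class_pair) == 2L)
  key <- .pair_key(class_pair[1L], class_pair[2L])
  positives <- unique(truth$entries$gene_id[truth$entries$pair == key])

  missed <- setdiff(positives, ranked)
  ranked <- c(ranked, sort(missed))  # untestable truth genes rank last
  labels <- as.integer(ranked %in% positives)
  P <- sum(labels); N <- length(labels) - P

  tp_at_n <- vapply(top_n, function(n)
    sum(labels[seq_len(min(n, length(labels)))]), integer(1))
  names(tp_at_n) <- as.character(top_n)

  if (P == 0L || N == 0L) {
    return(structure(list(class_pair = class_pair,
                          points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                          auc = NA_real_, n_positive = P, n_negative = N,
                          tp_at_n = tp_at_n),
                     class = "roc_result"))
  }
  tpr <- c(0, cumsum(labels) / P)
  fpr <- c(0, cumsum(1L - labels) / N)
  # trapezoid rule; with a strict ordering this equals the Mann-Whitney
  # statistic (fraction of positive-negative pairs ranked concordantly)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  structure(list(class_pair = class_pair,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_positive = P, n_negative = N,
                 tp_at_n = tp_at_n),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC %s vs %s: AUC = %s (%d positives, %d negatives)\n",
              x$class_pair[1L], x$class_pair[2L],
              if (is.na(x$auc)) "undefined" else sprintf("%.3f", x$auc),
              x$n_positive, x$n_negative))
  cat("  truth genes in top", paste(names(x$tp_at_n), collapse = "/"),
      ":", paste(x$tp_at_n, collapse = "/"), "\n")
  invisible(x)
}

#' Plot an ROC curve
#' @param x a `roc_result`.
#' @param add overlay on an existing plot.
#' @param ... passed to the line-drawing function.
#' @export
plot.roc_result <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                   xlab = "False positive rate",
                   ylab = "True positive rate", xlim = c(0, 1),
                   ylim = c(0, 1), ...)
    graphics::abline(0, 1, col = "grey", lty = 3)
  } else graphics::lines(x$points$fpr, x$points$tpr, ...)
  invisible(x)
}

#' Event-weighted average AUC over class pairs
#'
#' Averages per-pair AUCs weighted by the number of validated splicing
#' events in each pair, so pairs with more reference events count more.
#'
#' @param roc_results list of `roc_result` objects.
#' @param truth the `truth_set` used (weights are its per-pair event
#'   counts); omit to weight by each ROC's own positive count.
#' @return weighted mean AUC.
#' @export
weighted_auc_average <- function(roc_results, truth = NULL) {
  if (inherits(roc_results, "roc_result")) roc_results <- list(roc_results)
  auc <- vapply(roc_results, `[[`, numeric(1), "auc")
  w <- if (!is.null(truth)) {
    keys <- vapply(roc_results, function(r)
      .pair_key(r$class_pair[1L], r$class_pair[2L]), character(1))
    n <- truth$n_events[keys]
    n[is.na(n)] <- 0L
    as.numeric(n)
  } else {
    vapply(roc_results, function(r) as.numeric(r$n_positive), numeric(1))
  }
  ok <- !is.na(auc) & w > 0
  if (!any(ok)) stop("no class pair with a defined AUC")
  sum(auc[ok] * w[ok]) / sum(w[ok])
}

#' Benchmark test results against a truth set over all class pairs
#'
#' Runs the supervised test for every pairwise contrast of the labelled
#' classes, ranks genes by best p-value, and scores each ranking against
#' the truth set.
#'
#' @param fit an `eslim` fit carrying class labels.
#' @param truth a `truth_set`.
#' @param untestable_genes genes the method cannot test (e.g. empty core
#'   selection); appended as ranked-last negatives.
#' @inheritParams eslim_test
#' @return list with `roc` (per-pair `roc_result`s), `weighted_auc`, and
#'   `summary` (data.frame: pair, auc, n_events, tp@top-N).
#' @export
evaluate_contrasts <- function(fit, truth, untestable_genes = character(),
                               moderated = TRUE) {
  stopifnot(inherits(fit, "eslim"))
  if (is.null(fit$classes)) stop("fit carries no class labels")
  pairs <- pairwise_contrasts(fit$classes)
  rocs <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    res <- eslim_test(fit, pairs$class_a[i], pairs$class_b[i],
                      moderated = moderated)
    rk <- gene_ranking(res)
    ranked <- c(rk$gene_id, sort(setdiff(untestable_genes, rk$gene_id)))
    rocs[[i]] <- roc_and_auc(ranked, truth,
                             c(pairs$class_a[i], pairs$class_b[i]))
  }
  summary <- data.frame(
    class_a = pairs$class_a, class_b = pairs$class_b,
    auc = vapply(rocs, `[[`, numeric(1), "auc"),
    n_events = vapply(rocs, `[[`, integer(1), "n_positive"),
    do.call(rbind, lapply(rocs, function(r) {
      m <- t(r$tp_at_n); colnames(m) <- paste0("tp_at_", names(r$tp_at_n)); m
    })),
    stringsAsFactors = FALSE)
  list(roc = rocs,
       weighted_auc = weighted_auc_average(rocs, truth),
       summary = summary)
}
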