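# Shared fixtures built in code. All randomness is locally seeded.

# A random multi-transcript gene locus as an annotation data.frame; every
# transcript contains the first exon so models are always constructible.
random_gene_annotation <- function(gene_id = "G1", n_exons = 8L,
                                   n_transcripts = 4L) {
  starts <- (seq_len(n_exons) - 1L) * 300L + 1L
  exon_ids <- sprintf("%s_E%02d", gene_id, seq_len(n_exons))
  rows <- lapply(seq_len(n_transcripts), function(t) {
    keep <- c(1L, which(stats::runif(n_exons - 1L) > 0.4) + 1L)
    data.frame(gene_id = gene_id,
               transcript_id = sprintf("%s_T%d", gene_id, t),
               exon_id = exon_ids[keep], chrom = "chr1",
               start = starts[keep], end = starts[keep] + 99L,
               strand = "+", biotype = "protein_coding",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# tiny labelled matrix: features x (2 classes * n_per samples)
two_class_matrix <- function(n_features = 50L, n_per = 5L, seed = 1L,
                             delta = 0, delta_rows = integer()) {
  set.seed(seed)
  n <- 2L * n_per
  m <- matrix(rnorm(n_features * n), n_features, n,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n))))
  cl <- stats::setNames(factor(rep(c("A", "B"), each = n_per)), colnames(m))
  if (length(delta_rows)) m[delta_rows, cl == "A"] <-
      m[delta_rows, cl == "A"] + delta
  list(m = m, classes = cl)
}

# brute-force OLS via the normal equations (independent oracle)
ols_oracle <- function(y, x, intercept = TRUE) {
  X <- if (intercept) cbind(1, x) else cbind(x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  if (intercept) list(intercept = beta[1L], slope = beta[2L])
  else list(intercept = 0, slope = beta[1L])
}

# brute-force AUC: fraction of (positive, negative) pairs ranked
# concordantly (Mann-Whitney statistic)
auc_oracle <- function(ranked_ids, positive_ids) {
  lab <- ranked_ids %in% positive_ids
  pos_rank <- which(lab)
  neg_rank <- which(!lab)
  conc <- 0
  for (p in pos_rank) conc <- conc + sum(neg_rank > p)
  conc / (length(pos_rank) * length(neg_rank))
}
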