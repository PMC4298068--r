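test_that("null residuals give uniform p-values at nominal type-I error", {
  set.seed(2024)
  d <- two_class_matrix(n_features = 5000L, n_per = 15L, seed = 2024L)
  res <- moderated_t_test(d$m, d$classes, "A", "B")
  frac <- mean(res$p_value < 0.05)
  band <- 3 * sqrt(0.05 * 0.95 / nrow(res))
  expect_lt(abs(frac - 0.05), band)
  # uniformity beyond the 0.05 tail
  expect_lt(suppressWarnings(
    stats::ks.test(res$p_value, "punif")$statistic), 0.02)
})

test_that("zero mean difference gives t = 0, p = 1", {
  d <- two_class_matrix(n_features = 30L, n_per = 4L, seed = 5L)
  m <- d$m
  # force row 1 to have identical class profiles: zero mean difference
  m[1L, d$classes == "A"] <- c(-1, 0, 1, 2)
  m[1L, d$classes == "B"] <- c(-1, 0, 1, 2)
  res <- moderated_t_test(m, d$classes, "A", "B")
  i <- which(res$exon_id == rownames(m)[1L])
  expect_equal(res$t_statistic[i], 0)
  expect_equal(res$p_value[i], 1)
  expect_equal(res$r_fold[i], 1)
})

test_that("with equal row variances the moderated t equals the pooled
           common-variance t", {
  set.seed(13)
  n_per <- 6L
  d <- two_class_matrix(n_features = 200L, n_per = n_per, seed = 13L)
  m <- d$m
  a <- d$classes == "A"; b <- d$classes == "B"
  # rescale every row to unit pooled within-class variance
  for (i in seq_len(nrow(m))) {
    r <- c(m[i, a] - mean(m[i, a]), m[i, b] - mean(m[i, b]))
    s <- sqrt(sum(r^2) / (2 * n_per - 2))
    m[i, a] <- mean(m[i, a]) + (m[i, a] - mean(m[i, a])) / s
    m[i, b] <- mean(m[i, b]) + (m[i, b] - mean(m[i, b])) / s
  }
  res <- moderated_t_test(m, d$classes, "A", "B")
  expected_t <- (rowMeans(m[, a]) - rowMeans(m[, b])) /
    sqrt(1 * (1 / n_per + 1 / n_per))
  expect_equal(res$t_statistic[match(rownames(m), res$exon_id)],
               unname(expected_t), tolerance = 1e-6)
})

test_that("swapping the contrasted classes negates t, inverts r_fold,
           keeps p", {
  d <- two_class_matrix(n_features = 100L, n_per = 8L, seed = 17L,
                        delta = 1, delta_rows = 1:10)
  r1 <- moderated_t_test(d$m, d$classes, "A", "B")
  r2 <- moderated_t_test(d$m, d$classes, "B", "A")
  expect_equal(r1$t_statistic, -r2$t_statistic, tolerance = 1e-12)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  expect_equal(r1$r_fold, 1 / r2$r_fold, tolerance = 1e-12)
  expect_equal(r1$mean_residual_a, r2$mean_residual_b)
})

test_that("few rows fall back to the unmoderated test with a warning", {
  d <- two_class_matrix(n_features = 5L, n_per = 5L, seed = 19L)
  expect_warning(r <- moderated_t_test(d$m, d$classes, "A", "B"),
                 "fewer than 10 rows")
  w <- moderated_t_test(d$m, d$classes, "A", "B", moderated = FALSE)
  expect_equal(r$t_statistic, w$t_statistic)
  expect_error(moderated_t_test(d$m, d$classes, "A", "C"), "absent")
})

test_that("BH adjustment matches the textbook step-up procedure", {
  p <- c(0.01, 0.04, 0.03, 0.005, 0.5)
  # step-up by hand: sorted p (0.005, 0.01, 0.03, 0.04, 0.5),
  # p*(m/i) = (0.025, 0.025, 0.05, 0.05, 0.5); cumulative min from the top
  hand <- c(0.025, 0.05, 0.05, 0.025, 0.5)
  expect_equal(stats::p.adjust(p, "BH"), hand)
  d <- two_class_matrix(n_features = 5L, n_per = 5L, seed = 23L)
  r <- moderated_t_test(d$m, d$classes, "A", "B", moderated = FALSE)
  expect_equal(r$fdr, stats::p.adjust(r$p_value, "BH"))
})

test_that("splicing index matches the ratio-of-ratios formula on raw scale", {
  set.seed(29)
  n <- 10L
  e <- matrix(rnorm(3 * n, 8), 3, n,
              dimnames = list(paste0("E", 1:3), paste0("s", 1:n)))
  g <- matrix(rnorm(2 * n, 8), 2, n,
              dimnames = list(paste0("G", 1:2), paste0("s", 1:n)))
  map <- c(E1 = "G1", E2 = "G1", E3 = "G2")
  cl <- stats::setNames(factor(rep(c("A", "B"), each = n / 2)), colnames(e))
  si <- splicing_index(e, g, map, cl, "A", "B")
  # brute-force oracle on unlogged intensities:
  # SI = log2( (Ea/Ga) / (Eb/Gb) ) with class means of log2 signals
  for (i in 1:3) {
    ex <- si$exon_id[i]; gid <- map[ex]
    ea <- 2^mean(e[ex, cl == "A"]); eb <- 2^mean(e[ex, cl == "B"])
    ga <- 2^mean(g[gid, cl == "A"]); gb <- 2^mean(g[gid, cl == "B"])
    expect_equal(si$splicing_index[i], log2((ea / ga) / (eb / gb)),
                 tolerance = 1e-12)
  }
})

test_that("splicing index is zero when exon/gene ratio is class-invariant
           and log2(2) for a clean 2-fold exon change", {
  n <- 6L
  samples <- paste0("s", 1:n)
  cl <- stats::setNames(factor(rep(c("A", "B"), each = n / 2)), samples)
  g <- matrix(c(8, 8, 8, 10, 10, 10), 1, n,
              dimnames = list("G1", samples))
  e_flat <- g + 0.75  # constant exon/gene ratio in both classes
  rownames(e_flat) <- "E1"
  expect_identical(
    splicing_index(e_flat, g, c(E1 = "G1"), cl, "A", "B")$splicing_index, 0)

  e_up <- g; rownames(e_up) <- "E1"
  e_up[1L, cl == "A"] <- e_up[1L, cl == "A"] + 1  # 2x up in class A only
  expect_equal(
    splicing_index(e_up, g, c(E1 = "G1"), cl, "A", "B")$splicing_index, 1)
})

test_that("threshold filter keeps exactly the hand-enumerated rows", {
  tab <- data.frame(
    exon_id = paste0("E", 1:5),
    fdr = c(0.5, 1e-9, 1e-9, 1e-8, 1e-3),
    r_fold = c(2.0, 1.0, 1.8, 0.5, 3.0),
    stringsAsFactors = FALSE)
  # hand evaluation at fdr<0.01, p_adj<1e-7, r_fold>1.5 or <0.65:
  # E1 fails fdr; E2 inside the dead zone; E3 passes; E4 passes (repressed);
  # E5 fails the 1e-7 cutoff
  kept <- apply_thresholds(tab)
  expect_setequal(kept$exon_id, c("E3", "E4"))
})

test_that("gene ranking takes the best exon p-value with deterministic ties", {
  tab <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g3"),
    exon_id = paste0("E", 1:5),
    p_value = c(0.5, 0.01, 0.2, 0.01, 0.3),
    t_statistic = c(1, 2.5, -1, -3.5, 1.5),
    stringsAsFactors = FALSE)
  rk <- gene_ranking(tab)
  expect_equal(rk$best_p[rk$gene_id == "g1"], 0.01)
  expect_equal(rk$best_exon_id[rk$gene_id == "g1"], "E2")
  # g1 and g2 tie on p; the larger |t| (g2, -3.5) wins
  expect_equal(rk$gene_id[1:2], c("g2", "g1"))
  expect_equal(rk$rank, 1:3)

  # agrees with a brute-force group-by-min oracle on random tables
  set.seed(31)
  big <- data.frame(gene_id = sample(paste0("g", 1:30), 200, TRUE),
                    exon_id = paste0("E", 1:200),
                    p_value = runif(200),
                    t_statistic = rnorm(200), stringsAsFactors = FALSE)
  rk2 <- gene_ranking(big)
  oracle <- tapply(big$p_value, big$gene_id, min)
  expect_equal(rk2$best_p, as.numeric(oracle[rk2$gene_id]))
  expect_false(is.unsorted(rk2$best_p))
})

test_that("eslim_test returns a coherent joined result table", {
  sim <- simulate_splicing_dataset(simulation_config(n_genes = 40L,
                                                     seed = 47L))
  fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
               classes = sim$classes)
  res <- eslim_test(fit, "class1", "class2")
  expect_s3_class(res, "eslim_test")
  expect_true(all(c("gene_id", "exon_id", "slope", "t_statistic", "p_value",
                    "fdr", "r_fold", "splicing_index") %in% names(res)))
  expect_false(is.unsorted(res$p_value))
  expect_true(all(res$r_fold > 0))
  expect_true(all(res$fdr > 0 & res$fdr <= 1))
  expect_equal(res$r_fold,
               2^(res$mean_residual_a - res$mean_residual_b),
               tolerance = 1e-12)
})

test_that("power at fixed alpha increases with effect size", {
  # an injected event is detected if a contrast involving its class gives
  # p < 0.05 for the carrying exon
  power_at <- function(delta) {
    sim <- simulate_splicing_dataset(simulation_config(
      n_genes = 120L, splicing_fraction = 0.1, effect_size = delta,
      seed = 99L))
    fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
                 classes = sim$classes)
    pairs <- pairwise_contrasts(sim$classes)
    pvals <- lapply(seq_len(nrow(pairs)), function(j) {
      r <- eslim_test(fit, pairs$class_a[j], pairs$class_b[j])
      stats::setNames(r$p_value, r$exon_id)
    })
    hits <- vapply(seq_len(nrow(sim$truth)), function(i) {
      involved <- which(pairs$class_a == sim$truth$class[i] |
                          pairs$class_b == sim$truth$class[i])
      min(vapply(involved, function(j)
        pvals[[j]][sim$truth$exon_id[i]], numeric(1))) < 0.05
    }, logical(1))
    mean(hits)
  }
  p <- vapply(c(0.25, 0.5, 1.0), power_at, numeric(1))
  expect_true(all(diff(p) >= 0))
  expect_gt(p[3L], 0.9)
})
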