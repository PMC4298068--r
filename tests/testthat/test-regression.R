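test_that("single-pair OLS matches the normal-equations oracle", {
  # worked example: e = (1,2,3,5), g = (1,2,3,4)
  e <- c(1, 2, 3, 5); g <- c(1, 2, 3, 4)
  fit <- fit_gene_exon(e, g)
  oracle <- ols_oracle(e, g)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-12)

  # identity: exon tracks gene exactly
  fit_id <- fit_gene_exon(g, g)
  expect_equal(fit_id$slope, 1)
  expect_equal(fit_id$intercept, 0)
  expect_equal(fit_id$residuals, rep(0, 4))

  # constant exon: slope 0, intercept c
  fit_c <- fit_gene_exon(rep(3, 4), g)
  expect_equal(fit_c$slope, 0)
  expect_equal(fit_c$intercept, 3)
  expect_equal(fit_c$residuals, rep(0, 4))

  # degenerate: constant gene
  fit_d <- fit_gene_exon(e, rep(2, 4))
  expect_true(fit_d$degenerate)
  expect_true(is.na(fit_d$slope))

  expect_error(fit_gene_exon(1:3, 1:4), "length")
  expect_error(fit_gene_exon(1:2, 1:2), "at least 3")
})

test_that("OLS equals the oracle over many random small fits", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(3:12, 1L)
    g <- rnorm(n); e <- rnorm(n)
    fit <- fit_gene_exon(e, g)
    oracle <- ols_oracle(e, g)
    expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$intercept, oracle$intercept, tolerance = 1e-10)
  }
})

test_that("no-intercept fit regresses through the origin", {
  set.seed(7)
  g <- rnorm(10, mean = 5); e <- 2 * g + rnorm(10, sd = 0.1)
  fit <- fit_gene_exon(e, g, intercept = FALSE)
  oracle <- ols_oracle(e, g, intercept = FALSE)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$slope, oracle$slope, tolerance = 1e-10)
})

test_that("eslim fits every pair like the scalar fit and residuals satisfy
           OLS identities", {
  set.seed(21)
  sim <- simulate_splicing_dataset(simulation_config(n_genes = 25L,
                                                     seed = 21L))
  fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
               classes = sim$classes)
  # spot-check rows against the scalar path
  for (ex in sample(fit$fits$exon_id, 10L)) {
    row <- fit$fits[fit$fits$exon_id == ex, ]
    single <- fit_gene_exon(sim$exon_matrix[ex, ],
                            sim$gene_matrix[row$gene_id, ])
    expect_equal(row$slope, single$slope, tolerance = 1e-10)
    expect_equal(row$intercept, single$intercept, tolerance = 1e-10)
  }
  # with an intercept: residuals sum to zero and are orthogonal to gene
  res <- residuals(fit)
  G <- sim$gene_matrix[fit$fits$gene_id, , drop = FALSE]
  rownames(G) <- fit$fits$exon_id
  expect_lt(max(abs(rowSums(res))), 1e-8)
  expect_lt(max(abs(rowSums(res * G[rownames(res), , drop = FALSE]))), 1e-6)
})

test_that("an all-tracking dataset yields an all-zero residual matrix", {
  g <- matrix(rnorm(60, 8), 3, 20,
              dimnames = list(paste0("G", 1:3), paste0("s", 1:20)))
  e <- g[rep(1:3, each = 2), ]
  rownames(e) <- paste0("E", 1:6)
  map <- stats::setNames(rep(paste0("G", 1:3), each = 2), rownames(e))
  res <- residual_matrix(e, g, map)
  expect_lt(max(abs(res)), 1e-12)
})

test_that("a class-specific offset appears in the residuals, shrunk by
           leverage", {
  set.seed(33)
  n_per <- c(small = 3L, rest = 27L)
  g <- rnorm(30, 8, 2)
  e <- 0.5 + 1.2 * g + rnorm(30, sd = 0.01)
  delta <- 1.5
  spliced <- 1:3  # small fraction of samples carries the event
  e[spliced] <- e[spliced] + delta
  gm <- matrix(g, 1, 30, dimnames = list("G1", paste0("s", 1:30)))
  em <- matrix(e, 1, 30, dimnames = list("E1", paste0("s", 1:30)))
  res <- suppressWarnings(residual_matrix(em, gm, c(E1 = "G1")))
  expect_equal(mean(res[1L, spliced]), delta, tolerance = 0.15)
})

test_that("fitting is class-blind and shift-equivariant", {
  set.seed(55)
  sim <- simulate_splicing_dataset(simulation_config(n_genes = 15L,
                                                     seed = 55L))
  fit1 <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
                classes = sim$classes)
  fit2 <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes,
                classes = sample(sim$classes))
  expect_identical(residuals(fit1), residuals(fit2))

  # adding a constant to all gene values changes intercepts only
  fit3 <- eslim(sim$exon_matrix, sim$gene_matrix + 5, sim$exon_genes)
  expect_equal(residuals(fit3), residuals(fit1), tolerance = 1e-9)
  expect_equal(fit3$fits$slope, fit1$fits$slope, tolerance = 1e-9)
  expect_equal(fit3$fits$intercept, fit1$fits$intercept - 5 * fit1$fits$slope,
               tolerance = 1e-9)
})

test_that("degenerate and unmapped pairs are reported, not fatal", {
  g <- matrix(c(rnorm(20, 8), rep(2, 20)), 2, 20, byrow = TRUE,
              dimnames = list(c("G1", "Gflat"), paste0("s", 1:20)))
  e <- rbind(G1_E1 = 2 * g[1L, ] + rnorm(20, sd = .1),
             Gflat_E1 = rnorm(20),
             orphan_E1 = rnorm(20))
  colnames(e) <- colnames(g)
  map <- c(G1_E1 = "G1", Gflat_E1 = "Gflat", orphan_E1 = "Gmissing")
  expect_warning(expect_warning(
    fit <- eslim(e, g, map), "skipped"), "degenerate")
  expect_equal(rownames(residuals(fit)), "G1_E1")
  expect_setequal(fit$skipped$exon_id, c("orphan_E1", "Gflat_E1"))
  # single-sample input: error
  expect_error(eslim(e[, 1, drop = FALSE], g[, 1, drop = FALSE], map),
               "at least 3")
})

test_that("self-regression pairs are flagged and excluded from testing", {
  set.seed(77)
  g <- matrix(rnorm(40, 8), 2, 20,
              dimnames = list(c("G1", "G2"), paste0("s", 1:20)))
  e <- rbind(E1 = g[1L, ],                       # single-exon gene: e == g
             E2 = 1 + 0.9 * g[2L, ] + rnorm(20, sd = .1))
  colnames(e) <- colnames(g)
  cl <- stats::setNames(factor(rep(c("A", "B"), each = 10)), colnames(g))
  fit <- eslim(e, g, c(E1 = "G1", E2 = "G2"), classes = cl)
  expect_true(fit$fits$self_regression[fit$fits$exon_id == "E1"])
  res <- eslim_test(fit, "A", "B", moderated = FALSE)
  expect_false("E1" %in% res$exon_id)
  res_all <- eslim_test(fit, "A", "B", moderated = FALSE,
                        include_self_regression = TRUE)
  expect_true("E1" %in% res_all$exon_id)
})

test_that("predict and coef are consistent with the stored fit", {
  sim <- simulate_splicing_dataset(simulation_config(n_genes = 10L,
                                                     seed = 3L))
  fit <- eslim(sim$exon_matrix, sim$gene_matrix, sim$exon_genes)
  co <- coef(fit)
  pred <- predict(fit, sim$gene_matrix)
  ex <- rownames(pred)[1L]
  gid <- fit$fits$gene_id[fit$fits$exon_id == ex]
  expect_equal(pred[ex, ],
               co[ex, "intercept"] + co[ex, "slope"] * sim$gene_matrix[gid, ],
               tolerance = 1e-12)
  expect_equal(fitted(fit)[rownames(pred), ], pred, tolerance = 1e-12)
})
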