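test_that("PCA is self-consistent and orthonormal", {
  m <- two_pop_model(0.05, n_per_pop = 60, n_variants = 800)
  panel <- sample_genotype_panel(m, 1)
  pc <- compute_pca(panel, k = 10)
  expect_equal(crossprod(pc$loadings), diag(10), tolerance = 1e-8,
               ignore_attr = TRUE)
  # projecting the fitting samples reproduces their scores
  proj <- project_samples(pc, panel)
  expect_equal(unname(proj), unname(pc$scores), tolerance = 1e-8)
  expect_error(compute_pca(panel, k = 1e5), "rank")
})

test_that("PC1 separates populations at F = 0.05", {
  m <- two_pop_model(0.05, n_per_pop = 250, n_variants = 20000, nf = 500)
  panel <- sample_genotype_panel(m, 2)
  pc <- compute_pca(panel, k = 5)
  lab <- as.numeric(panel$samples$pop == "A")
  expect_gt(abs(cor(pc$scores[, 1], lab)), 0.9)
})

test_that("randomized and exact PCA agree on the separated component", {
  # PC1 (population structure) is well separated from the noise bulk and
  # must match; noise-bulk components are rotation-degenerate by nature
  m <- two_pop_model(0.05, n_per_pop = 100, n_variants = 3000, nf = 500)
  panel <- sample_genotype_panel(m, 3)
  exact <- compute_pca(panel, k = 4, exact_max = 1e9)
  rand <- compute_pca(panel, k = 4, exact_max = 1)
  expect_gt(abs(cor(exact$scores[, 1], rand$scores[, 1])), 0.999)
  expect_equal(exact$eigenvalues[1], rand$eigenvalues[1],
               tolerance = 1e-6)
  expect_equal(crossprod(rand$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # determinism of the randomized path
  rand2 <- compute_pca(panel, k = 4, exact_max = 1)
  expect_identical(rand$scores, rand2$scores)
})

test_that("projection harmonizes alleles and handles missingness", {
  m <- two_pop_model(0.02, n_per_pop = 80, n_variants = 500)
  panel <- sample_genotype_panel(m, 4)
  pc <- compute_pca(panel, k = 3)
  # swapped ref/alt with complementary dosage must project identically
  qp <- subset_panel(panel, samples = 1:10)
  qp_sw <- qp
  sw <- seq(1, ncol(qp$dosages), by = 2)
  sw <- sw[sw <= length(pc$variants$id)]
  swap_ids <- pc$variants$id[sw]
  cols <- match(swap_ids, qp_sw$variants$id)
  qp_sw$dosages[, cols] <- 2 - qp_sw$dosages[, cols]
  tmp <- qp_sw$variants$ref[cols]
  qp_sw$variants$ref[cols] <- qp_sw$variants$alt[cols]
  qp_sw$variants$alt[cols] <- tmp
  expect_equal(project_samples(pc, qp_sw), project_samples(pc, qp),
               tolerance = 1e-10)
  # an all-missing sample projects to the origin
  qp2 <- subset_panel(panel, samples = 1:3)
  qp2$dosages[1, ] <- NA
  proj <- project_samples(pc, qp2)
  expect_equal(unname(proj[1, ]), rep(0, 3), tolerance = 1e-10)
  # insufficient overlap errors
  qp3 <- subset_panel(panel, variants = 1:10)
  expect_error(project_samples(pc, qp3), "overlap")
})

test_that("GWAS matches lm() coefficient, SE and p exactly", {
  # 6-sample toy, no covariates
  D <- cbind(c(0, 0, 1, 1, 2, 2))
  y <- c(0.1, -0.1, 0.9, 1.1, 2.2, 1.8)
  panel <- toy_panel(D)
  g <- run_gwas(panel, y)
  fit <- summary(lm(y ~ D[, 1]))$coefficients
  expect_equal(g$BETA, fit[2, 1], tolerance = 1e-6)
  expect_equal(g$SE, fit[2, 2], tolerance = 1e-6)
  expect_equal(g$P, fit[2, 4], tolerance = 1e-6)

  # with covariates, many variants
  set.seed(5)
  n <- 80; mvar <- 30
  D2 <- matrix(rbinom(n * mvar, 2, 0.3), n, mvar)
  cv <- cbind(rnorm(n), rnorm(n))
  y2 <- 0.3 * D2[, 7] + 0.5 * cv[, 1] + rnorm(n)
  p2 <- toy_panel(D2)
  g2 <- run_gwas(p2, y2, covariates = cv)
  for (j in c(1, 7, 30)) {
    fit <- summary(lm(y2 ~ D2[, j] + cv))$coefficients
    expect_equal(g2$BETA[j], fit[2, 1], tolerance = 1e-8)
    expect_equal(g2$SE[j], fit[2, 2], tolerance = 1e-8)
    expect_equal(g2$P[j], fit[2, 4], tolerance = 1e-8)
  }
  expect_true(all(g2$N == n))
  # monomorphic variants are flagged with NA statistics
  D3 <- cbind(D2[, 1], 2)
  g3 <- run_gwas(toy_panel(D3), y2)
  expect_true(is.na(g3$BETA[2]) && is.na(g3$P[2]))
  expect_error(run_gwas(p2, y2, covariates = cbind(cv, cv[, 1])),
               "rank deficient")
})

test_that("GWAS effect estimates are unbiased for causal variants", {
  m <- population_model("A", c(A = 0.01), c(A = 1200),
                        n_founder_haplotypes = 100, n_chrom = 2,
                        variants_per_chrom = 500)
  panel <- sample_genotype_panel(m, 6)
  ratios <- c()
  for (s in 1:5) {
    arch <- draw_sparse_architecture(panel, 5, h2 = 0.8, seed = 10 + s)
    ph <- simulate_phenotype(panel, arch, seed = 20 + s)
    g <- run_gwas(panel, ph$phenotype)
    # y = h2 * (raw - mu)/sd + noise, so the expected slope at causal j is
    # h2 * beta_j / sd(raw)
    idx <- match(arch$causal_ids, g$ID)
    raw <- panel$dosages[, match(arch$causal_ids, panel$variants$id),
                         drop = FALSE] %*% arch$effects
    expected <- 0.8 * arch$effects / sqrt(mean((raw - mean(raw))^2))
    big <- abs(expected) > 0.05  # negligible effects are noise-dominated
    ratios <- c(ratios, g$BETA[idx][big] / expected[big])
  }
  expect_equal(mean(ratios), 1, tolerance = 0.05)
})

test_that("IVW meta-analysis reproduces hand arithmetic", {
  panel <- toy_panel(matrix(c(0, 1, 2, 1, 0, 1), 3, 2),
                     ref = c("A", "C"), alt = c("G", "T"))
  t1 <- toy_stats(panel, beta = c(0.2, 0.2), p = c(0.5, 0.5))
  t1$SE <- c(0.1, 0.1)
  t2 <- t1; t2$BETA <- c(0.4, 0.5); t2$SE <- c(0.1, 0.2)
  meta <- ivw_meta(list(t1, t2))
  expect_equal(meta$BETA[1], 0.3, tolerance = 1e-12)
  expect_equal(meta$SE[1], sqrt(1 / (100 + 100)), tolerance = 1e-9)
  expect_equal(meta$BETA[2], (0.2 / 0.01 + 0.5 / 0.04) / (100 + 25),
               tolerance = 1e-12)  # = 0.26
  expect_equal(meta$BETA[2], 0.26, tolerance = 1e-12)
  expect_equal(meta$SE[2], 1 / sqrt(125), tolerance = 1e-9)
  expect_equal(meta$SE[2], 0.0894, tolerance = 1e-3)
  expect_equal(meta$N, t1$N + t2$N)
  # single table: identity on beta/SE
  m1 <- ivw_meta(list(t1))
  expect_equal(m1$BETA, t1$BETA)
  expect_equal(m1$SE, t1$SE, tolerance = 1e-12)
  # equal-SE meta equals the arithmetic mean of betas exactly
  expect_equal(ivw_meta(list(t1, t1, t2))$BETA[1],
               mean(c(0.2, 0.2, 0.4)), tolerance = 1e-12)
})

test_that("IVW harmonizes swapped alleles and polices bad pairs", {
  panel <- toy_panel(matrix(c(0, 1, 2, 1), 2, 2),
                     ref = c("A", "C"), alt = c("G", "T"))
  t1 <- toy_stats(panel, beta = c(0.2, 0.3), p = c(0.5, 0.5))
  t1$SE <- c(0.1, 0.1)
  # swapped effect/other alleles in the second table -> sign flip
  t2 <- t1
  t2$A1 <- t1$A2; t2$A2 <- t1$A1; t2$BETA <- -t1$BETA
  t2$A1_FREQ <- 1 - t1$A1_FREQ
  meta <- ivw_meta(list(t1, t2))
  expect_equal(meta$BETA, t1$BETA, tolerance = 1e-12)
  # strand-ambiguous variants dropped by default
  t3 <- t1; t3$A1 <- c("A", "C"); t3$A2 <- c("T", "G")
  expect_equal(nrow(ivw_meta(list(t3))), 0)
  expect_equal(nrow(ivw_meta(list(t3), drop_ambiguous = FALSE)), 2)
  # irreconcilable allele pair errors
  t4 <- t1; t4$A1[1] <- "C"; t4$A2[1] <- "A"
  expect_error(ivw_meta(list(t1, t4)), "irreconcilable")
})
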