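test_that("Balding-Nichols law has the right mean and variance", {
  # direct Monte-Carlo of the Beta parameterization, 1e5 draws
  set.seed(1)
  p0 <- 0.3; fst <- 0.05
  draws <- rbeta(1e5, p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
  expect_equal(mean(draws), p0, tolerance = 0.01)
  expect_equal(var(draws), fst * p0 * (1 - p0), tolerance = 0.05)
  # the simulator's population frequencies follow the same law: fix the
  # ancestral frequency by a degenerate maf law and inspect frequencies
  m <- two_pop_model(0.05, n_per_pop = 500, n_variants = 2e4, nf = 2000,
                     ancestral_maf = c(0.3, 0.3))
  panel <- sample_genotype_panel(m, 11)
  freq_a <- colMeans(panel$dosages[panel$samples$pop == "A", ]) / 2
  # the founder pool adds ~p(1-p)/nf and the 2n sampled haplotypes add
  # ~p(1-p)/(2n) around the Beta-law variance F*p0*(1-p0)
  expect_equal(var(freq_a),
               0.3 * 0.7 * (0.05 + 1 / 2000 + 1 / 1000),
               tolerance = 0.05)
})

test_that("panel simulation is deterministic and honors the layout", {
  m <- agvp_population_model(n_variants = 600, n_chrom = 3)
  p1 <- sample_genotype_panel(m, 5)
  p2 <- sample_genotype_panel(m, 5)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$variants, p2$variants)
  expect_equal(nrow(p1$dosages), 589 + 517 + 186)
  expect_equal(as.vector(table(p1$samples$pop)[c("East", "West",
                                                 "South")]),
               c(589L, 517L, 186L))
  expect_equal(length(unique(p1$variants$chrom)), 3)
  expect_true(all(p1$dosages %in% 0:2))
  # positions strictly increasing within chromosome
  for (ch in unique(p1$variants$chrom))
    expect_false(is.unsorted(p1$variants$pos[p1$variants$chrom == ch],
                             strictly = TRUE))
  p3 <- sample_genotype_panel(m, 6)
  expect_false(identical(p1$dosages, p3$dosages))
})

test_that("model validation rejects bad drift and sizes", {
  expect_error(population_model("A", c(A = 0), c(A = 10)), "strictly")
  expect_error(population_model("A", c(A = 1), c(A = 10)), "strictly")
  expect_error(population_model("A", c(A = NaN), c(A = 10)), "strictly")
  expect_error(population_model("A", c(A = 0.1), c(A = 0)), "sizes")
  expect_error(population_model("A", c(A = 0.1), c(A = 5),
                                n_founder_haplotypes = 1), "founder")
})

test_that("Hudson F_ST is ~0 without drift and matches hand values", {
  # negligible drift, many variants
  m <- two_pop_model(1e-6, n_per_pop = 150, n_variants = 10000, nf = 4000)
  panel <- sample_genotype_panel(m, 21)
  expect_lt(abs(hudson_fst(panel, "A", "B")$fst), 0.005)

  # hand evaluation at p1 = 0.2, p2 = 0.8: (p1-p2)^2 / (p1(1-p2)+p2(1-p1))
  # = 0.36/0.68 at infinite n; build exact frequencies with 500 samples
  n <- 500
  dA <- c(rep(1, 200), rep(0, 300))              # freq 0.2
  dB <- c(rep(2, 350), rep(1, 100), rep(0, 50))  # freq 0.8
  D <- cbind(c(dA, dB))
  panel2 <- genotype_panel(
    D, data.frame(chrom = 1L, pos = 1000L, id = "v1", ref = "A",
                  alt = "C"),
    data.frame(fid = "f", iid = sprintf("s%03d", 1:(2 * n)),
               pop = rep(c("A", "B"), each = n)))
  est <- hudson_fst(panel2, "A", "B")
  expect_equal(unname(est$per_variant[1]), 0.36 / 0.68, tolerance = 0.01)

  # identical frequencies in both populations -> ~0
  panel3 <- genotype_panel(
    cbind(rep(c(0, 1, 2, 1), 50)),
    data.frame(chrom = 1L, pos = 1L, id = "v1", ref = "A", alt = "C"),
    data.frame(fid = "f", iid = sprintf("s%03d", 1:200),
               pop = rep(c("A", "B"), 50)))
  expect_lt(abs(hudson_fst(panel3, "A", "B")$fst), 0.01)

  expect_error(hudson_fst(panel2, "A", "missing"), "2 samples")
  mono <- toy_panel(matrix(2, 10, 3), pop = rep(c("A", "B"), 5))
  expect_error(hudson_fst(mono, "A", "B"), "monomorphic")
})

test_that("founder-haplotype pools create within-block but not cross-block LD", {
  m <- population_model("A", c(A = 0.01), c(A = 300),
                        n_founder_haplotypes = 20,
                        block_length_bp = 100000, n_chrom = 2,
                        variants_per_chrom = 1000, spacing_bp = 10000)
  panel <- sample_genotype_panel(m, 31)
  v <- panel$variants
  blk <- paste(v$chrom, (v$pos - 1) %/% 100000)
  D <- panel$dosages
  sds <- apply(D, 2, sd)
  ok <- sds > 0
  # adjacent pairs within a block
  adj <- which(blk[-1] == blk[-length(blk)] & ok[-1] & ok[-length(blk)])
  r_within <- mapply(function(a, b) cor(D[, a], D[, b]), adj, adj + 1)
  set.seed(1)
  ii <- sample(which(ok), 10000, replace = TRUE)
  jj <- sample(which(ok), 10000, replace = TRUE)
  far <- blk[ii] != blk[jj]
  r_cross <- mapply(function(a, b) cor(D[, a], D[, b]), ii[far], jj[far])
  expect_gt(mean(r_within^2), mean(r_cross^2))
  expect_lt(abs(mean(r_cross)), 0.01)
})

test_that("genotype frequencies are Hardy-Weinberg for large founder pools", {
  m <- population_model("A", c(A = 0.02), c(A = 2000),
                        n_founder_haplotypes = 4000, n_chrom = 1,
                        variants_per_chrom = 300)
  panel <- sample_genotype_panel(m, 41)
  D <- panel$dosages
  p <- colMeans(D) / 2
  het_obs <- colMeans(D == 1)
  het_exp <- 2 * p * (1 - p)
  # binomial sampling error at n=2000 is ~0.011; mean deviation ~ 0
  expect_lt(max(abs(het_obs - het_exp)), 0.05)
  expect_lt(abs(mean(het_obs - het_exp)), 0.005)
})

test_that("hierarchy groups make member populations more similar", {
  m <- population_model(
    c("A", "B", "C"), fst = c(A = 0.005, B = 0.005, C = 0.005),
    sample_sizes = c(A = 150, B = 150, C = 150),
    n_founder_haplotypes = 2000, n_chrom = 5, variants_per_chrom = 4000,
    hierarchy = list(list(members = c("A", "B"), fst = 0.005)))
  panel <- sample_genotype_panel(m, 51)
  fab <- hudson_fst(panel, "A", "B")$fst
  fac <- hudson_fst(panel, "A", "C")$fst
  expect_lt(fab, fac)
})

test_that("filter_variants applies MAF and missingness thresholds", {
  # MAFs 0.001, 0.04, 0.05, 0.2, 0.5 built from 500 samples
  n <- 500
  make_col <- function(maf) c(rep(1, round(2 * n * maf)),
                              rep(0, n - round(2 * n * maf)))
  D <- cbind(c(1, rep(0, n - 1)),  # maf 0.001
             make_col(0.04), make_col(0.05), make_col(0.2),
             make_col(0.5))
  panel <- toy_panel(D)
  kept <- filter_variants(panel, maf_min = 0.05, missing_max = 1)
  expect_equal(ncol(kept$dosages), 3)
  expect_equal(attr(kept, "n_removed"), 2)
  # identity case
  ident <- filter_variants(panel, maf_min = 0, missing_max = 1)
  expect_equal(ncol(ident$dosages), ncol(panel$dosages))
  # missingness filter
  D2 <- matrix(rep(c(0, 1, 2, 1), 25), 20, 5)
  D2[1:5, 2] <- NA  # 25% missing
  p2 <- toy_panel(D2)
  kept2 <- filter_variants(p2, maf_min = 0, missing_max = 0.05)
  expect_equal(ncol(kept2$dosages), 4)
})

test_that("cohort splits are disjoint, sized, and seed-deterministic", {
  m <- agvp_population_model(n_variants = 200, n_chrom = 2)
  panel <- sample_genotype_panel(m, 61)
  sp <- split_cohorts(panel, agvp_split_scheme(), 7)
  expect_named(sp$discovery, c("East", "West"), ignore.order = TRUE)
  expect_equal(nrow(sp$discovery$East$dosages), 403)
  expect_equal(nrow(sp$discovery$West$dosages), 331)
  expect_equal(vapply(sp$target, function(p) nrow(p$dosages), 0L),
               c(East = 186L, South = 186L, West = 186L)[names(sp$target)])
  for (pop in names(sp$discovery))
    expect_length(intersect(sp$discovery[[pop]]$samples$iid,
                            sp$target[[pop]]$samples$iid), 0)
  sp2 <- split_cohorts(panel, agvp_split_scheme(), 7)
  expect_identical(sp$discovery$East$samples$iid,
                   sp2$discovery$East$samples$iid)
  sp3 <- split_cohorts(panel, agvp_split_scheme(), 8)
  expect_false(identical(sp$target$East$samples$iid,
                         sp3$target$East$samples$iid))

  # pooled holdout scheme
  m4 <- population_model(c("P", "Q"), c(P = 0.01, Q = 0.01),
                         c(P = 40, Q = 30), n_chrom = 1,
                         variants_per_chrom = 50)
  p4 <- sample_genotype_panel(m4, 62)
  sp4 <- split_cohorts(p4, awigen_split_scheme("Q", target_n = 10), 9)
  expect_equal(nrow(sp4$target$Q$dosages), 10)
  expect_equal(nrow(sp4$discovery$pooled$dosages), 60)
  expect_true(all(sp4$target$Q$samples$pop == "Q"))
  expect_error(split_cohorts(p4, awigen_split_scheme("Q", target_n = 31),
                             9), "requested")
})
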