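test_that("greedy clumping follows the p-ordered absorb rule", {
  # A (p=1e-10) absorbs B (high r2, 100 kb) but not C (low r2, 200 kb)
  set.seed(1)
  n <- 60
  a <- rbinom(n, 2, 0.4)
  b <- a; b[1:4] <- rbinom(4, 2, 0.4)          # strongly correlated with a
  cc <- rbinom(n, 2, 0.4)                      # independent
  stopifnot(cor(a, b)^2 > 0.3, cor(a, cc)^2 < 0.1)
  panel <- toy_panel(cbind(a, b, cc), pos = c(1e6, 1.1e6, 1.2e6))
  stats <- toy_stats(panel, beta = c(1, 1, 1), p = c(1e-10, 1e-8, 1e-6))
  cl <- clump(stats, panel, r2_max = 0.1, window_kb = 500)
  expect_setequal(cl$retained$id, c("v001", "v003"))
  expect_equal(cl$absorbed$v001, "v002")
  # perfectly correlated but 600 kb apart -> both retained
  panel2 <- toy_panel(cbind(a, a), pos = c(1e6, 1.6e6 + 1))
  stats2 <- toy_stats(panel2, p = c(1e-5, 1e-4))
  cl2 <- clump(stats2, panel2, r2_max = 0.1, window_kb = 500)
  expect_equal(nrow(cl2$retained), 2)
  # single SNP
  cl3 <- clump(toy_stats(toy_panel(cbind(a)), p = 0.5),
               toy_panel(cbind(a)))
  expect_equal(cl3$retained$id, "v001")
  expect_error(clump(stats[0, ], panel), "empty")
})

test_that("clumping matches an independent brute-force oracle", {
  for (s in 1:200) {
    inst <- random_clump_instance(s)
    cl <- clump(inst$stats, inst$panel, r2_max = 0.1537, window_kb = 300)
    oracle <- brute_clump(inst$stats, inst$panel, r2_max = 0.1537,
                          window_kb = 300)
    expect_identical(sort(cl$retained$id), sort(oracle))
  }
})

test_that("retained sets are valid and partition the input", {
  inst <- random_clump_instance(999, n = 40, m = 80)
  cl <- clump(inst$stats, inst$panel, r2_max = 0.1, window_kb = 200,
              p_max = 0.5)
  ret <- cl$retained
  D <- inst$panel$dosages[, match(ret$id, inst$panel$variants$id)]
  # no retained pair violates (r2 <= cutoff OR distance > window)
  if (nrow(ret) > 1) {
    for (i in seq_len(nrow(ret) - 1)) {
      for (j in seq(i + 1, nrow(ret))) {
        if (ret$chrom[i] != ret$chrom[j]) next
        if (abs(ret$pos[i] - ret$pos[j]) > 200000) next
        expect_lte(cor(D[, i], D[, j])^2, 0.1)
      }
    }
  }
  # retained + absorbed + filtered = input
  expect_setequal(c(ret$id, unlist(cl$absorbed), cl$filtered),
                  inst$stats$ID)
})

test_that("clumping at a strict p_max equals thresholding the full clump", {
  inst <- random_clump_instance(77, n = 40, m = 120)
  full <- clump(inst$stats, inst$panel, r2_max = 0.1537, window_kb = 300)
  for (t in c(0.01, 0.1, 0.5)) {
    strict <- clump(inst$stats, inst$panel, r2_max = 0.1537, window_kb = 300,
                    p_max = t)
    expect_identical(sort(strict$retained$id),
                     sort(full$retained$id[full$retained$p <= t]))
  }
})

test_that("PRS scoring reproduces hand arithmetic and is linear", {
  panel <- toy_panel(matrix(c(0, 1, 2, 1), 2, 2), pos = c(1000, 2000))
  stats <- toy_stats(panel, beta = c(0.5, -0.25), p = c(0.01, 0.02))
  prof <- prs_score(panel, stats, thresholds = 0.05)
  expect_equal(unname(prof$scores[, 1]), c(-0.5, 0.25))
  expect_equal(prof$n_snps, 2L)
  # all-zero betas
  prof0 <- prs_score(panel, toy_stats(panel, beta = c(0, 0),
                                      p = c(0.01, 0.02)))
  expect_true(all(prof0$scores == 0))
  # linearity over disjoint variant sets
  s1 <- toy_stats(panel, beta = c(0.5, 0), p = c(0.01, 0.02))
  s2 <- toy_stats(panel, beta = c(0, -0.25), p = c(0.01, 0.02))
  p_all <- prs_score(panel, stats, thresholds = 1)
  p1 <- prs_score(panel, s1, thresholds = 1)
  p2 <- prs_score(panel, s2, thresholds = 1)
  expect_equal(p_all$scores, p1$scores + p2$scores, tolerance = 1e-12)
})

test_that("threshold counts are nested and defaults match the standard 10", {
  expect_equal(default_thresholds(),
               c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.2, 0.5, 1))
  set.seed(2)
  D <- matrix(rbinom(40 * 30, 2, 0.3), 40, 30)
  panel <- toy_panel(D)
  stats <- toy_stats(panel, beta = rnorm(30), p = runif(30)^3)
  prof <- prs_score(panel, stats)
  expect_equal(prof$thresholds, default_thresholds())
  expect_false(is.unsorted(prof$n_snps))
  long <- as.data.frame(prof)
  expect_equal(nrow(long), 40 * 10)
  expect_named(long, c("FID", "IID", "THRESHOLD", "PRS", "N_SNPS"))
})

test_that("harmonization flips swapped alleles and drops bad ones", {
  panel <- toy_panel(matrix(c(0, 1, 2, 1, 1, 0, 2, 2, 0, 1, 1, 1), 4, 3),
                     ref = c("G", "A", "A"), alt = c("T", "C", "G"))
  stats <- toy_stats(panel, beta = c(0.3, 0.2, 0.1), p = rep(0.01, 3))
  # v1: stats report A1=G (panel ref), A2=T (panel alt) -> swap/sign-flip
  stats$A1[1] <- "G"; stats$A2[1] <- "T"
  stats$A1_FREQ[1] <- 1 - stats$A1_FREQ[1]
  h <- harmonize_sumstats(stats, panel)
  expect_equal(unname(h$report[c("match", "swap")]), c(2L, 1L))
  expect_equal(h$stats$BETA[h$stats$ID == "v001"], -0.3)
  expect_equal(h$stats$A1[h$stats$ID == "v001"], "T")
  # identical coding is untouched
  expect_equal(h$stats$BETA[h$stats$ID == "v002"], 0.2)
  # ambiguous A/T pair dropped by default, kept on request
  stats2 <- toy_stats(panel, beta = c(1, 1, 1), p = rep(0.01, 3))
  stats2$A1[1] <- "T"; stats2$A2[1] <- "A"  # panel v1 is G/T -> mismatch
  h2 <- harmonize_sumstats(stats2, panel)
  expect_equal(unname(h2$report["mismatch_dropped"]), 1L)
  panel_at <- toy_panel(cbind(c(0, 1, 2, 1)), ref = "A", alt = "T")
  st_at <- toy_stats(panel_at, beta = 1, p = 0.01)
  expect_equal(unname(harmonize_sumstats(st_at, panel_at)$report[
    "ambiguous_dropped"]), 1L)
  expect_equal(nrow(harmonize_sumstats(st_at, panel_at,
                                       drop_ambiguous = FALSE)$stats), 1)
  # absent variants dropped with a count
  st_ab <- st_at; st_ab$ID <- "nope"
  expect_equal(unname(harmonize_sumstats(st_ab, panel_at)$report[
    "absent_dropped"]), 1L)
})

test_that("missing dosages are imputed from the effect-allele frequency", {
  D <- cbind(c(NA, 0, 2, 1))
  panel <- toy_panel(D)
  stats <- toy_stats(panel, beta = 1, p = 0.01)
  stats$A1_FREQ <- 0.25
  prof <- prs_score(panel, stats, thresholds = 1)
  expect_equal(unname(prof$scores[1, 1]), 2 * 0.25)
  prof2 <- prs_score(panel, stats, thresholds = 1, impute_missing = FALSE)
  expect_equal(unname(prof2$scores[1, 1]), 0)
})

test_that("LD reference panels are weighted and anchored", {
  m <- two_pop_model(0.02, n_per_pop = 30, n_variants = 100)
  panel <- sample_genotype_panel(m, 3)
  pa <- subset_panel(panel, samples = panel$samples$pop == "A")
  pb <- subset_panel(panel, samples = panel$samples$pop == "B")
  # single panel, weight 1 -> identity
  expect_identical(build_ld_reference(list(pa), 1)$dosages, pa$dosages)
  # anchored proportions: anchor 20 samples at weight 0.7, other 0.3
  pa20 <- subset_panel(pa, samples = 1:20)
  ref <- build_ld_reference(list(pa20, pb), c(0.7, 0.3), anchor = 1,
                            seed = 4)
  expect_equal(nrow(ref$dosages), 20 + round(20 * 0.3 / 0.7))
  expect_equal(sum(ref$samples$pop == "A"), 20)
  # the worked proportion from the construction rule: 503 at 0.7 vs 0.3
  expect_equal(as.integer(round(503 * 0.3 / 0.7)), 216L)
  # oversubscription errors
  expect_error(build_ld_reference(list(pa20, subset_panel(pb, samples = 1:3)),
                                  c(0.5, 0.5), anchor = 1, seed = 1),
               "more samples")
})
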