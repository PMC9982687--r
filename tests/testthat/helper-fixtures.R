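# Small deterministic fixtures and independent oracles used across tests.

# A tiny panel with fully specified dosages.
toy_panel <- function(dosages, chrom = NULL, pos = NULL, pop = "P",
                      ref = NULL, alt = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages); n <- nrow(dosages)
  chrom <- chrom %||% rep(1L, m)
  pos <- pos %||% unlist(lapply(split(seq_len(m), chrom),
                                function(ix) seq_along(ix) * 1000L))
  pop <- rep_len(pop, n)
  genotype_panel(
    dosages,
    data.frame(chrom = chrom, pos = pos, id = sprintf("v%03d", seq_len(m)),
               ref = ref %||% rep("A", m), alt = alt %||% rep("C", m),
               stringsAsFactors = FALSE),
    data.frame(fid = pop, iid = sprintf("s%03d", seq_len(n)), pop = pop,
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Association table for a panel with supplied betas / p values.
toy_stats <- function(panel, beta = NULL, p = NULL, se = NULL) {
  m <- nrow(panel$variants)
  af <- colMeans(panel$dosages, na.rm = TRUE) / 2
  data.frame(CHR = panel$variants$chrom, POS = panel$variants$pos,
             ID = panel$variants$id, A1 = panel$variants$alt,
             A2 = panel$variants$ref, A1_FREQ = unname(af),
             BETA = beta %||% rep(0, m), SE = se %||% rep(1, m),
             T_STAT = 0, P = p %||% rep(1, m), N = nrow(panel$dosages),
             stringsAsFactors = FALSE)
}

# Independent brute-force greedy clumping oracle (direct transcription of
# the algorithm definition; no shared code with clump()).
brute_clump <- function(stats, panel, r2_max, window_kb, p_max = 1) {
  keep <- !is.na(stats$P) & stats$P <= p_max &
    stats$ID %in% panel$variants$id
  sub <- stats[keep, ]
  sub <- sub[order(sub$P, sub$CHR, sub$POS), ]
  D <- panel$dosages[, match(sub$ID, panel$variants$id), drop = FALSE]
  if (anyNA(D)) {
    for (j in seq_len(ncol(D)))
      D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
  }
  alive <- rep(TRUE, nrow(sub))
  retained <- character()
  for (j in seq_len(nrow(sub))) {
    if (!alive[j]) next
    retained <- c(retained, sub$ID[j])
    for (k in seq_len(nrow(sub))) {
      if (!alive[k] || k == j) next
      if (sub$CHR[k] != sub$CHR[j]) next
      if (abs(sub$POS[k] - sub$POS[j]) > window_kb * 1000) next
      r <- suppressWarnings(cor(D[, j], D[, k]))
      if (!is.na(r) && r^2 > r2_max) alive[k] <- FALSE
    }
  }
  retained
}

# Random clumping instance on a small panel.
random_clump_instance <- function(seed, n = 25, m = 50, n_chrom = 2) {
  set.seed(seed)
  chrom <- sort(sample(seq_len(n_chrom), m, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(2e6, length(ix)))))
  # correlated-ish dosages: mixture of fresh and copied columns
  D <- matrix(rbinom(n * m, 2, 0.4), n, m)
  for (j in seq(2, m, by = 3)) {
    src <- j - 1
    flip <- sample(n, max(1, n %/% 8))
    D[, j] <- D[, src]
    D[flip, j] <- rbinom(length(flip), 2, 0.4)
  }
  panel <- toy_panel(D, chrom = chrom, pos = pos)
  stats <- toy_stats(panel, beta = rnorm(m), p = runif(m)^2)
  list(panel = panel, stats = stats)
}

# Two-population Balding-Nichols model helper.
two_pop_model <- function(fst, n_per_pop, n_variants, nf = 20,
                          variants_per_chrom = NULL, n_chrom = 5, ...) {
  vpc <- variants_per_chrom %||% ceiling(n_variants / n_chrom)
  population_model(labels = c("A", "B"), fst = c(A = fst, B = fst),
                   sample_sizes = c(A = n_per_pop, B = n_per_pop),
                   n_founder_haplotypes = nf, n_chrom = n_chrom,
                   variants_per_chrom = vpc, ...)
}
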