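#' Multi-population Balding-Nichols model with founder-haplotype LD
#'
#' Describes a set of populations that drift independently from a shared
#' ancestral allele-frequency pool. Per-population allele frequencies are
#' drawn from the Balding-Nichols Beta law
#' `p_k ~ Beta(p0 (1-F)/F, (1-p0)(1-F)/F)`, where `F` measures divergence
#' from the ancestor. Linkage disequilibrium is induced by drawing a finite
#' pool of founder haplotypes per LD block: all individuals of a population
#' inherit block haplotypes from that pool, which creates within-block
#' correlation that decays to zero across blocks.
#'
#' Hierarchical (non-star) topologies are expressed with `hierarchy`: each
#' element names a group of populations and a shared drift `fst`; an
#' intermediate ancestral frequency is drawn for the group, and the member
#' populations then drift from it with their own `fst` values.
#'
#' @param labels population names.
#' @param fst named (or positionally matched) per-population drift F,
#'   each strictly in (0, 1).
#' @param sample_sizes named per-population sample counts (>= 1).
#' @param ancestral_maf range of the uniform ancestral allele-frequency law.
#' @param n_founder_haplotypes founder-haplotype pool size per population
#'   per block (>= 2); smaller pools give stronger LD.
#' @param block_length_bp physical length of an LD block.
#' @param n_chrom number of chromosomes.
#' @param variants_per_chrom variants per chromosome, uniformly spaced.
#' @param spacing_bp base-pair spacing between adjacent variants.
#' @param hierarchy optional list of `list(members=, fst=)` group
#'   specifications.
#' @return an object of class `population_model`.
#' @export
population_model <- function(labels, fst, sample_sizes,
                             ancestral_maf = c(0.05, 0.5),
                             n_founder_haplotypes = 20,
                             block_length_bp = 100000,
                             n_chrom = 10,
                             variants_per_chrom = 1000,
                             spacing_bp = 10000,
                             hierarchy = NULL) {
  fst <- if (is.null(names(fst))) stats::setNames(fst, labels) else fst
  sample_sizes <- if (is.null(names(sample_sizes)))
    stats::setNames(sample_sizes, labels) else sample_sizes
  stopifnot(all(labels %in% names(fst)),
            all(labels %in% names(sample_sizes)))
  if (any(!is.finite(fst[labels])) || any(fst[labels] <= 0) ||
      any(fst[labels] >= 1))
    stop("all F values must be finite and strictly in (0, 1)")
  if (any(sample_sizes[labels] < 1)) stop("sample sizes must be >= 1")
  if (n_founder_haplotypes < 2) stop("need at least 2 founder haplotypes")
  if (n_chrom < 1 || variants_per_chrom < 1) stop("zero variants requested")
  if (!is.null(hierarchy)) {
    for (g in hierarchy) {
      stopifnot(all(g$members %in% labels), g$fst > 0, g$fst < 1)
    }
    mem <- unlist(lapply(hierarchy, `[[`, "members"))
    if (anyDuplicated(mem))
      stop("a population may belong to at most one hierarchy group")
  }
  structure(list(labels = labels, fst = fst[labels],
                 sample_sizes = sample_sizes[labels],
                 ancestral_maf = ancestral_maf,
                 n_founder_haplotypes = as.integer(n_founder_haplotypes),
                 block_length_bp = as.integer(block_length_bp),
                 n_chrom = as.integer(n_chrom),
                 variants_per_chrom = as.integer(variants_per_chrom),
                 spacing_bp = as.integer(spacing_bp),
                 hierarchy = hierarchy),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat(sprintf("population_model: %d populations, %d variants\n",
              length(x$labels), x$n_chrom * x$variants_per_chrom))
  for (l in x$labels)
    cat(sprintf("  %s: n=%d, F=%.4g\n", l, x$sample_sizes[[l]],
                x$fst[[l]]))
  invisible(x)
}

# Balding-Nichols draw of population frequencies around ancestral p0.
bn_draw <- function(p0, fst) {
  rbeta(length(p0), p0 * (1 - fst) / fst, (1 - p0) * (1 - fst) / fst)
}

#' Simulate a structured genotype panel
#'
#' For each population, per-variant allele frequencies are drawn from the
#' Balding-Nichols law around the ancestral frequency. A pool of founder
#' haplotypes is materialized per population, and every individual draws
#' two founder indices per LD block uniformly with replacement; the genotype
#' is the haplotype sum. Deterministic given `seed`.
#'
#' @param model a `population_model`.
#' @param seed integer seed.
#' @return a `genotype_panel` with integer dosages and no missing values.
#' @export
sample_genotype_panel <- function(model, seed) {
  stopifnot(inherits(model, "population_model"))
  with_seed(seed, {
    m_per <- model$variants_per_chrom
    M <- model$n_chrom * m_per
    chrom <- rep(seq_len(model$n_chrom), each = m_per)
    pos <- rep(model$spacing_bp * seq_len(m_per), times = model$n_chrom)
    bases <- c("A", "C", "G", "T")
    ref_i <- sample.int(4L, M, replace = TRUE)
    alt_i <- (ref_i - 1L + sample.int(3L, M, replace = TRUE)) %% 4L + 1L
    variants <- data.frame(chrom = chrom, pos = pos,
                           id = sprintf("snp%06d", seq_len(M)),
                           ref = bases[ref_i], alt = bases[alt_i],
                           stringsAsFactors = FALSE)
    # block index per variant (blocks never span chromosomes)
    block <- (chrom - 1) * (ceiling(max(pos) / model$block_length_bp) + 1) +
      (pos - 1) %/% model$block_length_bp
    block <- match(block, unique(block))
    n_blocks <- max(block)

    p0 <- runif(M, model$ancestral_maf[1], model$ancestral_maf[2])
    # intermediate ancestral frequencies for hierarchy groups
    base_freq <- lapply(model$labels, function(l) p0)
    names(base_freq) <- model$labels
    for (g in model$hierarchy %||% list()) {
      pg <- bn_draw(p0, g$fst)
      for (l in g$members) base_freq[[l]] <- pg
    }

    nf <- model$n_founder_haplotypes
    dosage_blocks <- vector("list", length(model$labels))
    names(dosage_blocks) <- model$labels
    for (l in model$labels) {
      pk <- bn_draw(base_freq[[l]], model$fst[[l]])
      # founder haplotypes: nf x M Bernoulli(pk); pools at different blocks
      # are independent, so one genome-wide founder index set per block is
      # equivalent to independent per-block pools
      H <- matrix(rbinom(nf * M, 1L, rep(pk, each = nf)), nrow = nf)
      n <- model$sample_sizes[[l]]
      a1 <- matrix(sample.int(nf, n * n_blocks, replace = TRUE), nrow = n)
      a2 <- matrix(sample.int(nf, n * n_blocks, replace = TRUE), nrow = n)
      # linear gather: element (i, j) of the genotype matrix is
      # H[a(i, block(j)), j]; column offsets into H are (j-1)*nf
      off <- rep((seq_len(M) - 1L) * nf, each = n)
      G <- H[a1[, block, drop = FALSE] + off] +
        H[a2[, block, drop = FALSE] + off]
      dim(G) <- c(n, M)
      dosage_blocks[[l]] <- G
      rm(H, a1, a2, off)
    }
    dosages <- do.call(rbind, dosage_blocks)
    n_tot <- nrow(dosages)
    samples <- data.frame(
      fid = rep(model$labels, times = model$sample_sizes),
      iid = sprintf("%s_%04d",
                    rep(model$labels, times = model$sample_sizes),
                    unlist(lapply(model$sample_sizes, seq_len))),
      pop = rep(model$labels, times = model$sample_sizes),
      stringsAsFactors = FALSE)
    new_genotype_panel(dosages, variants, samples)
  })
}

#' Hudson F_ST estimator
#'
#' Per-variant Hudson estimator
#' `[(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)] / [p1(1-p2) + p2(1-p1)]`
#' with `n` the number of observed alleles, and the genome-wide
#' ratio-of-averages estimate (summed numerators over summed denominators).
#'
#' @param panel a `genotype_panel`.
#' @param popA,popB population labels present in the panel.
#' @return list with `per_variant` (numeric vector, NA where the
#'   denominator is zero) and `fst` (genome-wide ratio of averages).
#' @export
hudson_fst <- function(panel, popA, popB) {
  maskA <- panel$samples$pop == popA
  maskB <- panel$samples$pop == popB
  if (sum(maskA) < 2 || sum(maskB) < 2)
    stop("both populations must be present with >= 2 samples")
  DA <- panel$dosages[maskA, , drop = FALSE]
  DB <- panel$dosages[maskB, , drop = FALSE]
  nA <- 2 * colSums(!is.na(DA))
  nB <- 2 * colSums(!is.na(DB))
  p1 <- colMeans(DA, na.rm = TRUE) / 2
  p2 <- colMeans(DB, na.rm = TRUE) / 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (nA - 1) - p2 * (1 - p2) / (nB - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- is.finite(num) & is.finite(den)
  if (!any(ok & den > 0))
    stop("F_ST undefined: all variants monomorphic in both populations")
  per_variant <- ifelse(ok & den > 0, num / den, NA_real_)
  list(per_variant = per_variant,
       fst = sum(num[ok & den > 0]) / sum(den[ok & den > 0]))
}

#' Cohort split schemes
#'
#' `agvp_split_scheme()` reproduces the three-region design: a fixed-size
#' target cohort per region (default 186) and per-region discovery cohorts
#' made of all remaining East and West samples (no southern discovery).
#' `awigen_split_scheme()` holds out a fixed number of samples (default
#' 500) from one named group as the target and pools every other sample
#' into a single discovery cohort.
#'
#' @param target_n target-cohort size per population.
#' @param discovery_pops populations that contribute discovery cohorts.
#' @param holdout population to hold out (AWI-Gen scheme).
#' @return a split-scheme specification for [split_cohorts()].
#' @export
agvp_split_scheme <- function(target_n = 186,
                              discovery_pops = c("East", "West")) {
  structure(list(type = "per_pop", target_n = target_n,
                 discovery_pops = discovery_pops),
            class = "split_scheme")
}

#' @rdname agvp_split_scheme
#' @export
awigen_split_scheme <- function(holdout, target_n = 500) {
  structure(list(type = "pooled_holdout", holdout = holdout,
                 target_n = target_n),
            class = "split_scheme")
}

#' Split a panel into disjoint discovery and target cohorts
#'
#' Sample partitions are random but fully determined by `seed`; discovery
#' and target sets are disjoint.
#'
#' @param panel a `genotype_panel`.
#' @param scheme a `split_scheme` from [agvp_split_scheme()] or
#'   [awigen_split_scheme()].
#' @param seed integer seed.
#' @return list with named lists `discovery` and `target` of
#'   `genotype_panel` objects.
#' @export
split_cohorts <- function(panel, scheme, seed) {
  stopifnot(inherits(scheme, "split_scheme"))
  pops <- panel$samples$pop
  with_seed(seed, {
    if (scheme$type == "per_pop") {
      target <- list(); discovery <- list()
      for (l in unique(pops)) {
        idx <- which(pops == l)
        if (length(idx) < scheme$target_n)
          stop(sprintf("population %s has %d samples, %d requested",
                       l, length(idx), scheme$target_n))
        t_idx <- sort(sample(idx, scheme$target_n))
        target[[l]] <- subset_panel(panel, samples = t_idx)
        if (l %in% scheme$discovery_pops) {
          d_idx <- setdiff(idx, t_idx)
          discovery[[l]] <- subset_panel(panel, samples = d_idx)
        }
      }
      list(discovery = discovery, target = target)
    } else {
      idx <- which(pops == scheme$holdout)
      if (length(idx) < scheme$target_n)
        stop(sprintf("population %s has %d samples, %d requested",
                     scheme$holdout, length(idx), scheme$target_n))
      t_idx <- sort(sample(idx, scheme$target_n))
      d_idx <- setdiff(seq_along(pops), t_idx)
      list(discovery = list(pooled = subset_panel(panel, samples = d_idx)),
           target = stats::setNames(
             list(subset_panel(panel, samples = t_idx)), scheme$holdout))
    }
  })
}

#' Ready-made population models for the two study designs
#'
#' `agvp_population_model()` is a three-region panel (East n=589, West
#' n=517, South n=186) with small pairwise divergence.
#' `awigen_population_model()` is a four-group panel (n = 1703, 1661,
#' 1701, 4455) with smaller divergence. Realized pairwise Hudson F_ST
#' between two populations is approximately `(F_a + F_b)/2 + 1/n_founders`
#' — the finite founder-haplotype pool behaves as an extra bottleneck
#' generation shared by all variants of a population. The defaults
#' (per-population F of 0.006/0.006/0.012 for the three regions,
#' 0.004/0.004/0.004/0.008 for the four groups, 150 founder haplotypes)
#' are calibrated so realized pairwise F_ST lands in the 0.01-0.02 band
#' typical of within-continent African divergence; both knobs are
#' configurable.
#'
#' @param n_variants total variant count (uniformly divided over `n_chrom`
#'   chromosomes).
#' @param fst named per-population drift values.
#' @param n_chrom number of chromosomes.
#' @param ... passed through to [population_model()].
#' @return a `population_model`.
#' @export
agvp_population_model <- function(n_variants = 50000,
                                  fst = c(East = 0.006, West = 0.006,
                                          South = 0.012),
                                  n_chrom = 10,
                                  n_founder_haplotypes = 150, ...) {
  population_model(labels = c("East", "West", "South"), fst = fst,
                   sample_sizes = c(East = 589, West = 517, South = 186),
                   n_chrom = n_chrom,
                   variants_per_chrom = ceiling(n_variants / n_chrom),
                   n_founder_haplotypes = n_founder_haplotypes, ...)
}

#' @rdname agvp_population_model
#' @export
awigen_population_model <- function(n_variants = 5000,
                                    fst = c(BurkinaFaso = 0.004,
                                            Ghana = 0.004, Kenya = 0.004,
                                            SouthAfrica = 0.008),
                                    n_chrom = 10,
                                    n_founder_haplotypes = 150, ...) {
  population_model(labels = names(fst), fst = fst,
                   sample_sizes = c(BurkinaFaso = 1703, Ghana = 1661,
                                    Kenya = 1701, SouthAfrica = 4455),
                   n_chrom = n_chrom,
                   variants_per_chrom = ceiling(n_variants / n_chrom),
                   n_founder_haplotypes = n_founder_haplotypes, ...)
}
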