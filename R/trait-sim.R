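#' Trait architectures
#'
#' A trait architecture is the set of causal variants and their raw
#' per-allele effects, plus the heritability weight used when the phenotype
#' is assembled. `draw_sparse_architecture()` picks `n_causal` variants
#' uniformly at random (above a MAF floor) with i.i.d. Normal(0, 1)
#' effects — the design used for the smaller three-region panel at
#' n_causal in \{5, 20, 100, 2000, 10000, 50000\}.
#' `draw_maf_coupled_architecture()` draws every eligible variant (or a
#' proportion) as causal with effect variance coupled to allele frequency,
#' `beta_j ~ Normal(0, [2 p_j (1-p_j)]^alpha)` — the infinitesimal design
#' with the frequency-dependence exponent `alpha` (default -0.38, the
#' published point estimate for such coupling). The scale of the effects is
#' immaterial because the genetic score is standardized downstream.
#'
#' @param panel a `genotype_panel`.
#' @param n_causal number of causal variants (sparse mode).
#' @param h2 heritability weight in \[0, 1\].
#' @param seed integer seed.
#' @param maf_min MAF floor for causal eligibility.
#' @param alpha MAF-coupling exponent.
#' @param prop_causal proportion of eligible variants that are causal.
#' @return an object of class `trait_architecture` with fields `mode`,
#'   `causal_ids`, `effects`, `alpha`, `h2`.
#' @export
draw_sparse_architecture <- function(panel, n_causal, h2, seed,
                                     maf_min = 0.01) {
  stopifnot(h2 >= 0, h2 <= 1)
  if (n_causal < 1) stop("n_causal must be >= 1")
  af <- allele_freq(panel)
  eligible <- which(pmin(af, 1 - af) >= maf_min)
  if (n_causal > length(eligible))
    stop(sprintf("n_causal = %d exceeds the %d eligible variants",
                 n_causal, length(eligible)))
  with_seed(seed, {
    causal <- sort(sample(eligible, n_causal))
    effects <- rnorm(n_causal)
    structure(list(mode = "sparse",
                   causal_ids = panel$variants$id[causal],
                   effects = stats::setNames(effects,
                                             panel$variants$id[causal]),
                   alpha = NULL, h2 = h2),
              class = "trait_architecture")
  })
}

#' @rdname draw_sparse_architecture
#' @export
draw_maf_coupled_architecture <- function(panel, h2, alpha = -0.38,
                                          prop_causal = 1, seed) {
  stopifnot(is.finite(alpha), prop_causal > 0, prop_causal <= 1,
            h2 >= 0, h2 <= 1)
  af <- allele_freq(panel)
  eligible <- which(af > 0 & af < 1)  # monomorphic variants excluded
  if (!length(eligible)) stop("no polymorphic variants")
  with_seed(seed, {
    n_causal <- max(1L, round(prop_causal * length(eligible)))
    causal <- sort(sample(eligible, n_causal))
    p <- af[causal]
    sd_j <- (2 * p * (1 - p))^(alpha / 2)
    effects <- rnorm(n_causal, 0, sd_j)
    structure(list(mode = "maf_coupled",
                   causal_ids = panel$variants$id[causal],
                   effects = stats::setNames(effects,
                                             panel$variants$id[causal]),
                   alpha = alpha, h2 = h2),
              class = "trait_architecture")
  })
}

#' Simulate a quantitative phenotype
#'
#' The raw genetic score of individual i is the dosage-weighted sum of the
#' causal effects; it is standardized to mean 0 and SD 1 (population
#' denominator) across all panel samples, giving the true polygenic score
#' G. Environmental noise E is drawn i.i.d. Normal(0, 1), and the phenotype
#' is assembled as the printed-form weighted sum
#' `y = h2 * G + (1 - h2) * E` (`weighting = "literal"`, the default).
#' Under this form the fraction of phenotypic variance that is genetic is
#' `h2^2 / (h2^2 + (1 - h2)^2)` — e.g. 0.941 at h2 = 0.8 — which is what a
#' perfectly estimated PRS can recover. The conventional variance-partition
#' form `y = sqrt(h2) G + sqrt(1 - h2) E` (genetic fraction exactly h2) is
#' available with `weighting = "sqrt"`.
#'
#' @param panel a `genotype_panel` (all samples; standardize before any
#'   cohort split so discovery and target phenotypes share one scale).
#' @param arch a `trait_architecture`.
#' @param seed integer seed for the environmental draw.
#' @param weighting `"literal"` (default) or `"sqrt"`.
#' @return an object of class `simulated_phenotype` with per-sample
#'   `true_score` (G), `environment` (E), `phenotype` (y), and the
#'   `realized_genetic_fraction`.
#' @export
simulate_phenotype <- function(panel, arch, seed,
                               weighting = c("literal", "sqrt")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(arch, "trait_architecture"))
  idx <- match(arch$causal_ids, panel$variants$id)
  if (anyNA(idx)) stop("architecture references variants absent from panel")
  D <- panel$dosages[, idx, drop = FALSE]
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  raw <- unname(drop(D %*% arch$effects))
  G <- standardize_pop(raw)
  h2 <- arch$h2
  with_seed(seed, {
    E <- rnorm(length(G))
    if (weighting == "literal") {
      y <- h2 * G + (1 - h2) * E
      rgf <- h2^2 / (h2^2 + (1 - h2)^2)
    } else {
      y <- sqrt(h2) * G + sqrt(1 - h2) * E
      rgf <- h2
    }
    structure(list(iid = panel$samples$iid, true_score = G,
                   environment = E, phenotype = y, h2 = h2,
                   weighting = weighting,
                   realized_genetic_fraction = rgf),
              class = "simulated_phenotype")
  })
}

#' @export
print.simulated_phenotype <- function(x, ...) {
  cat(sprintf(paste0("simulated_phenotype: n=%d, h2=%.2f (%s weighting), ",
                     "realized genetic fraction %.3f\n"),
              length(x$phenotype), x$h2, x$weighting,
              x$realized_genetic_fraction))
  invisible(x)
}

#' Write / read phenotype and architecture TSVs
#'
#' Phenotype TSV columns: FID, IID, TRUE_SCORE, ENV, PHENO. Architecture
#' sidecar columns: ID, BETA.
#'
#' @param pheno a `simulated_phenotype`.
#' @param panel the panel the phenotype was simulated on (for FIDs).
#' @param arch a `trait_architecture`.
#' @param path output path.
#' @export
write_phenotype <- function(pheno, panel, path) {
  data.table::fwrite(data.frame(FID = panel$samples$fid,
                                IID = pheno$iid,
                                TRUE_SCORE = pheno$true_score,
                                ENV = pheno$environment,
                                PHENO = pheno$phenotype),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotype
#' @export
write_architecture <- function(arch, path) {
  data.table::fwrite(data.frame(ID = arch$causal_ids,
                                BETA = unname(arch$effects)),
                     path, sep = "\t")
  invisible(path)
}
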