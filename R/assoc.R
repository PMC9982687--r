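#' Principal components of a genotype panel
#'
#' Variants are filtered (default MAF > 0.05, missingness < 0.05, the
#' standard pre-PCA filter), mean-imputed, centered at 2p and scaled by
#' sqrt(2p(1-p)). The top-k components of the sample covariance are
#' computed exactly via the smaller-side eigendecomposition when feasible,
#' and otherwise by randomized subspace iteration (deterministic; the
#' global RNG state is untouched). Sign convention: the largest-magnitude
#' loading of each component is positive.
#'
#' @param panel a `genotype_panel`.
#' @param k number of components (default 20, the discovery-GWAS covariate
#'   count).
#' @param maf_min,missing_max pre-PCA variant filters.
#' @param exact_max use the exact decomposition when `min(n, m)` does not
#'   exceed this; larger problems use the randomized solver.
#' @return an object of class `pc_model` with `variants` (metadata of the
#'   variants used), `means`, `scales`, `loadings` (variants x k),
#'   `eigenvalues`, `scores` (samples x k), `k`.
#' @export
compute_pca <- function(panel, k = 20, maf_min = 0.05, missing_max = 0.05,
                        exact_max = 400) {
  stopifnot(k >= 1)
  fp <- filter_variants(panel, maf_min = maf_min, missing_max = missing_max)
  D <- imputed_dosages(fp)
  p <- colMeans(D) / 2
  sc <- sqrt(2 * p * (1 - p))
  keep <- sc > 0
  D <- D[, keep, drop = FALSE]
  Xs <- sweep(sweep(D, 2, 2 * p[keep], "-"), 2, sc[keep], "/")
  n <- nrow(Xs); m <- ncol(Xs)
  if (k > min(n, m) - 1) stop("k exceeds the available rank")
  if (min(n, m) <= exact_max) {
    if (n <= m) {
      ei <- eigen(tcrossprod(Xs), symmetric = TRUE)
      d <- sqrt(pmax(ei$values[seq_len(k)], 0))
      U <- ei$vectors[, seq_len(k), drop = FALSE]
      V <- crossprod(Xs, U)
      V <- sweep(V, 2, ifelse(d > 0, d, 1), "/")
    } else {
      ei <- eigen(crossprod(Xs), symmetric = TRUE)
      d <- sqrt(pmax(ei$values[seq_len(k)], 0))
      V <- ei$vectors[, seq_len(k), drop = FALSE]
    }
  } else {
    V <- rsvd_right(Xs, k)
    d <- sqrt(colSums((Xs %*% V)^2))
  }
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xs %*% V
  colnames(V) <- colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- fp$samples$iid
  structure(list(variants = fp$variants[keep, , drop = FALSE],
                 means = 2 * p[keep], scales = sc[keep],
                 loadings = V, eigenvalues = d^2 / (n - 1),
                 scores = scores, k = k),
            class = "pc_model")
}

# Randomized right singular subspace (top-k) by subspace iteration with a
# deterministic probe matrix; accurate for the well-separated leading
# structure typical of population stratification.
rsvd_right <- function(X, k, oversample = 10, iters = 3) {
  m <- ncol(X)
  l <- min(m, k + oversample)
  Om <- with_seed(760437L + m + k,
                  matrix(rnorm(m * l), m, l))
  Q <- qr.Q(qr(crossprod(X, X %*% Om)))
  for (i in seq_len(iters)) {
    Q <- qr.Q(qr(crossprod(X, X %*% Q)))
  }
  B <- X %*% Q                       # n x l
  sv <- svd(B, nu = 0, nv = l)
  (Q %*% sv$v)[, seq_len(k), drop = FALSE]
}

#' Project samples onto a fitted PC model
#'
#' Standardizes the panel's dosages with the model's means and scales and
#' multiplies by the loadings. Variants are matched by identifier with
#' allele harmonization (ref/alt swap reverses the dosage); model variants
#' absent from the panel (or with irreconcilable alleles) contribute zero
#' (the post-centering mean). An error is raised when the usable overlap
#' falls below `min_overlap`.
#'
#' @param pcmodel a `pc_model`.
#' @param panel a `genotype_panel`.
#' @param min_overlap minimum usable fraction of model variants.
#' @return samples x k score matrix.
#' @export
project_samples <- function(pcmodel, panel, min_overlap = 0.95) {
  mv <- pcmodel$variants
  idx <- match(mv$id, panel$variants$id)
  found <- !is.na(idx)
  swap <- rep(FALSE, nrow(mv))
  if (any(found)) {
    pv <- panel$variants[idx[found], ]
    same <- pv$alt == mv$alt[found] & pv$ref == mv$ref[found]
    swapped <- pv$alt == mv$ref[found] & pv$ref == mv$alt[found]
    found[found] <- same | swapped
    swap[which(found)] <- swapped[same | swapped]
  }
  overlap <- mean(found)
  if (overlap < min_overlap)
    stop(sprintf("variant overlap %.3f below minimum %.3f",
                 overlap, min_overlap))
  D <- panel$dosages[, idx[found], drop = FALSE]
  if (any(swap[found])) {
    sw <- swap[found]
    D[, sw] <- 2 - D[, sw]
  }
  if (anyNA(D)) {
    # missing entries contribute the model mean, i.e. zero after centering
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- pcmodel$means[found][nas[, 2]]
  }
  Xs <- sweep(sweep(D, 2, pcmodel$means[found], "-"), 2,
              pcmodel$scales[found], "/")
  scores <- Xs %*% pcmodel$loadings[found, , drop = FALSE]
  rownames(scores) <- panel$samples$iid
  scores
}

#' Per-variant GWAS by ordinary least squares
#'
#' For each variant, fits `y ~ intercept + dosage + covariates` and
#' reports the dosage coefficient, its standard error, t statistic and
#' two-sided p value (t distribution, `n - (#covariates + 2)` df).
#' Implemented by residualizing both phenotype and dosages on the
#' covariates (Frisch-Waugh-Lovell), which is algebraically identical to
#' the full per-variant fit. Missing dosages are mean-imputed per variant;
#' monomorphic variants are emitted with NA statistics.
#'
#' @param panel a `genotype_panel`.
#' @param phenotype numeric vector aligned to the panel's samples.
#' @param covariates optional numeric matrix (samples x q), e.g. PC scores.
#' @return an association table (data.frame) with columns CHR, POS, ID, A1
#'   (effect = alternate allele), A2, A1_FREQ, BETA, SE, T_STAT, P, N.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL) {
  n <- nrow(panel$dosages)
  stopifnot(length(phenotype) == n)
  C <- cbind(rep(1, n), covariates)
  qr_c <- qr(C)
  if (qr_c$rank < ncol(C)) stop("covariate matrix is rank deficient")
  df <- n - ncol(C) - 1L
  if (df <= 0) stop("more parameters than observations")
  D <- imputed_dosages(panel)
  af <- colMeans(D) / 2
  yr <- qr.resid(qr_c, phenotype)
  Dr <- D - C %*% qr.coef(qr_c, D)
  xx <- colSums(Dr^2)
  xy <- drop(crossprod(Dr, yr))
  mono <- xx <= .Machine$double.eps * n
  beta <- ifelse(mono, NA_real_, xy / xx)
  rss <- sum(yr^2) - ifelse(mono, 0, beta^2 * xx)
  se <- ifelse(mono, NA_real_, sqrt(pmax(rss, 0) / df / xx))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  data.frame(CHR = panel$variants$chrom, POS = panel$variants$pos,
             ID = panel$variants$id, A1 = panel$variants$alt,
             A2 = panel$variants$ref, A1_FREQ = af, BETA = beta, SE = se,
             T_STAT = tstat, P = pval, N = n, stringsAsFactors = FALSE)
}

#' Inverse-variance-weighted meta-analysis of association tables
#'
#' Variants are matched on identifier and allele pair against the first
#' table in which they appear; swapped effect/other alleles flip the beta
#' sign (and the frequency), strand-ambiguous (A/T, C/G) variants are
#' dropped by default, and irreconcilable allele pairs raise an error.
#' For each variant present in at least one table,
#' `beta = sum(w_i b_i)/sum(w_i)` with `w_i = 1/SE_i^2`,
#' `SE = 1/sqrt(sum(w_i))`, and p from the normal approximation.
#'
#' @param tables list of association tables as produced by [run_gwas()].
#' @param drop_ambiguous drop strand-ambiguous variants.
#' @return a meta-analysis association table.
#' @export
ivw_meta <- function(tables, drop_ambiguous = TRUE) {
  stopifnot(length(tables) >= 1)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_tab <- NULL
  for (tab in tables) {
    tab <- tab[!is.na(tab$SE) & tab$SE > 0, , drop = FALSE]
    if (drop_ambiguous) {
      amb <- !is.na(comp[tab$A1]) & comp[tab$A1] == tab$A2
      tab <- tab[!amb, , drop = FALSE]
    }
    if (is.null(ref_tab)) {
      ref_tab <- tab[, c("CHR", "POS", "ID", "A1", "A2")]
      acc <- data.frame(ID = tab$ID, w = 1 / tab$SE^2,
                        wb = tab$BETA / tab$SE^2,
                        wf = tab$A1_FREQ / tab$SE^2, N = tab$N,
                        stringsAsFactors = FALSE)
      next
    }
    m <- match(tab$ID, ref_tab$ID)
    new <- is.na(m)
    if (any(!new)) {
      sub <- tab[!new, ]
      ref <- ref_tab[m[!new], ]
      same <- sub$A1 == ref$A1 & sub$A2 == ref$A2
      swap <- sub$A1 == ref$A2 & sub$A2 == ref$A1
      if (any(!same & !swap))
        stop(sprintf("irreconcilable allele pairs at %d variant(s), e.g. %s",
                     sum(!same & !swap),
                     sub$ID[which(!same & !swap)[1]]))
      b <- ifelse(swap, -sub$BETA, sub$BETA)
      f <- ifelse(swap, 1 - sub$A1_FREQ, sub$A1_FREQ)
      i <- m[!new]
      w <- 1 / sub$SE^2
      agg <- rowsum(data.frame(w = w, wb = w * b, wf = w * f, N = sub$N),
                    group = i)
      ii <- as.integer(rownames(agg))
      acc$w[ii] <- acc$w[ii] + agg$w
      acc$wb[ii] <- acc$wb[ii] + agg$wb
      acc$wf[ii] <- acc$wf[ii] + agg$wf
      acc$N[ii] <- acc$N[ii] + agg$N
    }
    if (any(new)) {
      ref_tab <- rbind(ref_tab, tab[new, c("CHR", "POS", "ID", "A1", "A2")])
      acc <- rbind(acc, data.frame(ID = tab$ID[new], w = 1 / tab$SE[new]^2,
                                   wb = tab$BETA[new] / tab$SE[new]^2,
                                   wf = tab$A1_FREQ[new] / tab$SE[new]^2,
                                   N = tab$N[new], stringsAsFactors = FALSE))
    }
  }
  if (is.null(ref_tab) || !nrow(ref_tab)) {
    return(data.frame(CHR = integer(), POS = integer(), ID = character(),
                      A1 = character(), A2 = character(),
                      A1_FREQ = numeric(), BETA = numeric(),
                      SE = numeric(), T_STAT = numeric(), P = numeric(),
                      N = numeric(), stringsAsFactors = FALSE))
  }
  beta <- acc$wb / acc$w
  se <- 1 / sqrt(acc$w)
  z <- beta / se
  out <- data.frame(CHR = ref_tab$CHR, POS = ref_tab$POS, ID = ref_tab$ID,
                    A1 = ref_tab$A1, A2 = ref_tab$A2,
                    A1_FREQ = acc$wf / acc$w, BETA = beta, SE = se,
                    T_STAT = z, P = 2 * pnorm(-abs(z)), N = acc$N,
                    stringsAsFactors = FALSE)
  out[order(out$CHR, out$POS), ]
}

#' Write / read GWAS summary statistics TSV
#' @param stats an association table.
#' @param path TSV path.
#' @export
write_sumstats <- function(stats, path) {
  data.table::fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' @rdname write_sumstats
#' @export
read_sumstats <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE))
}
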