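#' Genotype panel container
#'
#' The central data structure: a samples-by-variants dosage matrix in
#' \[0, 2\] (hard genotypes or imputed dosages, NA allowed) plus variant and
#' sample metadata. The counted allele is always the alternate allele
#' (PLINK A1 convention), so a dosage of 2 means homozygous alternate.
#'
#' @param dosages numeric matrix, samples in rows, variants in columns.
#' @param variants data.frame with columns `chrom` (integer), `pos`
#'   (1-based integer, sorted within chromosome), `id` (unique), `ref`,
#'   `alt`.
#' @param samples data.frame with columns `fid`, `iid` (unique), `pop`;
#'   optional further columns (sex, age).
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variants, samples) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(samples), ncol(dosages) == nrow(variants))
  if (anyDuplicated(variants$id)) stop("variant identifiers must be unique")
  if (anyDuplicated(samples$iid)) stop("sample iids must be unique")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("variant positions must be strictly increasing within chromosome")
  }
  new_genotype_panel(dosages, variants, samples)
}

# Internal constructor: trusted inputs, no validation pass over the
# (possibly very large) dosage matrix.
new_genotype_panel <- function(dosages, variants, samples) {
  rownames(dosages) <- samples$iid
  colnames(dosages) <- variants$id
  structure(list(dosages = dosages,
                 variants = as.data.frame(variants),
                 samples = as.data.frame(samples)),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d samples x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  tab <- table(x$samples$pop)
  cat("populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat(sprintf("chromosomes: %s\n",
              paste(unique(x$variants$chrom), collapse = " ")))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosages)

#' Alternate-allele frequency per variant
#'
#' @param panel a `genotype_panel`.
#' @return named numeric vector of alternate-allele frequencies.
#' @export
allele_freq <- function(panel) {
  colMeans(panel$dosages, na.rm = TRUE) / 2
}

#' Per-variant missingness fraction
#' @param panel a `genotype_panel`.
#' @return named numeric vector in \[0, 1\].
#' @export
variant_missingness <- function(panel) {
  colMeans(is.na(panel$dosages))
}

#' Subset a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @param samples sample iids, logical mask, or indices; NULL keeps all.
#' @param variants variant ids, logical mask, or indices; NULL keeps all.
#' @return a `genotype_panel`.
#' @export
subset_panel <- function(panel, samples = NULL, variants = NULL) {
  si <- seq_len(nrow(panel$dosages))
  vi <- seq_len(ncol(panel$dosages))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, panel$samples$iid)
          else si[samples]
    if (anyNA(si)) stop("unknown sample iid(s)")
  }
  if (!is.null(variants)) {
    vi <- if (is.character(variants)) match(variants, panel$variants$id)
          else vi[variants]
    if (anyNA(vi)) stop("unknown variant id(s)")
  }
  new_genotype_panel(panel$dosages[si, vi, drop = FALSE],
                     panel$variants[vi, , drop = FALSE],
                     panel$samples[si, , drop = FALSE])
}

#' Filter variants by MAF and missingness
#'
#' Retains variants with minor-allele frequency at or above `maf_min` and
#' missingness at or below `missing_max`. The default thresholds are those
#' used before principal-component analysis (MAF > 0.05, missingness
#' < 0.05).
#'
#' @param panel a `genotype_panel`.
#' @param maf_min minimum minor-allele frequency in \[0, 0.5\].
#' @param missing_max maximum per-variant missingness in \[0, 1\].
#' @param verbose report the number of variants removed.
#' @return filtered `genotype_panel` (sample set unchanged) with an
#'   attribute `n_removed`.
#' @export
filter_variants <- function(panel, maf_min = 0.05, missing_max = 0.05,
                            verbose = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5,
            missing_max >= 0, missing_max <= 1)
  af <- allele_freq(panel)
  maf <- pmin(af, 1 - af)
  miss <- variant_missingness(panel)
  keep <- !is.na(maf) & maf >= maf_min & miss <= missing_max
  n_removed <- sum(!keep)
  if (verbose || all(!keep))
    message(sprintf("filter_variants: removed %d of %d variants",
                    n_removed, length(keep)))
  out <- subset_panel(panel, variants = keep)
  attr(out, "n_removed") <- n_removed
  out
}

# Mean-imputed, optionally centered dosage matrix (used by LD, PCA, GWAS).
imputed_dosages <- function(panel, center = FALSE) {
  D <- panel$dosages
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  if (center) D <- sweep(D, 2, colMeans(D), "-")
  D
}
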