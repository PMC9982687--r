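#' Residualize phenotypes on age and sex
#'
#' Per trait, replaces values with the OLS residuals of
#' `trait ~ intercept + age + sex` (mean-centering plus removal of
#' demographic effects). Rows with missing trait/age/sex values stay NA;
#' the regression uses the complete rows of each trait.
#'
#' @param traits numeric matrix or data.frame, samples in rows, traits in
#'   columns.
#' @param age numeric vector.
#' @param sex numeric or two-level factor vector.
#' @return matrix of residualized traits with attribute
#'   `residualized = TRUE`.
#' @export
residualize <- function(traits, age, sex) {
  traits <- as.matrix(traits)
  sex <- if (is.factor(sex) || is.character(sex))
    as.numeric(as.factor(sex)) else as.numeric(sex)
  stopifnot(nrow(traits) == length(age), length(age) == length(sex))
  out <- traits
  for (j in seq_len(ncol(traits))) {
    y <- traits[, j]
    ok <- !is.na(y) & !is.na(age) & !is.na(sex)
    if (var(y[ok]) == 0) stop(sprintf("trait %d is constant", j))
    fit <- ols_fit(y[ok], cbind(age = age[ok], sex = sex[ok]))
    out[ok, j] <- fit$residuals
    out[!ok, j] <- NA_real_
  }
  attr(out, "residualized") <- TRUE
  out
}

#' Distribution and variance comparison of one trait across two cohorts
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on the (residualized)
#' values and variance-ratio F test `F = var(A)/var(B)` with a two-sided p
#' from the F distribution on (nA - 1, nB - 1) degrees of freedom.
#'
#' @param a,b numeric vectors (one trait, two cohorts).
#' @return data.frame with KS_D, KS_P, F_RATIO, F_P.
#' @export
distribution_tests <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stopifnot(length(a) >= 2, length(b) >= 2)
  ks <- suppressWarnings(ks.test(a, b, alternative = "two.sided"))
  if (var(a) == 0 || var(b) == 0)
    stop("zero variance on one side; F test undefined")
  ft <- var.test(a, b)
  data.frame(KS_D = unname(ks$statistic), KS_P = ks$p.value,
             F_RATIO = unname(ft$estimate), F_P = ft$p.value)
}

#' Trait correlation matrix with hierarchical-clustering order
#'
#' Pairwise-complete Pearson correlations between traits, with a row order
#' from average-linkage agglomerative clustering on the distance
#' `1 - correlation`. The order fitted in one cohort can be imposed on
#' another via `order_from`, as done when displaying two cohorts on a
#' common layout.
#'
#' @param traits samples x traits matrix or data.frame.
#' @param order_from optional character vector of trait names fixing the
#'   display order (e.g. the `order` element from another cohort).
#' @return list with `cor` (ordered correlation matrix) and `order`
#'   (trait names in display order).
#' @export
correlation_matrix <- function(traits, order_from = NULL) {
  traits <- as.matrix(traits)
  stopifnot(ncol(traits) >= 2)
  sds <- apply(traits, 2, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) stop("trait with zero variance")
  R <- cor(traits, use = "pairwise.complete.obs")
  ord <- if (is.null(order_from)) {
    hc <- hclust(as.dist(1 - R), method = "average")
    colnames(R)[hc$order]
  } else {
    stopifnot(all(colnames(R) %in% order_from))
    order_from[order_from %in% colnames(R)]
  }
  list(cor = R[ord, ord], order = ord)
}

#' Mantel permutation test between two symmetric matrices
#'
#' The statistic Z is the Pearson correlation of the vectorized strict
#' upper triangles. The null distribution is generated by simultaneously
#' permuting the rows and columns of the second matrix `n_perm` times;
#' the two-sided p value is `(1 + #[|Z_perm| >= |Z_obs|]) / (n_perm + 1)`,
#' bounded below by `1/(n_perm + 1)`.
#'
#' @param matA,matB symmetric matrices of equal dimension (>= 3 x 3),
#'   typically trait correlation or covariance matrices.
#' @param n_perm number of permutations (default 9999, resolving p down
#'   to 1e-4).
#' @param seed integer seed.
#' @return list with `z` and `p`.
#' @export
mantel_test <- function(matA, matB, n_perm = 9999, seed = 1) {
  matA <- as.matrix(matA); matB <- as.matrix(matB)
  stopifnot(identical(dim(matA), dim(matB)), nrow(matA) >= 3,
            isSymmetric(unname(matA), tol = 1e-8),
            isSymmetric(unname(matB), tol = 1e-8))
  ut <- upper.tri(matA)
  z_obs <- cor(matA[ut], matB[ut])
  n <- nrow(matA)
  a_vec <- matA[ut]
  with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n)
      zp <- cor(a_vec, matB[idx, idx][ut])
      if (abs(zp) >= abs(z_obs)) exceed <- exceed + 1L
    }
    list(z = z_obs, p = (1 + exceed) / (n_perm + 1))
  })
}

#' Compare a battery of traits across two cohorts
#'
#' Residualizes each cohort's traits on age and sex, runs the per-trait
#' K-S and F tests, computes each cohort's clustered correlation matrix
#' (cohort A's order imposed on B), and the Mantel permutation test
#' between the two correlation matrices. A Bonferroni-adjusted column is
#' included for convenience; the raw p values are the primary output.
#'
#' @param cohortA,cohortB lists with elements `traits` (samples x traits),
#'   `age`, `sex`.
#' @param n_perm Mantel permutations.
#' @param seed integer seed.
#' @return list with `tests` (per-trait data.frame), `corA`, `corB`
#'   (clustered correlation results), `mantel`.
#' @export
compare_cohorts <- function(cohortA, cohortB, n_perm = 9999, seed = 1) {
  ra <- residualize(cohortA$traits, cohortA$age, cohortA$sex)
  rb <- residualize(cohortB$traits, cohortB$age, cohortB$sex)
  common <- intersect(colnames(ra), colnames(rb))
  stopifnot(length(common) >= 2)
  tests <- do.call(rbind, lapply(common, function(tr) {
    cbind(TRAIT = tr, distribution_tests(ra[, tr], rb[, tr]))
  }))
  tests$KS_P_BONF <- pmin(1, tests$KS_P * length(common))
  tests$F_P_BONF <- pmin(1, tests$F_P * length(common))
  corA <- correlation_matrix(ra[, common, drop = FALSE])
  corB <- correlation_matrix(rb[, common, drop = FALSE],
                             order_from = corA$order)
  list(tests = tests, corA = corA, corB = corB,
       mantel = mantel_test(corA$cor, corB$cor[corA$order, corA$order],
                            n_perm = n_perm, seed = seed))
}
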