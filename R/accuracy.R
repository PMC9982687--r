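#' Incremental adjusted R-squared of a PRS
#'
#' Fits the two nested OLS models
#' `H0: phenotype ~ covariates` and `H1: phenotype ~ PRS + covariates`
#' and returns the difference in adjusted R-squared
#' (`adjR2 = 1 - (1 - R2)(n - 1)/(n - p - 1)`), i.e. the change in model
#' accuracy attributable to the PRS, together with the two-sided p value of
#' the PRS term in H1.
#'
#' @param phenotype numeric outcome vector.
#' @param prs numeric PRS vector.
#' @param covariates optional numeric matrix of covariates (no intercept
#'   column; one is added internally).
#' @return list with `inc_r2`, `p`, `adj_r2_h0`, `adj_r2_h1`, `n`.
#' @export
incremental_r2 <- function(phenotype, prs, covariates = NULL) {
  n <- length(phenotype)
  stopifnot(length(prs) == n,
            is.null(covariates) || nrow(covariates) == n)
  if (var(prs) == 0) stop("zero-variance PRS")
  h1 <- ols_fit(phenotype, cbind(PRS = prs, covariates))
  h0 <- if (is.null(covariates)) {
    list(adj_r2 = 0)  # intercept-only model explains nothing
  } else {
    ols_fit(phenotype, covariates)
  }
  list(inc_r2 = h1$adj_r2 - h0$adj_r2, p = unname(h1$p["PRS"]),
       adj_r2_h0 = h0$adj_r2, adj_r2_h1 = h1$adj_r2, n = n)
}

#' Bootstrap confidence interval for incremental adjusted R-squared
#'
#' Whole individuals (their phenotype, PRS and covariate rows together)
#' are resampled with replacement `n_boot` times; the incremental adjusted
#' R-squared is recomputed per replicate and the percentile interval
#' (default 2.5% and 97.5% quantiles of 100 replicates) is returned.
#' Degenerate replicates (zero-variance PRS or rank-deficient covariates
#' after resampling) are redrawn; more than 50% degenerate draws is an
#' error.
#'
#' @inheritParams incremental_r2
#' @param n_boot number of bootstrap replicates.
#' @param seed integer seed.
#' @param probs interval quantiles.
#' @return list with `lower`, `upper`, `replicates`, `n_redrawn`.
#' @export
bootstrap_ci <- function(phenotype, prs, covariates = NULL, n_boot = 100,
                         seed = 1, probs = c(0.025, 0.975)) {
  stopifnot(n_boot >= 1)
  n <- length(phenotype)
  with_seed(seed, {
    reps <- numeric(n_boot)
    n_redrawn <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(
          incremental_r2(phenotype[idx], prs[idx],
                         if (is.null(covariates)) NULL
                         else covariates[idx, , drop = FALSE])$inc_r2,
          error = function(e) NA_real_)
        if (!is.na(val)) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > n_boot / 2)
          stop("more than 50% of bootstrap replicates were degenerate")
      }
      reps[b] <- val
    }
    ci <- unname(quantile(reps, probs))
    list(lower = ci[1], upper = ci[2], replicates = reps,
         n_redrawn = n_redrawn)
  })
}

#' Evaluate a score profile across thresholds
#'
#' Convenience wrapper: computes the incremental adjusted R-squared (and
#' optionally a bootstrap CI) for every threshold of a `score_profile`.
#'
#' @param profile a `score_profile`.
#' @param phenotype outcome vector aligned to the profile's samples.
#' @param covariates optional covariate matrix.
#' @param n_boot bootstrap replicates (0 skips the CI).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per threshold: THRESHOLD, INC_R2, CI_L,
#'   CI_U, P, N, N_SNPS.
#' @export
evaluate_profile <- function(profile, phenotype, covariates = NULL,
                             n_boot = 100, seed = 1) {
  out <- lapply(seq_along(profile$thresholds), function(k) {
    prs <- profile$scores[, k]
    if (var(prs) == 0)
      return(data.frame(THRESHOLD = profile$thresholds[k],
                        INC_R2 = NA_real_, CI_L = NA_real_,
                        CI_U = NA_real_, P = NA_real_,
                        N = length(phenotype),
                        N_SNPS = profile$n_snps[k]))
    est <- incremental_r2(phenotype, prs, covariates)
    ci <- if (n_boot > 0)
      bootstrap_ci(phenotype, prs, covariates, n_boot = n_boot,
                   seed = child_seed(seed, k))
    else list(lower = NA_real_, upper = NA_real_)
    data.frame(THRESHOLD = profile$thresholds[k], INC_R2 = est$inc_r2,
               CI_L = ci$lower, CI_U = ci$upper, P = est$p, N = est$n,
               N_SNPS = profile$n_snps[k])
  })
  do.call(rbind, out)
}

#' Best-threshold selection
#'
#' Returns the row with the maximum incremental adjusted R-squared; exact
#' ties go to the stricter (smaller) threshold.
#'
#' @param estimates data.frame as returned by [evaluate_profile()] (columns
#'   THRESHOLD and INC_R2).
#' @return the selected row.
#' @export
best_threshold <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  ok <- !is.na(estimates$INC_R2)
  if (!any(ok)) return(estimates[1, , drop = FALSE])
  est <- estimates[ok, , drop = FALSE]
  est <- est[order(-est$INC_R2, est$THRESHOLD), , drop = FALSE]
  est[1, , drop = FALSE]
}

#' Relative accuracy, median RA and MAD across traits
#'
#' For each population and trait, the relative accuracy is the ratio of
#' the population's maximum (best-threshold) R-squared to the baseline
#' population's for the same trait. Negative incremental values are
#' floored at 0 before the ratio (flagged in the output); traits whose
#' baseline R-squared is 0 are excluded with a warning. Per population the
#' median RA across traits and the MAD (median of absolute deviations from
#' the median, unscaled) are reported, along with the loss of accuracy
#' `LOA = (1 - RA) * 100`.
#'
#' @param r2_table data.frame with columns `pop`, `trait`, `r2` (max
#'   incremental adjusted R-squared per population x trait).
#' @param baseline baseline population name (RA denominator; its RA is 1).
#' @return list with `per_trait` (POP, TRAIT, R2, RA, LOA, FLOORED) and
#'   `per_pop` (POP, MEDIAN_RA, MAD).
#' @export
relative_accuracy <- function(r2_table, baseline) {
  stopifnot(all(c("pop", "trait", "r2") %in% names(r2_table)))
  if (!baseline %in% r2_table$pop) stop("baseline population missing")
  floored <- !is.na(r2_table$r2) & r2_table$r2 < 0
  r2 <- pmax(r2_table$r2, 0)
  base <- r2_table$pop == baseline
  base_r2 <- stats::setNames(r2[base], r2_table$trait[base])
  if (anyNA(base_r2[unique(r2_table$trait)]))
    stop("baseline must have a value for every trait")
  zero <- names(base_r2)[base_r2 == 0]
  if (length(zero)) {
    warning(sprintf("excluding %d trait(s) with zero baseline R2: %s",
                    length(zero), paste(zero, collapse = ", ")))
  }
  keep <- !(r2_table$trait %in% zero)
  per_trait <- data.frame(POP = r2_table$pop[keep],
                          TRAIT = r2_table$trait[keep], R2 = r2[keep],
                          RA = r2[keep] / base_r2[r2_table$trait[keep]],
                          FLOORED = floored[keep],
                          stringsAsFactors = FALSE)
  per_trait$LOA <- loss_of_accuracy(per_trait$RA)
  agg <- lapply(split(per_trait$RA, per_trait$POP), function(ra) {
    c(median = median(ra), mad = median(abs(ra - median(ra))))
  })
  per_pop <- data.frame(POP = names(agg),
                        MEDIAN_RA = vapply(agg, `[[`, 0, "median"),
                        MAD = vapply(agg, `[[`, 0, "mad"),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_trait = per_trait, per_pop = per_pop)
}

#' Loss of prediction accuracy
#'
#' `LOA = (1 - RA) * 100` percent.
#'
#' @param ra relative accuracy (>= 0).
#' @return percentage loss.
#' @export
loss_of_accuracy <- function(ra) {
  stopifnot(all(ra >= 0, na.rm = TRUE))
  (1 - ra) * 100
}

#' Daetwyler expected PRS accuracy
#'
#' `E(R2) = h2 / (1 + M / (N * h2))`, with `M` the number of independent
#' trait-associated markers (the LD-clumped count at p < 1) and `N` the
#' discovery sample size.
#'
#' @param h2 heritability in \[0, 1\].
#' @param M number of independent markers (>= 0).
#' @param N discovery sample size (>= 1).
#' @return expected R-squared.
#' @export
daetwyler_expected_r2 <- function(h2, M, N) {
  stopifnot(all(h2 >= 0 & h2 <= 1), all(M >= 0), all(N >= 1))
  ifelse(h2 == 0, 0, h2 / (1 + M / (N * h2)))
}
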