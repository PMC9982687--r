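#' @importFrom stats rnorm rbinom rbeta runif cor sd var lm pnorm pt qnorm
#' @importFrom stats median quantile residuals as.dist hclust ks.test var.test
#' @importFrom stats complete.cases predict
#' @importFrom utils head
NULL

#' Derive a child seed from a master seed
#'
#' Experiment templates draw many independent random streams (panel
#' generation, architecture, phenotype noise, cohort splits, bootstraps).
#' Each stream gets its own deterministic child seed derived from the master
#' seed and a small set of integer keys, so that cells of an experiment grid
#' are reproducible in isolation.
#'
#' @param seed master seed (integer).
#' @param ... integer keys identifying the stream (stage index, cell index,
#'   replicate number, ...).
#' @return an integer in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, ...) {
  keys <- c(seed, ...)
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  s <- 0
  for (k in keys) {
    s <- (s * 69621 + (as.numeric(k) %% m) + 1) %% m
  }
  as.integer(s %% (m - 2)) + 1L
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG
# state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Fast OLS with intercept prepended. X may be NULL (intercept-only model).
# Returns coefficients, standard errors, residuals, R2 and adjusted R2.
ols_fit <- function(y, X = NULL) {
  n <- length(y)
  M <- cbind(`(Intercept)` = rep(1, n), X)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) stop("design matrix is rank deficient")
  cf <- qr.coef(qr_m, y)
  res <- qr.resid(qr_m, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  p <- ncol(M) - 1L            # predictors excluding intercept
  df <- n - p - 1L
  if (df <= 0) stop("not enough observations for the model")
  sigma2 <- rss / df
  XtXinv <- chol2inv(qr.R(qr_m))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(M)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  adj <- if (tss > 0) 1 - (1 - r2) * (n - 1) / (n - p - 1) else NA_real_
  tval <- cf / se
  list(coef = cf, se = se, t = tval,
       p = 2 * pt(-abs(tval), df),
       residuals = res, df = df, r2 = r2, adj_r2 = adj)
}

# Standardize a vector with the population (n-denominator) standard
# deviation; fixed convention so simulated scores are bit-reproducible.
standardize_pop <- function(x) {
  mu <- mean(x)
  s <- sqrt(mean((x - mu)^2))
  if (s == 0) stop("cannot standardize a zero-variance vector")
  (x - mu) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
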