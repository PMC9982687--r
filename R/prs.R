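#' The 10 pruning-and-thresholding p-value thresholds
#'
#' @return numeric vector `c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.2,
#'   0.5, 1)`; the loosest threshold ("all") is p <= 1.
#' @export
default_thresholds <- function() {
  c(5e-8, 1e-6, 1e-4, 1e-3, 1e-2, 0.05, 0.1, 0.2, 0.5, 1)
}

#' Harmonize summary statistics to a panel's allele coding
#'
#' Matches variants by identifier and aligns the effect allele to the
#' panel's alternate allele. Outcomes per variant: `match` (identical
#' coding), `swap` (effect/other alleles exchanged; beta sign and
#' frequency flipped), `ambiguous_dropped` (strand-ambiguous A/T or C/G
#' pair, dropped by default), `mismatch_dropped` (allele pair irreconcilable
#' with the panel), `absent_dropped` (identifier not in the panel).
#'
#' @param stats an association table.
#' @param panel a `genotype_panel`.
#' @param drop_ambiguous drop strand-ambiguous variants.
#' @return list with `stats` (aligned subset, effect allele = panel alt)
#'   and `report` (named counts).
#' @export
harmonize_sumstats <- function(stats, panel, drop_ambiguous = TRUE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  idx <- match(stats$ID, panel$variants$id)
  absent <- is.na(idx)
  status <- rep("absent_dropped", nrow(stats))
  pv_alt <- panel$variants$alt[idx]
  pv_ref <- panel$variants$ref[idx]
  same <- !absent & stats$A1 == pv_alt & stats$A2 == pv_ref
  swap <- !absent & stats$A1 == pv_ref & stats$A2 == pv_alt
  amb <- !is.na(comp[stats$A1]) & comp[stats$A1] == stats$A2
  status[same] <- "match"
  status[swap] <- "swap"
  status[!absent & !same & !swap] <- "mismatch_dropped"
  if (drop_ambiguous) status[(same | swap) & amb] <- "ambiguous_dropped"
  keep <- status %in% c("match", "swap")
  out <- stats[keep, , drop = FALSE]
  sw <- status[keep] == "swap"
  out$BETA[sw] <- -out$BETA[sw]
  if ("A1_FREQ" %in% names(out)) out$A1_FREQ[sw] <- 1 - out$A1_FREQ[sw]
  tmp <- out$A1[sw]; out$A1[sw] <- out$A2[sw]; out$A2[sw] <- tmp
  report <- table(factor(status, levels = c("match", "swap",
                                            "ambiguous_dropped",
                                            "mismatch_dropped",
                                            "absent_dropped")))
  list(stats = out, report = c(report))
}

#' Greedy LD clumping of summary statistics
#'
#' Variants with p <= `p_max` are visited in ascending p order (ties broken
#' by chromosome then position). Each variant not yet absorbed becomes an
#' index; every not-yet-absorbed considered variant on the same chromosome
#' within +/- `window_kb` kb whose squared Pearson dosage correlation with
#' the index exceeds `r2_max` is absorbed. Defaults follow the
#' pruning-and-thresholding recipe: r-squared cutoff 0.1 within 500 kb,
#' LD measured in the supplied panel (in-sample LD when the discovery
#' panel is passed). r-squared is computed on mean-imputed dosages.
#'
#' @param stats an association table.
#' @param ld_panel a `genotype_panel` providing the LD estimates.
#' @param r2_max clumping r-squared cutoff (absorb when r2 > r2_max).
#' @param window_kb window half-width in kb around the index variant.
#' @param p_max only variants with p <= p_max are considered.
#' @param pairs optional precomputed [ld_hit_pairs()] for `ld_panel` with
#'   the same `r2_max`/`window_kb`; the pair structure does not depend on
#'   the p values, so grids of traits over one LD panel can share it.
#' @return an object of class `clump_result`: `retained` data.frame (id,
#'   chrom, pos, p, n_absorbed), `absorbed` named list (index id ->
#'   absorbed ids), `filtered` ids (p > p_max or absent from the LD
#'   panel), `params`.
#' @export
clump <- function(stats, ld_panel, r2_max = 0.1, window_kb = 500,
                  p_max = 1, pairs = NULL) {
  stopifnot(p_max > 0, p_max <= 1)
  if (!nrow(stats)) stop("empty summary statistics")
  if (nrow(ld_panel$dosages) < 2) stop("LD panel needs >= 2 samples")
  in_panel <- stats$ID %in% ld_panel$variants$id
  if (any(!in_panel))
    warning(sprintf("%d variant(s) absent from the LD panel were filtered",
                    sum(!in_panel)))
  considered <- which(in_panel & !is.na(stats$P) & stats$P <= p_max)
  filtered <- stats$ID[setdiff(seq_len(nrow(stats)), considered)]
  params <- list(r2_max = r2_max, window_kb = window_kb, p_max = p_max)
  if (!length(considered)) {
    return(structure(list(retained = data.frame(id = character(),
                                                chrom = integer(),
                                                pos = integer(),
                                                p = numeric(),
                                                n_absorbed = integer()),
                          absorbed = list(), filtered = filtered,
                          params = params),
                     class = "clump_result"))
  }
  sub <- stats[considered, ]
  ord <- order(sub$P, sub$CHR, sub$POS)
  sub <- sub[ord, ]
  nv <- nrow(sub)
  ids <- sub$ID
  if (is.null(pairs)) {
    cols <- match(sub$ID, ld_panel$variants$id)
    hits <- banded_hits(ld_panel$dosages[, cols, drop = FALSE],
                        sub$CHR, sub$POS, r2_max, window_kb * 1000)
  } else {
    stopifnot(inherits(pairs, "ld_pairs"))
    if (pairs$r2_max != r2_max || pairs$window_kb != window_kb)
      stop("pairs were precomputed with different clumping parameters")
    ph <- pairs$hits
    from <- rep(names(ph), lengths(ph))
    to <- unlist(ph, use.names = FALSE)
    fi <- match(from, ids)
    ti <- match(to, ids)
    ok <- !is.na(fi) & !is.na(ti)
    hits <- vector("list", nv)
    if (any(ok)) {
      spl <- split(ti[ok], fi[ok])
      hits[as.integer(names(spl))] <- spl
    }
  }
  alive <- rep(TRUE, nv)
  is_index <- rep(FALSE, nv)
  absorbed_by <- vector("list", nv)
  for (j in seq_len(nv)) {
    if (!alive[j]) next
    is_index[j] <- TRUE
    h <- hits[[j]]
    if (is.null(h)) next
    h <- h[alive[h]]
    if (length(h)) {
      alive[h] <- FALSE
      absorbed_by[[j]] <- ids[h]
    }
  }
  ret <- which(is_index)
  retained <- data.frame(id = sub$ID[ret], chrom = sub$CHR[ret],
                         pos = sub$POS[ret], p = sub$P[ret],
                         n_absorbed = vapply(absorbed_by[ret], length, 0L),
                         stringsAsFactors = FALSE)
  absorbed <- absorbed_by[ret]
  names(absorbed) <- sub$ID[ret]
  absorbed <- absorbed[vapply(absorbed, length, 0L) > 0]
  structure(list(retained = retained, absorbed = absorbed,
                 filtered = filtered, params = params),
            class = "clump_result")
}

# Blocked (BLAS-3) banded scan: all pairs of variants on the same
# chromosome within `window` bp whose squared dosage correlation exceeds
# r2_max. D holds the dosage columns (mean-imputed here); returns a list
# of integer partner indices per column.
banded_hits <- function(D, chr, pos, r2_max, window) {
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    nas <- which(is.na(D), arr.ind = TRUE)
    D[nas] <- mu[nas[, 2]]
  }
  Xc <- sweep(D, 2, colMeans(D), "-")
  ssq <- colSums(Xc^2)
  nv <- ncol(Xc)
  hits <- vector("list", nv)
  for (ch in unique(chr)) {
    ix <- which(chr == ch)
    ix <- ix[order(pos[ix])]
    posc <- pos[ix]
    nc <- length(ix)
    Xp <- Xc[, ix, drop = FALSE]
    ssqc <- ssq[ix]
    B <- 128L
    for (s in seq(1L, nc, by = B)) {
      e <- min(s + B - 1L, nc)
      lo <- findInterval(posc[s] - window - 0.5, posc) + 1L
      hi <- findInterval(posc[e] + window + 0.5, posc)
      Cm <- crossprod(Xp[, s:e, drop = FALSE], Xp[, lo:hi, drop = FALSE])
      R2 <- Cm^2 / (ssqc[s:e] %o% ssqc[lo:hi])
      R2[!is.finite(R2)] <- 0
      hit <- which(R2 > r2_max, arr.ind = TRUE)
      if (nrow(hit)) {
        a <- s + hit[, 1] - 1L         # indices into ix
        b <- lo + hit[, 2] - 1L
        keep <- a != b & abs(posc[a] - posc[b]) <= window
        if (any(keep)) {
          a <- a[keep]; b <- b[keep]
          spl <- split(ix[b], a)
          for (nm in names(spl))
            hits[[ix[as.integer(nm)]]] <-
              c(hits[[ix[as.integer(nm)]]], spl[[nm]])
        }
      }
    }
  }
  hits
}

#' Precompute within-window high-LD variant pairs
#'
#' Scans a panel once for all same-chromosome variant pairs within
#' `window_kb` whose squared dosage correlation exceeds `r2_max`. The
#' result can be passed to [clump()] (argument `pairs`) to amortize the LD
#' scan across many summary-statistics tables that share one LD panel —
#' the pair structure does not depend on p values.
#'
#' @param ld_panel a `genotype_panel`.
#' @param r2_max clumping r-squared cutoff.
#' @param window_kb window half-width in kb.
#' @return an `ld_pairs` object.
#' @export
ld_hit_pairs <- function(ld_panel, r2_max = 0.1, window_kb = 500) {
  v <- ld_panel$variants
  hits <- banded_hits(ld_panel$dosages, v$chrom, v$pos, r2_max,
                      window_kb * 1000)
  named <- lapply(hits, function(h) v$id[h])
  names(named) <- v$id
  structure(list(hits = named[lengths(named) > 0], r2_max = r2_max,
                 window_kb = window_kb),
            class = "ld_pairs")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf(paste0("clump_result: %d index variants (r2 > %.3g absorbed, ",
                     "window %g kb, p <= %g); %d absorbed, %d filtered\n"),
              nrow(x$retained), x$params$r2_max, x$params$window_kb,
              x$params$p_max, sum(x$retained$n_absorbed),
              length(x$filtered)))
  invisible(x)
}

#' Pruning-and-thresholding polygenic scores
#'
#' For each threshold t, `PRS_i = sum over retained variants with p <= t of
#' beta_j * dosage_ij`. Alleles are harmonized to the panel first
#' (swap = sign flip, ambiguous dropped by default). Missing dosages are
#' imputed as twice the effect-allele frequency from the summary statistics
#' (falling back to the panel frequency), the standard dosage-scoring
#' default; set `impute_missing = FALSE` to drop missing entries instead.
#'
#' @param panel the target `genotype_panel` to score.
#' @param stats an association table.
#' @param clump optional `clump_result`; when given, only retained index
#'   variants are scored.
#' @param thresholds p-value thresholds (default [default_thresholds()]).
#' @param drop_ambiguous drop strand-ambiguous variants during
#'   harmonization.
#' @param impute_missing impute missing dosages from the effect-allele
#'   frequency.
#' @return an object of class `score_profile`: `scores` (samples x
#'   thresholds matrix), `n_snps` per threshold, `thresholds`, `samples`.
#' @export
prs_score <- function(panel, stats, clump = NULL,
                      thresholds = default_thresholds(),
                      drop_ambiguous = TRUE, impute_missing = TRUE) {
  stopifnot(length(thresholds) >= 1)
  harm <- harmonize_sumstats(stats, panel, drop_ambiguous = drop_ambiguous)
  st <- harm$stats
  if (!is.null(clump)) st <- st[st$ID %in% clump$retained$id, , drop = FALSE]
  thresholds <- sort(thresholds)
  n <- nrow(panel$dosages)
  scores <- matrix(0, n, length(thresholds),
                   dimnames = list(panel$samples$iid,
                                   format(thresholds, trim = TRUE)))
  n_snps <- integer(length(thresholds))
  if (nrow(st)) {
    idx <- match(st$ID, panel$variants$id)
    D <- panel$dosages[, idx, drop = FALSE]
    if (anyNA(D)) {
      if (impute_missing) {
        fill <- 2 * st$A1_FREQ
        bad <- !is.finite(fill)
        if (any(bad)) fill[bad] <- 2 * colMeans(D[, bad, drop = FALSE],
                                                na.rm = TRUE)
        nas <- which(is.na(D), arr.ind = TRUE)
        D[nas] <- fill[nas[, 2]]
      } else {
        D[is.na(D)] <- 0
      }
    }
    for (k in seq_along(thresholds)) {
      sel <- !is.na(st$P) & st$P <= thresholds[k]
      n_snps[k] <- sum(sel)
      if (n_snps[k] > 0)
        scores[, k] <- drop(D[, sel, drop = FALSE] %*% st$BETA[sel])
    }
  }
  if (n_snps[1] == 0)
    message("no variants pass the strictest threshold; score is 0 there")
  structure(list(scores = scores, n_snps = n_snps,
                 thresholds = thresholds,
                 samples = panel$samples[, c("fid", "iid")],
                 harmonization = harm$report),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("score_profile: %d samples x %d thresholds\n",
              nrow(x$scores), length(x$thresholds)))
  cat("variants per threshold:",
      paste(sprintf("%g:%d", x$thresholds, x$n_snps), collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.score_profile <- function(x, ...) {
  data.frame(FID = rep(x$samples$fid, times = length(x$thresholds)),
             IID = rep(x$samples$iid, times = length(x$thresholds)),
             THRESHOLD = rep(x$thresholds, each = nrow(x$scores)),
             PRS = as.vector(x$scores),
             N_SNPS = rep(x$n_snps, each = nrow(x$scores)),
             stringsAsFactors = FALSE)
}

#' Build a weighted composite LD reference panel
#'
#' Combines population panels into one reference with ancestral
#' representation proportional to the supplied weights, anchored on one
#' panel taken in full (mirroring the construction where the largest
#' discovery cohort's reference samples are all included and the others are
#' subsampled proportionally): with anchor a, panel i contributes
#' `round(n_a * w_i / w_a)` samples drawn without replacement.
#'
#' @param panels list of `genotype_panel` objects sharing a variant set.
#' @param weights non-negative weights summing to 1.
#' @param anchor index of the panel included in full (default: largest
#'   weight).
#' @param seed integer seed for the subsampling.
#' @return a composite `genotype_panel`.
#' @export
build_ld_reference <- function(panels, weights, anchor = which.max(weights),
                               seed = 1) {
  stopifnot(length(panels) == length(weights), all(weights >= 0),
            abs(sum(weights) - 1) < 1e-8)
  n_a <- nrow(panels[[anchor]]$dosages)
  take <- vapply(seq_along(panels), function(i) {
    if (i == anchor) n_a
    else as.integer(round(n_a * weights[i] / weights[anchor]))
  }, 0L)
  avail <- vapply(panels, function(p) nrow(p$dosages), 0L)
  if (any(take > avail))
    stop("weighting demands more samples than a panel provides")
  with_seed(seed, {
    parts <- lapply(seq_along(panels), function(i) {
      if (take[i] == 0) return(NULL)
      if (take[i] == avail[i]) return(panels[[i]])
      subset_panel(panels[[i]],
                   samples = sort(sample(avail[i], take[i])))
    })
    parts <- parts[!vapply(parts, is.null, TRUE)]
    base <- parts[[1]]
    if (length(parts) > 1) {
      for (p in parts[-1]) {
        if (!identical(base$variants$id, p$variants$id))
          stop("panels must share an identical variant set")
      }
      base <- genotype_panel(do.call(rbind,
                                     lapply(parts, `[[`, "dosages")),
                             parts[[1]]$variants,
                             do.call(rbind, lapply(parts, `[[`, "samples")))
    }
    base
  })
}

#' Write a clump result TSV (INDEX_ID, P, N_ABSORBED, ABSORBED_IDS)
#' @param clump a `clump_result`.
#' @param path TSV path.
#' @export
write_clump <- function(clump, path) {
  ab <- vapply(clump$retained$id, function(id)
    paste(clump$absorbed[[id]] %||% character(), collapse = ","), "")
  data.table::fwrite(data.frame(INDEX_ID = clump$retained$id,
                                P = clump$retained$p,
                                N_ABSORBED = clump$retained$n_absorbed,
                                ABSORBED_IDS = ab),
                     path, sep = "\t")
  invisible(path)
}
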