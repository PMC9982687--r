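#' Experiment configurations
#'
#' Templates bundle every parameter of the three end-to-end experiment
#' designs. Defaults reproduce the reference experimental conditions: the three-region
#' sparse-architecture design (discovery East n=403 / West n=331, targets
#' n=186, h2 grid \{0.1, 0.2, 0.4, 0.8\}, n_causal grid \{5, 20, 100,
#' 2000, 10000, 50000\}), the four-group infinitesimal design (500-sample
#' holdouts, discovery 9,020, MAF-coupled effects), and a transfer ladder
#' with a baseline discovery population and targets at increasing
#' divergence. GWAS uses 20 PCs, evaluation 10 PCs, clumping r2 > 0.1
#' within 500 kb with in-sample LD, the 10 standard p-value thresholds,
#' and 100 bootstrap replicates (`n_boot = 0` skips the CIs). Variant
#' counts are desk-scale defaults; all parameters are overridable.
#'
#' @param model a `population_model`.
#' @param h2 heritability grid.
#' @param n_causal causal-count grid (sparse designs).
#' @param alpha MAF-coupling exponent (infinitesimal design).
#' @param prop_causal causal proportion (infinitesimal design).
#' @param thresholds p-value thresholds.
#' @param gwas_pcs,eval_pcs numbers of PC covariates for GWAS and
#'   evaluation.
#' @param weighting phenotype weighting, `"literal"` or `"sqrt"`.
#' @param clump_r2,clump_kb clumping parameters.
#' @param n_boot bootstrap replicates per evaluation (0 = none).
#' @param seeds integer vector of master seeds (one full replicate each).
#' @param cache_dir optional directory for stage checkpoints (per-cell
#'   TSVs keyed by template, seed and cell; reruns reuse existing files).
#' @param baseline baseline population (transfer design).
#' @param discovery_n,target_n cohort sizes (transfer design).
#' @param n_traits number of trait replicates (transfer design).
#' @param ci_width_max exclude traits whose baseline bootstrap CI range is
#'   at least this wide (transfer design; default 0.08).
#' @param matched_pop,matched_n optional ancestry-matched second discovery
#'   cohort (transfer design): population label and size.
#' @return an `experiment_config` list.
#' @name experiment_config
NULL

#' @rdname experiment_config
#' @export
agvp_experiment_config <- function(model = agvp_population_model(),
                                   h2 = c(0.1, 0.2, 0.4, 0.8),
                                   n_causal = c(5, 20, 100, 2000, 10000,
                                                50000),
                                   thresholds = default_thresholds(),
                                   gwas_pcs = 20, eval_pcs = 10,
                                   weighting = "literal",
                                   clump_r2 = 0.1, clump_kb = 500,
                                   n_boot = 100, seeds = 1:20,
                                   target_n = 186, cache_dir = NULL) {
  structure(list(template = "agvp", model = model, h2 = h2,
                 n_causal = n_causal, target_n = target_n,
                 thresholds = thresholds,
                 gwas_pcs = gwas_pcs, eval_pcs = eval_pcs,
                 weighting = weighting, clump_r2 = clump_r2,
                 clump_kb = clump_kb, n_boot = n_boot, seeds = seeds,
                 cache_dir = cache_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
awigen_experiment_config <- function(model = awigen_population_model(),
                                     h2 = c(0.1, 0.2, 0.4, 0.8),
                                     alpha = -0.38, prop_causal = 1,
                                     thresholds = default_thresholds(),
                                     gwas_pcs = 20, eval_pcs = 10,
                                     weighting = "literal",
                                     clump_r2 = 0.1, clump_kb = 500,
                                     n_boot = 100, seeds = 1,
                                     target_n = 500, cache_dir = NULL) {
  structure(list(template = "awigen", model = model, h2 = h2,
                 alpha = alpha, prop_causal = prop_causal,
                 target_n = target_n,
                 thresholds = thresholds, gwas_pcs = gwas_pcs,
                 eval_pcs = eval_pcs, weighting = weighting,
                 clump_r2 = clump_r2, clump_kb = clump_kb,
                 n_boot = n_boot, seeds = seeds, cache_dir = cache_dir),
            class = "experiment_config")
}

#' @rdname experiment_config
#' @export
transfer_experiment_config <- function(model = NULL, baseline = "Base",
                                       discovery_n = 2000, target_n = 500,
                                       n_traits = 5, n_causal = 1000,
                                       h2 = 0.8,
                                       thresholds = default_thresholds(),
                                       gwas_pcs = 10, eval_pcs = 10,
                                       weighting = "literal",
                                       clump_r2 = 0.1, clump_kb = 500,
                                       n_boot = 100, ci_width_max = 0.08,
                                       matched_pop = NULL, matched_n = 1000,
                                       seeds = 1, cache_dir = NULL) {
  if (is.null(model)) {
    sizes <- c(Base = discovery_n + target_n, Near = target_n,
               Mid = target_n, Far = target_n)
    if (!is.null(matched_pop))
      sizes[matched_pop] <- sizes[matched_pop] + matched_n
    # drift chosen so realized F_ST to Base ((F_a+F_b)/2 + 1/founders)
    # steps through ~0.009, 0.05, 0.10 - a well-separated ladder
    model <- population_model(
      labels = c("Base", "Near", "Mid", "Far"),
      fst = c(Base = 0.002, Near = 0.002, Mid = 0.085, Far = 0.185),
      sample_sizes = sizes, n_chrom = 10, variants_per_chrom = 1000,
      n_founder_haplotypes = 150)
  }
  structure(list(template = "transfer", model = model, baseline = baseline,
                 discovery_n = discovery_n, target_n = target_n,
                 n_traits = n_traits, n_causal = n_causal, h2 = h2,
                 thresholds = thresholds, gwas_pcs = gwas_pcs,
                 eval_pcs = eval_pcs, weighting = weighting,
                 clump_r2 = clump_r2, clump_kb = clump_kb, n_boot = n_boot,
                 ci_width_max = ci_width_max, matched_pop = matched_pop,
                 matched_n = matched_n, seeds = seeds,
                 cache_dir = cache_dir),
            class = "experiment_config")
}

# Checkpoint helper: evaluate compute() or reuse an existing TSV.
cached_table <- function(cache_dir, key, compute) {
  if (is.null(cache_dir)) return(compute())
  if (!dir.exists(cache_dir)) dir.create(cache_dir, recursive = TRUE)
  path <- file.path(cache_dir, paste0(key, ".tsv"))
  if (file.exists(path)) return(as.data.frame(data.table::fread(path)))
  out <- compute()
  data.table::fwrite(out, path, sep = "\t")
  out
}

# Shared evaluation step: score a target panel and evaluate every
# threshold with the target's own evaluation PCs (precomputable).
# Strand-ambiguity filtering is disabled: summary statistics and target
# dosages come from one simulated source, so A/T and C/G variants carry
# no strand uncertainty and dropping them would only discard signal.
eval_target <- function(target_panel, stats, cl, pheno_by_iid, config,
                        seed, eval_scores = NULL) {
  profile <- suppressMessages(
    prs_score(target_panel, stats, clump = cl,
              thresholds = config$thresholds, drop_ambiguous = FALSE))
  if (is.null(eval_scores))
    eval_scores <- compute_pca(target_panel, k = config$eval_pcs)$scores
  y <- pheno_by_iid[target_panel$samples$iid]
  evaluate_profile(profile, y, covariates = eval_scores,
                   n_boot = config$n_boot, seed = seed)
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
}

#' Run the three-region sparse-architecture experiment
#'
#' For every master seed: simulate the panel, the trait grid and the
#' cohort splits; run a 20-PC GWAS in each discovery region; clump with
#' in-sample LD; score every target region at all thresholds; evaluate
#' incremental adjusted R-squared (10 evaluation PCs) with optional
#' bootstrap CIs. Returns one row per (seed, discovery, target, h2,
#' n_causal, threshold).
#'
#' @param config an `experiment_config` from [agvp_experiment_config()].
#' @param verbose emit stage log lines.
#' @return long-format data.frame.
#' @export
run_agvp_experiment <- function(config, verbose = FALSE) {
  stopifnot(config$template == "agvp")
  rows <- list()
  for (seed in config$seeds) {
    log_stage(verbose, "agvp seed %d: simulating panel", seed)
    panel <- sample_genotype_panel(config$model, child_seed(seed, 1))
    split <- split_cohorts(panel,
                           agvp_split_scheme(target_n = config$target_n),
                           child_seed(seed, 3))
    eval_scores <- lapply(split$target, function(p)
      compute_pca(p, k = config$eval_pcs)$scores)
    pheno_cache <- list()
    n_cells <- length(config$n_causal) * length(config$h2)
    for (disc_name in names(split$discovery)) {
      disc <- split$discovery[[disc_name]]
      dpc <- compute_pca(disc, k = config$gwas_pcs)
      ld_pairs <- if (n_cells > 1 && max(config$thresholds) > 0.01)
        ld_hit_pairs(disc, config$clump_r2, config$clump_kb) else NULL
      for (i_nc in seq_along(config$n_causal)) {
        nc <- config$n_causal[i_nc]
        for (i_h2 in seq_along(config$h2)) {
          h2 <- config$h2[i_h2]
          arch <- draw_sparse_architecture(panel, nc, h2,
                                           seed = child_seed(seed, 2, i_nc))
          ph_key <- sprintf("%d_%d", i_nc, i_h2)
          if (is.null(pheno_cache[[ph_key]]))
            pheno_cache[[ph_key]] <- simulate_phenotype(
              panel, arch, seed = child_seed(seed, 4, i_nc, i_h2),
              weighting = config$weighting)
          pheno <- pheno_cache[[ph_key]]
          y <- stats::setNames(pheno$phenotype, pheno$iid)
          log_stage(verbose, "agvp seed %d: GWAS %s nc=%d h2=%.2g",
                    seed, disc_name, nc, h2)
          stats_tab <- cached_table(
            config$cache_dir,
            sprintf("agvp_s%d_%s_nc%d_h2%g_gwas", seed, disc_name, nc, h2),
            function() run_gwas(disc, y[disc$samples$iid],
                                covariates = dpc$scores))
          cl <- clump(stats_tab, disc, r2_max = config$clump_r2,
                      window_kb = config$clump_kb,
                      p_max = max(config$thresholds), pairs = ld_pairs)
          for (tgt_name in names(split$target)) {
            res <- cached_table(
              config$cache_dir,
              sprintf("agvp_s%d_%s_to_%s_nc%d_h2%g_eval", seed, disc_name,
                      tgt_name, nc, h2),
              function() eval_target(split$target[[tgt_name]], stats_tab,
                                     cl, y, config,
                                     seed = child_seed(seed, 5, i_nc, i_h2),
                                     eval_scores = eval_scores[[tgt_name]]))
            rows[[length(rows) + 1]] <-
              cbind(SEED = seed, DISCOVERY = disc_name, TARGET = tgt_name,
                    H2 = h2, N_CAUSAL = nc, res)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the four-group infinitesimal experiment
#'
#' For every master seed and heritability: simulate a MAF-coupled
#' infinitesimal trait; for each holdout group, hold out the target
#' samples, run a 20-PC GWAS in the pooled discovery cohort, clump, score
#' the target at all thresholds, and evaluate with bootstrap CIs. Returns
#' one row per (seed, holdout, h2, threshold).
#'
#' @param config an `experiment_config` from [awigen_experiment_config()].
#' @param verbose emit stage log lines.
#' @return long-format data.frame.
#' @export
run_awigen_experiment <- function(config, verbose = FALSE) {
  stopifnot(config$template == "awigen")
  rows <- list()
  for (seed in config$seeds) {
    log_stage(verbose, "awigen seed %d: simulating panel", seed)
    panel <- sample_genotype_panel(config$model, child_seed(seed, 1))
    for (i_hold in seq_along(config$model$labels)) {
      holdout <- config$model$labels[i_hold]
      split <- split_cohorts(panel,
                             awigen_split_scheme(holdout,
                                                 target_n = config$target_n),
                             child_seed(seed, 3, i_hold))
      disc <- split$discovery$pooled
      dpc <- compute_pca(disc, k = config$gwas_pcs)
      ld_pairs <- if (length(config$h2) > 1 &&
                        max(config$thresholds) > 0.01)
        ld_hit_pairs(disc, config$clump_r2, config$clump_kb) else NULL
      for (i_h2 in seq_along(config$h2)) {
        h2 <- config$h2[i_h2]
        arch <- draw_maf_coupled_architecture(
          panel, h2, alpha = config$alpha,
          prop_causal = config$prop_causal, seed = child_seed(seed, 2))
        pheno <- simulate_phenotype(panel, arch,
                                    seed = child_seed(seed, 4, i_h2),
                                    weighting = config$weighting)
        y <- stats::setNames(pheno$phenotype, pheno$iid)
        log_stage(verbose, "awigen seed %d: GWAS holdout=%s h2=%.2g",
                  seed, holdout, h2)
        stats_tab <- cached_table(
          config$cache_dir,
          sprintf("awigen_s%d_%s_h2%g_gwas", seed, holdout, h2),
          function() run_gwas(disc, y[disc$samples$iid],
                              covariates = dpc$scores))
        cl <- clump(stats_tab, disc, r2_max = config$clump_r2,
                    window_kb = config$clump_kb,
                      p_max = max(config$thresholds), pairs = ld_pairs)
        res <- eval_target(split$target[[holdout]], stats_tab, cl, y,
                           config, seed = child_seed(seed, 5, i_hold, i_h2))
        rows[[length(rows) + 1]] <-
          cbind(SEED = seed, HOLDOUT = holdout, H2 = h2, res)
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the cross-population transfer experiment
#'
#' One designated baseline population provides the discovery GWAS and a
#' withheld baseline target; every other population is a target at its
#' own genetic distance. Per trait replicate: GWAS in the baseline
#' discovery cohort, clump, multi-threshold scoring in every target,
#' best-threshold selection, and relative accuracy / LOA / per-population
#' median and MAD against the baseline target. Traits whose baseline
#' bootstrap CI range is `ci_width_max` or wider are excluded. When
#' `matched_pop` is set, a second GWAS in an ancestry-matched discovery
#' cohort is combined with the baseline GWAS by inverse-variance
#' meta-analysis and the matched target is re-evaluated, quantifying the
#' benefit of diverse discovery data.
#'
#' @param config an `experiment_config` from
#'   [transfer_experiment_config()].
#' @param verbose emit stage log lines.
#' @return list with `per_trait`, `per_pop` (relative-accuracy tables,
#'   pooled over seeds), `r2` (per seed/trait/population best-threshold
#'   estimates), and `matched` (mismatched-vs-meta comparison, when
#'   configured).
#' @export
run_transfer_experiment <- function(config, verbose = FALSE) {
  stopifnot(config$template == "transfer")
  base <- config$baseline
  r2_rows <- list(); matched_rows <- list()
  for (seed in config$seeds) {
    log_stage(verbose, "transfer seed %d: simulating panel", seed)
    panel <- sample_genotype_panel(config$model, child_seed(seed, 1))
    pops <- config$model$labels
    with_seed(child_seed(seed, 3), {
      idx_base <- which(panel$samples$pop == base)
      t_base <- sort(sample(idx_base, config$target_n))
      d_base <- sort(sample(setdiff(idx_base, t_base), config$discovery_n))
      targets <- list()
      matched_disc_idx <- NULL
      for (p in setdiff(pops, base)) {
        idx_p <- which(panel$samples$pop == p)
        targets[[p]] <- sort(sample(idx_p, config$target_n))
        if (!is.null(config$matched_pop) && p == config$matched_pop)
          matched_disc_idx <- sort(sample(setdiff(idx_p, targets[[p]]),
                                          config$matched_n))
      }
    })
    disc <- subset_panel(panel, samples = d_base)
    dpc <- compute_pca(disc, k = config$gwas_pcs)
    ld_pairs <- if (max(config$thresholds) > 0.01)
      ld_hit_pairs(disc, config$clump_r2, config$clump_kb) else NULL
    target_panels <- c(stats::setNames(list(subset_panel(panel,
                                                         samples = t_base)),
                                       base),
                       lapply(targets, function(ix)
                         subset_panel(panel, samples = ix)))
    if (!is.null(matched_disc_idx)) {
      mdisc <- subset_panel(panel, samples = matched_disc_idx)
      mpc <- compute_pca(mdisc, k = config$gwas_pcs)
    }
    for (t in seq_len(config$n_traits)) {
      arch <- draw_sparse_architecture(panel, config$n_causal, config$h2,
                                       seed = child_seed(seed, 2, t))
      pheno <- simulate_phenotype(panel, arch,
                                  seed = child_seed(seed, 4, t),
                                  weighting = config$weighting)
      y <- stats::setNames(pheno$phenotype, pheno$iid)
      log_stage(verbose, "transfer seed %d: trait %d GWAS", seed, t)
      stats_tab <- run_gwas(disc, y[disc$samples$iid],
                            covariates = dpc$scores)
      cl <- clump(stats_tab, disc, r2_max = config$clump_r2,
                  window_kb = config$clump_kb,
                      p_max = max(config$thresholds), pairs = ld_pairs)
      best <- list()
      for (p in names(target_panels)) {
        res <- eval_target(target_panels[[p]], stats_tab, cl, y, config,
                           seed = child_seed(seed, 5, t, match(p, pops)))
        best[[p]] <- best_threshold(res)
      }
      ci_width <- best[[base]]$CI_U - best[[base]]$CI_L
      keep <- is.na(ci_width) || ci_width < config$ci_width_max
      for (p in names(best)) {
        r2_rows[[length(r2_rows) + 1]] <-
          data.frame(SEED = seed, TRAIT = sprintf("trait%02d_s%d", t, seed),
                     POP = p, THRESHOLD = best[[p]]$THRESHOLD,
                     R2 = best[[p]]$INC_R2, CI_L = best[[p]]$CI_L,
                     CI_U = best[[p]]$CI_U, KEPT = keep,
                     stringsAsFactors = FALSE)
      }
      if (!is.null(matched_disc_idx)) {
        mstats <- run_gwas(mdisc, y[mdisc$samples$iid],
                           covariates = mpc$scores)
        meta <- ivw_meta(list(stats_tab, mstats))
        mcl <- clump(meta, disc, r2_max = config$clump_r2,
                     window_kb = config$clump_kb,
                      p_max = max(config$thresholds), pairs = ld_pairs)
        mres <- eval_target(target_panels[[config$matched_pop]], meta,
                            mcl, y, config, seed = child_seed(seed, 6, t))
        matched_rows[[length(matched_rows) + 1]] <-
          data.frame(SEED = seed, TRAIT = sprintf("trait%02d_s%d", t, seed),
                     R2_MISMATCHED = best[[config$matched_pop]]$INC_R2,
                     R2_META = best_threshold(mres)$INC_R2,
                     stringsAsFactors = FALSE)
      }
    }
  }
  r2 <- do.call(rbind, r2_rows)
  kept <- r2[r2$KEPT, ]
  ra <- relative_accuracy(data.frame(pop = kept$POP, trait = kept$TRAIT,
                                     r2 = kept$R2), baseline = base)
  list(per_trait = ra$per_trait, per_pop = ra$per_pop, r2 = r2,
       matched = if (length(matched_rows)) do.call(rbind, matched_rows)
       else NULL)
}
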