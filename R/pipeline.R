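#' Simulate a full pooled experiment
#'
#' Runs the generative model end to end: true group frequencies, per-pool
#' read counts, analysis windows, gene intervals, and the ground-truth
#' labels.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_experiment`: `freqs`, `counts` (long
#'   `SiteCounts` over all pools), `windows`, `genes`, `truth`, `config`.
#' @export
simulate_experiment <- function(config) {
  freqs <- simulate_group_frequencies(config)
  counts <- do.call(rbind, lapply(config$pools, function(p)
    simulate_pool_readcounts(freqs, p, config)))
  structure(list(freqs = freqs, counts = counts,
                 windows = make_windows(config),
                 genes = if (config$n_genes > 0) make_genes(config) else NULL,
                 truth = truth_table(config), config = config),
            class = "sim_experiment")
}

#' Group haploid sample sizes for a pool set
#'
#' Pooled statistics use `2 x` the summed diploid individuals of each
#' group's pools as the haploid sample size.
#'
#' @param pools List of [pool_spec()].
#' @return Named integer vector of chromosomes per group.
#' @export
group_n_chrom <- function(pools) {
  grp <- vapply(pools, `[[`, "", "group")
  n <- vapply(pools, `[[`, 0L, "n_individuals")
  2L * vapply(split(n, grp), sum, 0L)
}

#' Windowed statistics per group from pooled counts
#'
#' Applies the site filters, sums read counts across each group's pools,
#' and computes [window_stats()] per group.
#'
#' @param counts Long `SiteCounts` with a `group` column (e.g. from
#'   [simulate_experiment()] or [read_sync()] plus a pool map).
#' @param windows Window table.
#' @param n_chrom Named vector of haploid sample sizes per group (e.g.
#'   [group_n_chrom()]).
#' @param ... Filter options passed to [filter_sites()] and
#'   `min_minor_count` passed to [window_stats()].
#' @param min_minor_count Minimum minor read count for segregating sites.
#' @return Named list of [window_stats()] tables, one per group.
#' @export
group_window_stats <- function(counts, windows, n_chrom,
                               min_minor_count = 2L, ...) {
  combined <- group_counts(counts)
  lapply(setNames(nm = names(n_chrom)), function(g) {
    sub <- combined[combined$group == g, , drop = FALSE]
    flt <- filter_sites(sub, ...)
    window_stats(flt$sites, windows, n_chrom[[g]],
                 min_minor_count = min_minor_count, group = g)
  })
}

#' Sweep scan: permutation test, local FDR and candidate calls
#'
#' Convenience wrapper chaining [observed_difference()],
#' [permutation_test()], [local_fdr()] and [call_candidates()] for one
#' group contrast (conventionally A = wild, B = orchard).
#'
#' @param stats_a,stats_b Per-group [window_stats()] tables on one grid.
#' @param n_perm,seed,mode,alternative Passed to [permutation_test()].
#' @param alpha_run,alpha_single,min_run Passed to [call_candidates()].
#' @param with_lfdr Compute local FDRs (needs >= 50 testable windows).
#' @return List of class `sweep_scan`: `windows` (per-window table with
#'   `delta`, `p_value`, `lfdr`), `calls`, `perm`, `lfdr`.
#' @export
scan_sweeps <- function(stats_a, stats_b, n_perm = 1000L, seed = NULL,
                        mode = "per-window", alternative = "greater",
                        alpha_run = 0.01, alpha_single = 0.001,
                        min_run = 2L, with_lfdr = TRUE) {
  diff <- observed_difference(stats_a, stats_b)
  perm <- permutation_test(stats_a$D, stats_b$D, n_perm = n_perm,
                           seed = seed, mode = mode,
                           alternative = alternative)
  lf <- NULL
  diff$p_value <- perm$p_value
  diff$lfdr <- NA_real_
  ok <- !is.na(perm$p_value)
  if (with_lfdr && sum(ok) >= 50) {
    lf <- local_fdr(perm$p_value[ok])
    diff$lfdr[ok] <- lf$lfdr
  }
  calls <- call_candidates(perm, diff[c("chrom", "start", "end")],
                           alpha_run = alpha_run,
                           alpha_single = alpha_single, min_run = min_run)
  structure(list(windows = diff, calls = calls, perm = perm, lfdr = lf),
            class = "sweep_scan")
}
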