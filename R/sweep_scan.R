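#' Observed between-group Tajima's D difference per window
#'
#' `delta_i = D_A,i - D_B,i` on a shared window grid. Called as
#' `observed_difference(wild, orchard)`, a positive delta marks windows
#' where the orchard spectrum is shifted toward rare variants relative to
#' wild — the sweep-like direction. Missing D on either side propagates.
#'
#' @param stats_a,stats_b [window_stats()] tables on identical grids.
#' @return Data.frame: `chrom`, `start`, `end`, `d_a`, `d_b`, `delta`.
#' @export
observed_difference <- function(stats_a, stats_b) {
  if (nrow(stats_a) != nrow(stats_b))
    stop("window grids differ in length: ", nrow(stats_a), " vs ", nrow(stats_b))
  mism <- which(stats_a$chrom != stats_b$chrom |
                  stats_a$start != stats_b$start | stats_a$end != stats_b$end)
  if (length(mism))
    stop(sprintf("window grids differ first at row %d: %s:%d-%d vs %s:%d-%d",
                 mism[1], stats_a$chrom[mism[1]], stats_a$start[mism[1]],
                 stats_a$end[mism[1]], stats_b$chrom[mism[1]],
                 stats_b$start[mism[1]], stats_b$end[mism[1]]))
  data.frame(stats_a[c("chrom", "start", "end")],
             d_a = stats_a$D, d_b = stats_b$D,
             delta = stats_a$D - stats_b$D, stringsAsFactors = FALSE)
}

#' Permutation test for between-group Tajima's D differences
#'
#' Each permutation independently shuffles the observed D values of each
#' group across window positions and recomputes the per-window difference.
#' In `per-window` mode the p-value counts, at each window, permuted
#' differences at least as large as the observed one, with the +1
#' small-sample correction: `p_i = (1 + #exceed_i) / (1 + n_perm)`. In
#' `pooled-null` mode the observed difference is compared against the
#' shuffled differences from all windows and permutations.
#'
#' When the number of distinct permutation pairs `(n_A!)*(n_B!)` is at most
#' 10,000 (or `exact = TRUE`), the exact distribution is used instead: under
#' independent uniform permutations the shuffled difference at any window is
#' distributed as a uniformly drawn value pair `A_a - B_b`, so exact
#' exceedance probabilities are enumerated over all `n^2` pairs (identical
#' to enumerating every permutation pair).
#'
#' @param d_a,d_b Aligned numeric vectors of window D values (or
#'   [window_stats()] tables, from which `D` is taken). `NA` windows are
#'   excluded from the null and get `NA` p-values.
#' @param n_perm Number of Monte-Carlo permutations (default 1000).
#' @param seed Optional integer seed.
#' @param mode `"per-window"` (default) or `"pooled-null"`.
#' @param alternative `"greater"` (one-sided in the `d_a - d_b` direction,
#'   default) or `"two.sided"` (on `|delta|`).
#' @param exact `"auto"` (default), `TRUE`, or `FALSE`.
#' @return List of class `perm_test`: `delta`, `p_value`, `exceed_count`,
#'   `n_perm` (effective draws), `mode`, `alternative`, `exact`, `seed`.
#' @export
permutation_test <- function(d_a, d_b, n_perm = 1000L, seed = NULL,
                             mode = c("per-window", "pooled-null"),
                             alternative = c("greater", "two.sided"),
                             exact = "auto") {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (is.data.frame(d_a)) d_a <- d_a$D
  if (is.data.frame(d_b)) d_b <- d_b$D
  if (length(d_a) != length(d_b)) stop("tracks differ in length")
  if (n_perm < 1) stop("n_perm must be >= 1")
  ok <- !is.na(d_a) & !is.na(d_b)
  m <- sum(ok)
  if (m < 2) stop("need at least 2 non-missing windows per track")
  a <- d_a[ok]; b <- d_b[ok]
  obs_all <- d_a - d_b
  obs <- obs_all[ok]
  side <- function(x) if (alternative == "two.sided") abs(x) else x
  use_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && factorial(m)^2 <= 10000)
  p <- exceed <- rep(NA_real_, length(d_a))
  if (use_exact) {
    pairs <- side(as.vector(outer(a, b, `-`)))
    sp <- sort(pairs)
    n_eff <- length(pairs)
    ex <- n_eff - findInterval(side(obs) - 1e-12, sp)
    p[ok] <- ex / n_eff
    exceed[ok] <- ex
  } else {
    if (!is.null(seed)) set.seed(seed)
    tobs <- side(obs)
    if (mode == "per-window") {
      ex <- numeric(m)
      for (k in seq_len(n_perm))
        ex <- ex + (side(sample(a) - sample(b)) >= tobs)
      p[ok] <- (1 + ex) / (1 + n_perm)
      exceed[ok] <- ex
      n_eff <- n_perm
    } else {
      all_delta <- numeric(n_perm * m)
      for (k in seq_len(n_perm))
        all_delta[((k - 1) * m + 1):(k * m)] <- sample(a) - sample(b)
      sp <- sort(side(all_delta))
      n_eff <- length(sp)
      ex <- n_eff - findInterval(tobs - 1e-12, sp)
      p[ok] <- (1 + ex) / (1 + n_eff)
      exceed[ok] <- ex
    }
  }
  structure(list(delta = obs_all, p_value = p, exceed_count = exceed,
                 n_perm = n_eff, mode = mode, alternative = alternative,
                 exact = use_exact, seed = seed),
            class = "perm_test")
}

#' Call candidate sweep regions from permutation p-values
#'
#' Two calling rules, applied on the genome-ordered window grid: (1) maximal
#' runs of at least `min_run` adjacent windows with `p <= alpha_run` become
#' one merged call (`consecutive_p01`); (2) isolated windows with
#' `p <= alpha_single` become singleton calls (`single_p001`). Overlaps are
#' merged; resulting calls are disjoint.
#'
#' @param perm A [permutation_test()] result, or a numeric p-value vector.
#' @param windows Window table aligned with the p-values.
#' @param alpha_run Run-rule threshold (default 0.01).
#' @param alpha_single Singleton threshold (default 0.001).
#' @param min_run Minimum run length for the consecutive rule (default 2).
#' @return Data.frame: `chrom`, `start`, `end`, `n_windows`, `min_p`,
#'   `rule`.
#' @export
call_candidates <- function(perm, windows, alpha_run = 0.01,
                            alpha_single = 0.001, min_run = 2L) {
  p <- if (inherits(perm, "perm_test")) perm$p_value else perm
  if (length(p) != nrow(windows)) stop("p-values do not match window grid")
  sig <- !is.na(p) & p <= alpha_run
  calls <- list()
  r <- rle(paste(windows$chrom, sig))
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (j in seq_along(r$lengths)) {
    i0 <- idx_start[j]; i1 <- idx_end[j]
    if (!sig[i0]) next
    len <- i1 - i0 + 1L
    pmin_run <- min(p[i0:i1])
    if (len >= min_run) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = windows$chrom[i0], start = windows$start[i0],
        end = windows$end[i1], n_windows = len, min_p = pmin_run,
        rule = "consecutive_p01", stringsAsFactors = FALSE)
    } else if (pmin_run <= alpha_single) {
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = windows$chrom[i0], start = windows$start[i0],
        end = windows$end[i1], n_windows = len, min_p = pmin_run,
        rule = "single_p001", stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_windows = integer(0),
                      min_p = numeric(0), rule = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, calls)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Histogram-based local false discovery rate
#'
#' Storey's null-proportion estimate at `lambda = 0.5`,
#' `pi0 = min(1, #\{p > 0.5\} / (0.5 m))`, divided by a 20-bin histogram
#' density of the p-values, clipped to \[0, 1\] and made monotone
#' non-decreasing in p by cumulative-maximum regularization.
#'
#' @param p P-values in \[0, 1\]; at least 50 required for the density.
#' @param n_bins Number of equal-width histogram bins (default 20).
#' @return List of class `lfdr_result`: `lfdr` (per input p), `pi0_hat`,
#'   `lambda`, `bin_lfdr`.
#' @export
local_fdr <- function(p, n_bins = 20L) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0,1]")
  m <- length(p)
  if (m < 50) stop("need at least 50 p-values for density estimation")
  pi0 <- min(1, sum(p > 0.5) / (0.5 * m))
  idx <- pmin(floor(p * n_bins) + 1L, n_bins)
  dens <- tabulate(idx, nbins = n_bins) * n_bins / m
  bin_lfdr <- ifelse(dens > 0, pi0 / dens, 1)
  bin_lfdr <- cummax(pmin(pmax(bin_lfdr, 0), 1))
  structure(list(lfdr = bin_lfdr[idx], pi0_hat = pi0, lambda = 0.5,
                 bin_lfdr = bin_lfdr),
            class = "lfdr_result")
}

#' Major-allele fixation outlier scan over 10-gene intervals
#'
#' Annotated genes with SNPs in both groups are ordered along the genome and
#' grouped into consecutive non-overlapping intervals of `interval_size`
#' genes per linkage group (trailing remainders dropped). Per interval,
#' `delta` is the difference of interval-averaged per-gene mean major-allele
#' frequencies (group A minus group B); intervals with
#' `delta > mean + sd_multiplier * SD` (population SD over all intervals
#' genome-wide) are flagged.
#'
#' @param genes_a,genes_b [gene_major_allele_freq()] tables for the two
#'   groups over the same gene set (e.g. orchard and wild).
#' @param interval_size Genes per interval (default 10).
#' @param sd_multiplier Outlier cutoff in SD units; defaults to 3 for the
#'   `"domestication"` contrast and 2 for `"regional"`.
#' @param contrast `"domestication"` or `"regional"`.
#' @param sliding If `TRUE`, use overlapping intervals stepping one gene at
#'   a time instead of disjoint blocks.
#' @return Data.frame: `chrom`, `start`, `end`, `gene_ids`, `n_genes`,
#'   `mean_a`, `mean_b`, `delta`, `z_sd`, `flagged`, `contrast`.
#' @export
fixation_scan <- function(genes_a, genes_b, interval_size = 10L,
                          sd_multiplier = NULL,
                          contrast = c("domestication", "regional"),
                          sliding = FALSE) {
  contrast <- match.arg(contrast)
  if (is.null(sd_multiplier))
    sd_multiplier <- if (contrast == "domestication") 3 else 2
  m <- merge(genes_a[c("gene_id", "chrom", "start", "end", "annotated",
                       "mean_major_freq", "n_snps")],
             genes_b[c("gene_id", "mean_major_freq", "n_snps")],
             by = "gene_id", suffixes = c("_a", "_b"))
  if (nrow(m) < max(nrow(genes_a), nrow(genes_b)))
    stop("gene tables do not cover the same gene set")
  m <- m[m$annotated & m$n_snps_a > 0 & m$n_snps_b > 0 &
           !is.na(m$mean_major_freq_a) & !is.na(m$mean_major_freq_b), ]
  m <- m[order(m$chrom, m$start), ]
  rows <- list()
  for (cc in unique(m$chrom)) {
    g <- m[m$chrom == cc, ]
    n <- nrow(g)
    starts <- if (sliding) seq_len(max(0L, n - interval_size + 1L))
    else seq(1L, n - n %% interval_size, by = interval_size)
    starts <- starts[starts + interval_size - 1L <= n]
    for (s in starts) {
      blk <- g[s:(s + interval_size - 1L), ]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cc, start = min(blk$start), end = max(blk$end),
        gene_ids = paste(blk$gene_id, collapse = ","),
        n_genes = interval_size,
        mean_a = mean(blk$mean_major_freq_a),
        mean_b = mean(blk$mean_major_freq_b), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no complete gene interval: too few usable genes")
  out <- do.call(rbind, rows)
  out$delta <- out$mean_a - out$mean_b
  mu <- mean(out$delta)
  sigma <- sqrt(mean((out$delta - mu)^2))
  if (sigma == 0) {
    warning("all interval deltas identical (SD = 0): no outliers flagged")
    out$z_sd <- NA_real_
    out$flagged <- FALSE
  } else {
    out$z_sd <- (out$delta - mu) / sigma
    out$flagged <- out$z_sd > sd_multiplier
  }
  out$contrast <- contrast
  out
}
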