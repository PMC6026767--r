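#' Filter pooled SNP sites and tally summary statistics
#'
#' A *variant site* has read depth above `min_depth` and at least one
#' alternate read. The tally reports, in the style of a per-pool sequencing
#' summary: the variant-site count, the count of variant sites whose
#' alternate-allele frequency is at least `min_alt_freq`, and the mean depth
#' at variant sites. The returned table keeps variant sites passing the
#' stricter `coverage_floor` used by all downstream window and gene
#' statistics.
#'
#' @param sites `SiteCounts` data.frame with columns `ref_count`,
#'   `alt_count` (and any coordinate/pool columns, carried through).
#' @param min_depth Variant sites must have depth strictly above this
#'   (default 6).
#' @param min_alt_freq Alternate-frequency threshold for the second tally
#'   (default 0.2).
#' @param coverage_floor Minimum depth for sites entering downstream
#'   statistics (default 8).
#' @return List of class `site_filter`: `sites` (filtered table) and
#'   `tally` (`n_variant`, `n_alt_ge_threshold`, `mean_depth_variant`).
#' @export
filter_sites <- function(sites, min_depth = 6L, min_alt_freq = 0.2,
                         coverage_floor = 8L) {
  if (min_depth < 0) stop("min_depth must be >= 0")
  if (min_alt_freq < 0 || min_alt_freq > 1) stop("min_alt_freq must be in [0,1]")
  if (nrow(sites) && (any(sites$ref_count < 0) || any(sites$alt_count < 0)))
    stop("negative read counts")
  depth <- sites$ref_count + sites$alt_count
  variant <- depth > min_depth & sites$alt_count > 0
  tally <- list(
    n_variant = sum(variant),
    n_alt_ge_threshold =
      sum(variant & sites$alt_count >= min_alt_freq * depth),
    mean_depth_variant = if (any(variant)) mean(depth[variant]) else 0)
  keep <- sites$alt_count > 0 & depth >= coverage_floor
  structure(list(sites = sites[keep, , drop = FALSE], tally = tally),
            class = "site_filter")
}

#' Sum read counts across the pools of each group
#'
#' Group-level allele-frequency estimates are made from read counts summed
#' site-wise across a group's pools, mirroring group-level pileups.
#'
#' @param sites Long `SiteCounts` data.frame with a `group` column (as
#'   produced by [simulate_pool_readcounts()] or [read_sync()] plus a
#'   pool-to-group mapping).
#' @param pool_groups Optional named character vector mapping `pool_id` to
#'   group, used when `sites` lacks a `group` column.
#' @return `SiteCounts` data.frame with one row per (site, group) and
#'   `pool_id` set to the group label.
#' @export
group_counts <- function(sites, pool_groups = NULL) {
  if (is.null(sites$group)) {
    if (is.null(pool_groups)) stop("need a group column or pool_groups map")
    miss <- setdiff(unique(sites$pool_id), names(pool_groups))
    if (length(miss)) stop("pools without group assignment: ",
                           paste(miss, collapse = ", "))
    sites$group <- unname(pool_groups[sites$pool_id])
  }
  key <- interaction(sites$chrom, sites$pos, sites$group, drop = TRUE)
  first <- !duplicated(key)
  out <- sites[first, c("chrom", "pos", "ref_allele", "alt_allele", "group")]
  rs_ref <- rowsum(sites$ref_count, key)
  rs_alt <- rowsum(sites$alt_count, key)
  out$ref_count <- rs_ref[as.character(key[first]), 1]
  out$alt_count <- rs_alt[as.character(key[first]), 1]
  out$pool_id <- out$group
  rownames(out) <- NULL
  out[order(out$group, out$chrom, out$pos),
      c("chrom", "pos", "ref_allele", "alt_allele",
        "ref_count", "alt_count", "pool_id", "group")]
}

assign_windows <- function(chrom, pos, windows) {
  idx <- rep(NA_integer_, length(pos))
  for (cc in unique(windows$chrom)) {
    w <- which(windows$chrom == cc)
    s <- which(chrom == cc)
    if (!length(s)) next
    j <- findInterval(pos[s] - 1L, windows$start[w])
    ok <- j >= 1L & (pos[s] - 1L) < windows$end[w][pmax(j, 1L)]
    idx[s[ok]] <- w[j[ok]]
  }
  idx
}

#' Windowed pooled diversity statistics
#'
#' Computes, per window and for one pool group: the segregating-site count
#' `S` (sites with both alleles seen and minor read count at least
#' `min_minor_count`), the pi sum over sites (unbiased per-site
#' heterozygosity, [site_pi()]), pi per bp, and Tajima's D from `S`, pi and
#' the Tajima constants at `n_chrom`. `D` is `NA` where `S = 0`.
#'
#' @param sites Filtered `SiteCounts` for a single pool or group.
#' @param windows Window table (`chrom`, `start`, `end`; 0-based half-open),
#'   e.g. from [make_windows()].
#' @param n_chrom Haploid sample size of the pool group (2 x diploids).
#' @param min_minor_count Minimum minor-allele read count for a site to be
#'   called segregating (default 2).
#' @param group Group label for the output (default: from `sites`).
#' @return Data.frame: `chrom`, `start`, `end`, `group`, `S`, `pi`,
#'   `pi_per_bp`, `D`, `n_sites`.
#' @export
window_stats <- function(sites, windows, n_chrom, min_minor_count = 2L,
                         group = NULL) {
  if (n_chrom < 4) stop("n_chrom must be >= 4 for windowed Tajima's D")
  if (is.null(group))
    group <- if (nrow(sites)) as.character(sites$pool_id[1]) else NA_character_
  wi <- assign_windows(sites$chrom, sites$pos, windows)
  if (nrow(sites) && anyNA(wi))
    sites <- sites[!is.na(wi), , drop = FALSE]
  wi <- wi[!is.na(wi)]
  depth <- sites$ref_count + sites$alt_count
  seg <- sites$ref_count > 0 & sites$alt_count > 0 &
    pmin(sites$ref_count, sites$alt_count) >= min_minor_count
  pi_site <- numeric(nrow(sites))
  if (any(seg))
    pi_site[seg] <- site_pi(sites$ref_count[seg], sites$alt_count[seg], n_chrom)
  nw <- nrow(windows)
  S <- tabulate(wi[seg], nbins = nw)
  n_sites <- tabulate(wi, nbins = nw)
  pi_sum <- numeric(nw)
  if (length(wi)) {
    agg <- rowsum(pi_site, wi)
    pi_sum[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             group = group, S = S, pi = pi_sum,
             pi_per_bp = pi_sum / (windows$end - windows$start),
             D = tajima_d(S, pi_sum, n_chrom), n_sites = n_sites,
             stringsAsFactors = FALSE)
}

#' Per-gene mean major-allele frequency
#'
#' For each gene interval, the major-allele frequency `max(p, 1-p)` is
#' averaged over the filtered SNPs falling in the gene, using group-level
#' read counts. Genes with no SNPs get `NA` and are excluded from the
#' downstream fixation scan.
#'
#' @param sites Filtered group-level `SiteCounts` (one group).
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`,
#'   `annotated`; 0-based half-open), e.g. from [make_genes()] or
#'   [read_intervals()].
#' @param group Group label for the output.
#' @return Data.frame: `gene_id`, `chrom`, `start`, `end`, `annotated`,
#'   `group`, `mean_major_freq`, `n_snps`.
#' @export
gene_major_allele_freq <- function(sites, genes, group = NULL) {
  if (any(genes$start >= genes$end)) stop("malformed gene interval")
  if (is.null(group))
    group <- if (nrow(sites)) as.character(sites$pool_id[1]) else NA_character_
  gi <- assign_windows(sites$chrom, sites$pos, genes)
  keep <- !is.na(gi)
  depth <- sites$ref_count + sites$alt_count
  p <- ifelse(depth > 0, sites$alt_count / depth, NA_real_)
  major <- pmax(p, 1 - p)
  ng <- nrow(genes)
  n_snps <- tabulate(gi[keep & !is.na(major)], nbins = ng)
  msum <- numeric(ng)
  sel <- keep & !is.na(major)
  if (any(sel)) {
    agg <- rowsum(major[sel], gi[sel])
    msum[as.integer(rownames(agg))] <- agg[, 1]
  }
  data.frame(genes[c("gene_id", "chrom", "start", "end", "annotated")],
             group = group,
             mean_major_freq = ifelse(n_snps > 0, msum / n_snps, NA_real_),
             n_snps = n_snps, stringsAsFactors = FALSE)
}
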