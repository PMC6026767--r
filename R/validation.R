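#' Genotype set container
#'
#' Individual diploid genotypes: a matrix of alternate-allele dosages
#' (individuals x sites, values 0/1/2 or `NA`), site coordinates, and a
#' group label per individual.
#'
#' @param geno Integer matrix with individual row names.
#' @param sites Data.frame with `chrom`, `pos` (1-based), one row per
#'   matrix column.
#' @param groups Named character vector, one group per individual.
#' @return List of class `genotype_set`.
#' @export
genotype_set <- function(geno, sites, groups) {
  if (ncol(geno) != nrow(sites)) stop("sites do not match genotype columns")
  if (is.null(rownames(geno))) stop("genotype matrix needs individual ids")
  miss <- setdiff(rownames(geno), names(groups))
  if (length(miss)) stop("individuals without group: ",
                         paste(miss, collapse = ", "))
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    stop("genotype dosages must be 0, 1, 2 or NA")
  structure(list(geno = geno, sites = sites,
                 groups = groups[rownames(geno)]),
            class = "genotype_set")
}

gene_site_cols <- function(gt, gene) {
  which(gt$sites$chrom == gene$chrom &
          gt$sites$pos - 1L >= gene$start & gt$sites$pos - 1L < gene$end)
}

#' Per-gene diversity statistics from individual genotypes
#'
#' For one gene interval and one group: per-site pi
#' `2*p*q * 2N/(2N-1)` with `2N` the called chromosomes at the site,
#' summed over sites and divided by interval length (`pi_per_bp`);
#' segregating-site count `S`; Tajima's D using the Tajima constants at the
#' median called-chromosome count across the gene's sites; and mean
#' per-individual heterozygosity (heterozygous / called sites in the gene).
#'
#' @param gt A [genotype_set()].
#' @param gene One-row gene interval (`gene_id`, `chrom`, `start`, `end`;
#'   0-based half-open).
#' @param group Group label.
#' @return One-row data.frame: `gene_id`, `group`, `S`, `pi`, `pi_per_bp`,
#'   `tajima_d`, `het_mean`, `n_sites`, `n_chrom_median`. All statistics
#'   `NA` when the gene has no called sites.
#' @export
gene_diversity <- function(gt, gene, group) {
  stopifnot(inherits(gt, "genotype_set"))
  if (!group %in% gt$groups) stop("unknown group: ", group)
  ind <- names(gt$groups)[gt$groups == group]
  if (length(ind) < 2) stop("need >= 2 individuals with calls in the group")
  cols <- gene_site_cols(gt, gene)
  sub <- gt$geno[ind, cols, drop = FALSE]
  called <- colSums(!is.na(sub))
  use <- called >= 1L
  empty <- data.frame(gene_id = gene$gene_id, group = group, S = NA_integer_,
                      pi = NA_real_, pi_per_bp = NA_real_,
                      tajima_d = NA_real_, het_mean = NA_real_,
                      n_sites = 0L, n_chrom_median = NA_real_,
                      stringsAsFactors = FALSE)
  if (!length(cols) || !any(use)) return(empty)
  sub <- sub[, use, drop = FALSE]
  called <- called[use]
  n2 <- 2 * called
  ac <- colSums(sub, na.rm = TRUE)
  p <- ac / n2
  seg <- p > 0 & p < 1
  pi_site <- ifelse(n2 >= 2, 2 * p * (1 - p) * n2 / pmax(n2 - 1, 1), 0)
  pi_site[!seg] <- 0
  pi_sum <- sum(pi_site)
  S <- sum(seg)
  n_med <- round(median(n2))
  D <- if (S > 0 && n_med >= 4) tajima_d(S, pi_sum, n_med) else NA_real_
  ncall <- rowSums(!is.na(sub))
  het <- rowSums(sub == 1, na.rm = TRUE) / ncall
  het_mean <- mean(het[ncall > 0])
  data.frame(gene_id = gene$gene_id, group = group, S = S, pi = pi_sum,
             pi_per_bp = pi_sum / (gene$end - gene$start), tajima_d = D,
             het_mean = het_mean, n_sites = length(called),
             n_chrom_median = n_med, stringsAsFactors = FALSE)
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# n1, n2: called individuals; p1, p2: alternate-allele frequencies;
# h1, h2: observed heterozygote proportions. Vectorized over sites.
wc84_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  list(a = a, b = b, c = c)
}

#' Per-gene Weir-Cockerham F_ST between two groups
#'
#' Weir & Cockerham's (1984) two-population estimator: per-site variance
#' components `a` (among populations), `b` (among individuals within
#' populations) and `c` (within individuals) are computed from sample
#' sizes, allele frequencies and observed heterozygote counts, then
#' combined as a gene-level ratio of sums `sum(a) / sum(a+b+c)`.
#' Monomorphic sites are skipped; negative estimates are reported raw.
#'
#' @param gt A [genotype_set()].
#' @param gene One-row gene interval.
#' @param group_a,group_b Group labels.
#' @return One-row data.frame: `gene_id`, `fst`, `sum_a`, `sum_b`, `sum_c`,
#'   `n_sites_used`.
#' @export
gene_fst <- function(gt, gene, group_a, group_b) {
  stopifnot(inherits(gt, "genotype_set"))
  ia <- names(gt$groups)[gt$groups == group_a]
  ib <- names(gt$groups)[gt$groups == group_b]
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 individuals with calls in each group")
  cols <- gene_site_cols(gt, gene)
  out <- data.frame(gene_id = gene$gene_id, fst = NA_real_, sum_a = NA_real_,
                    sum_b = NA_real_, sum_c = NA_real_, n_sites_used = 0L,
                    stringsAsFactors = FALSE)
  if (!length(cols)) return(out)
  ga <- gt$geno[ia, cols, drop = FALSE]
  gb <- gt$geno[ib, cols, drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  ok <- n1 >= 1 & n2 >= 1
  p1 <- colSums(ga, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(gb, na.rm = TRUE) / (2 * n2)
  pbar_n <- colSums(ga, na.rm = TRUE) + colSums(gb, na.rm = TRUE)
  poly <- ok & pbar_n > 0 & pbar_n < 2 * (n1 + n2)
  if (!any(poly)) return(out)
  h1 <- colSums(ga == 1, na.rm = TRUE) / n1
  h2 <- colSums(gb == 1, na.rm = TRUE) / n2
  comp <- wc84_components(n1[poly], n2[poly], p1[poly], p2[poly],
                          h1[poly], h2[poly])
  sa <- sum(comp$a); sb <- sum(comp$b); sc <- sum(comp$c)
  denom <- sa + sb + sc
  out$fst <- if (denom != 0) sa / denom else NA_real_
  out$sum_a <- sa; out$sum_b <- sb; out$sum_c <- sc
  out$n_sites_used <- sum(poly)
  out
}

#' Ratio of nucleotide diversities (wild over domesticated)
#'
#' The factor by which diversity in the wild comparator exceeds diversity
#' in the domesticated group. A zero denominator yields `Inf` (flagged
#' infinite) rather than an error.
#'
#' @param pi_wild_species,pi_domesticated Non-negative diversities
#'   (vectorized).
#' @return Numeric ratio(s); `Inf` where the denominator is 0.
#' @export
pi_ratio <- function(pi_wild_species, pi_domesticated) {
  if (any(pi_wild_species < 0, na.rm = TRUE) ||
      any(pi_domesticated < 0, na.rm = TRUE))
    stop("diversities must be non-negative")
  ifelse(pi_domesticated == 0, Inf, pi_wild_species / pi_domesticated)
}

#' Support verdict for candidate sweep genes
#'
#' A candidate gene is *supported* when its Tajima's D is negative AND its
#' per-bp diversity and mean heterozygosity both fall below the genome-wide
#' lower quantiles (default quartiles) computed over all genes with data.
#' Genes with missing statistics get `"insufficient_data"`.
#'
#' @param stats Per-gene [gene_diversity()] table over all genes (one
#'   group).
#' @param candidates Character vector of candidate gene ids.
#' @param d_max Tajima's D must be strictly below this (default 0).
#' @param pi_quantile,het_quantile Genome-wide quantile thresholds
#'   (default 0.25).
#' @return Data.frame: `gene_id`, `verdict`, with the thresholds as
#'   attributes `pi_threshold`, `het_threshold`.
#' @export
candidate_support <- function(stats, candidates, d_max = 0,
                              pi_quantile = 0.25, het_quantile = 0.25) {
  ok <- !is.na(stats$pi_per_bp) & !is.na(stats$het_mean)
  pi_thr <- quantile(stats$pi_per_bp[ok], pi_quantile, names = FALSE)
  het_thr <- quantile(stats$het_mean[ok], het_quantile, names = FALSE)
  idx <- match(candidates, stats$gene_id)
  verdict <- vapply(idx, function(i) {
    if (is.na(i) || is.na(stats$tajima_d[i]) || is.na(stats$pi_per_bp[i]) ||
        is.na(stats$het_mean[i])) return("insufficient_data")
    if (stats$tajima_d[i] < d_max && stats$pi_per_bp[i] < pi_thr &&
        stats$het_mean[i] < het_thr) "supported" else "not_supported"
  }, "")
  structure(data.frame(gene_id = candidates, verdict = verdict,
                       stringsAsFactors = FALSE),
            pi_threshold = pi_thr, het_threshold = het_thr)
}
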