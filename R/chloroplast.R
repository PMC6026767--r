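#' Bin chloroplast SNP alternate-allele frequencies
#'
#' Tallies SNPs into frequency bins of width `bin_width` with centers
#' `bin_width, 2*bin_width, ..., 1.0` (default centers 0.10-1.00, spanning
#' 10-100% alternate frequency). Bins are half-open
#' `[center - w/2, center + w/2)`, lower-edge inclusive, with the top bin
#' closed at 1.0. SNPs below the lowest edge are dropped.
#'
#' @param snps `CpSnp` data.frame: `pos`, `alt_freq` in (0, 1\], `pool_id`.
#' @param bin_width Bin width; `1/bin_width` must be whole (default 0.10).
#' @return List of class `freq_histogram`: `pool_id`, `centers`, `counts`,
#'   `members` (list of member SNP positions per bin).
#' @export
bin_frequencies <- function(snps, bin_width = 0.10) {
  k <- 1 / bin_width
  if (abs(k - round(k)) > 1e-9)
    stop("bin_width must divide the (0.05, 1.05] span evenly")
  k <- as.integer(round(k))
  if (nrow(snps) && (any(snps$alt_freq <= 0) || any(snps$alt_freq > 1)))
    stop("alt_freq must be in (0, 1]")
  pool <- if (nrow(snps)) as.character(snps$pool_id[1]) else NA_character_
  centers <- round(seq_len(k) * bin_width, 10)
  keep <- snps$alt_freq >= bin_width / 2
  f <- snps$alt_freq[keep]
  pos <- snps$pos[keep]
  idx <- pmin(floor((f - bin_width / 2) / bin_width + 1e-9) + 1L, k)
  structure(list(
    pool_id = pool, centers = centers,
    counts = tabulate(idx, nbins = k),
    members = lapply(seq_len(k), function(b) sort(pos[idx == b]))),
    class = "freq_histogram")
}

#' Detect haplotype peaks in a binned frequency histogram
#'
#' A bin is a peak when its SNP count is at least `min_snps` and strictly
#' exceeds both neighbors (a missing neighbor counts as 0). The top bin
#' (frequency 1.0, a fixed non-reference haplotype) is always reported when
#' it holds at least `min_snps` SNPs. The peak's bin center estimates the
#' haplotype frequency in the pool and its SNP count the haplotype's
#' divergence from the reference.
#'
#' @param hist A [bin_frequencies()] result.
#' @param min_snps Minimum SNP support for a peak (default 30).
#' @return Data.frame of class `haplotype_peaks`, sorted by `snp_count`
#'   descending: `pool_id`, `freq_estimate`, `snp_count`, `snp_set`
#'   (list-column of member positions).
#' @export
detect_peaks <- function(hist, min_snps = 30L) {
  stopifnot(inherits(hist, "freq_histogram"))
  ct <- hist$counts
  k <- length(ct)
  left <- c(0, ct[-k])
  right <- c(ct[-1], 0)
  is_peak <- ct >= min_snps & ct > left & ct > right
  is_peak[k] <- ct[k] >= min_snps
  idx <- which(is_peak)
  out <- data.frame(pool_id = rep(hist$pool_id, length(idx)),
                    freq_estimate = hist$centers[idx],
                    snp_count = ct[idx], stringsAsFactors = FALSE)
  out$snp_set <- hist$members[idx]
  out <- out[order(-out$snp_count), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("haplotype_peaks", "data.frame")
  out
}

#' Match haplotype peaks across pools by SNP-set overlap
#'
#' Two peaks from different pools are called the same haplotype when the
#' Jaccard similarity of their member SNP sets reaches `jaccard_threshold`.
#' Haplotype groups are the connected components of the match graph; each
#' group reports its mean SNP count and the per-pool frequency estimates.
#'
#' @param peaks One [detect_peaks()] table or a list of them (concatenated).
#' @param jaccard_threshold Minimum Jaccard similarity (default 0.5).
#' @return List: `matches` (data.frame `pool_i`, `freq_i`, `pool_j`,
#'   `freq_j`, `jaccard`, `same_haplotype`), `groups` (data.frame
#'   `haplotype`, `n_peaks`, `mean_snp_count`, `pools`), `membership`
#'   (per-peak group id alongside the concatenated peak table).
#' @export
match_peaks <- function(peaks, jaccard_threshold = 0.5) {
  if (is.list(peaks) && !is.data.frame(peaks))
    peaks <- do.call(rbind, peaks)
  n <- nrow(peaks)
  if (!n) stop("no peaks to match")
  if (any(lengths(peaks$snp_set) == 0)) stop("peak with empty snp_set")
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || peaks$pool_id[i] == peaks$pool_id[j]) next
    si <- peaks$snp_set[[i]]; sj <- peaks$snp_set[[j]]
    jac <- length(intersect(si, sj)) / length(union(si, sj))
    pairs[[length(pairs) + 1L]] <- data.frame(
      i = i, j = j, pool_i = peaks$pool_id[i],
      freq_i = peaks$freq_estimate[i], pool_j = peaks$pool_id[j],
      freq_j = peaks$freq_estimate[j], jaccard = jac,
      same_haplotype = jac >= jaccard_threshold, stringsAsFactors = FALSE)
  }
  matches <- if (length(pairs)) do.call(rbind, pairs)
  else data.frame(i = integer(0), j = integer(0), pool_i = character(0),
                  freq_i = numeric(0), pool_j = character(0),
                  freq_j = numeric(0), jaccard = numeric(0),
                  same_haplotype = logical(0), stringsAsFactors = FALSE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  ed <- matches[matches$same_haplotype, c("i", "j")]
  if (nrow(ed))
    g <- igraph::add_edges(g, as.vector(t(as.matrix(ed))))
  comp <- igraph::components(g)$membership
  groups <- do.call(rbind, lapply(sort(unique(comp)), function(h) {
    sel <- comp == h
    data.frame(haplotype = h, n_peaks = sum(sel),
               mean_snp_count = mean(peaks$snp_count[sel]),
               pools = paste(sprintf("%s:%.2f", peaks$pool_id[sel],
                                     peaks$freq_estimate[sel]),
                             collapse = ";"), stringsAsFactors = FALSE)
  }))
  member <- peaks
  member$haplotype <- comp
  list(matches = matches[, setdiff(names(matches), c("i", "j"))],
       groups = groups, membership = member)
}
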