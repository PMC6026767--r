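# Independent oracles, coded separately from the package implementation.

# Tajima (1989) D computed from scratch: explicit loops for the harmonic
# sums and the textbook sequence of coefficient definitions.
oracle_tajima_d <- function(S, pi_sum, n) {
  if (S == 0) return(NA_real_)
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) {
    a1 <- a1 + 1 / i
    a2 <- a2 + 1 / i^2
  }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  theta_w <- S / a1
  (pi_sum - theta_w) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Average pairwise difference among n_chrom chromosomes of which alt_n carry
# the alternate allele, by explicit enumeration of all chromosome pairs.
oracle_pairwise_pi <- function(alt_n, n_chrom) {
  chroms <- c(rep(1L, alt_n), rep(0L, n_chrom - alt_n))
  diff_pairs <- 0L
  total <- 0L
  for (i in 1:(n_chrom - 1)) for (j in (i + 1):n_chrom) {
    diff_pairs <- diff_pairs + (chroms[i] != chroms[j])
    total <- total + 1L
  }
  diff_pairs / total
}

# Weir & Cockerham (1984) single-site variance components, scalar,
# transcribed independently from the published component formulas.
oracle_wc84_site <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  sum_sq <- n1^2 + n2^2
  nc <- (r * nbar - sum_sq / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nc) * (ssq - 1 / (nbar - 1) *
                        (pbar * (1 - pbar) - ssq * (r - 1) / r - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - ssq * (r - 1) / r -
                              hbar * (2 * nbar - 1) / (4 * nbar))
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

# Per-window D computed directly from a filtered site table, re-deriving
# S and the pi sum with its own arithmetic (no package calls).
oracle_window_d <- function(ref, alt, n_chrom, min_minor = 2L) {
  seg <- ref > 0 & alt > 0 & pmin(ref, alt) >= min_minor
  ref <- ref[seg]; alt <- alt[seg]
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  p <- alt / (ref + alt)
  pi_sum <- sum(2 * p * (1 - p)) * n_chrom / (n_chrom - 1)
  oracle_tajima_d(S, pi_sum, n_chrom)
}

# Small SiteCounts builder for hand-made fixtures.
make_sites <- function(pos, ref_count, alt_count, chrom = "lg01",
                       pool_id = "poolA") {
  data.frame(chrom = rep(chrom, length(pos)), pos = pos,
             ref_allele = rep("A", length(pos)),
             alt_allele = rep("C", length(pos)),
             ref_count = ref_count, alt_count = alt_count,
             pool_id = rep(pool_id, length(pos)), stringsAsFactors = FALSE)
}
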