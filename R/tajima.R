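#' Tajima (1989) normalizing constants
#'
#' Coefficients used to standardize the difference between pairwise
#' nucleotide diversity (pi) and Watterson's estimator of theta for a sample
#' of `n` chromosomes.
#'
#' @param n Haploid sample size (number of sampled chromosomes), `n >= 2`.
#'   For pooled data this is twice the number of diploid individuals in the
#'   pool group.
#' @return A list of class `tajima_constants` with elements `n`, `a1`, `a2`,
#'   `b1`, `b2`, `c1`, `c2`, `e1`, `e2`.
#' @examples
#' tajima_constants(20)$a1  # sum of 1/i for i in 1..19
#' @export
tajima_constants <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2 || n != round(n))
    stop("n must be a single integer >= 2")
  n <- as.numeric(n)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2),
            class = "tajima_constants")
}

#' Tajima's D from a segregating-site count and a pi sum
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))`. Returns `NA` where `S = 0`
#' (the statistic is undefined without polymorphism); at `S = 1` the
#' denominator reduces to `sqrt(e1)`.
#'
#' @param S Number of segregating sites (vectorized).
#' @param pi_sum Sum over sites of per-site heterozygosity (vectorized).
#' @param n Haploid sample size, or a [tajima_constants()] object.
#' @return Numeric vector of D values, `NA` where undefined.
#' @export
tajima_d <- function(S, pi_sum, n) {
  k <- if (inherits(n, "tajima_constants")) n else tajima_constants(n)
  if (any(S < 0, na.rm = TRUE)) stop("S must be non-negative")
  denom <- sqrt(k$e1 * S + k$e2 * S * (S - 1))
  d <- (pi_sum - S / k$a1) / denom
  d[is.na(S) | S == 0] <- NA_real_
  d
}

#' Per-site unbiased heterozygosity from pooled read counts
#'
#' Estimates allele frequency as `p = alt/(ref+alt)` and returns
#' `2*p*(1-p) * n/(n-1)`, the small-sample-corrected expected
#' heterozygosity for `n` sampled chromosomes (equivalently, the average
#' pairwise difference at this site).
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @param n_chrom Haploid sample size, `>= 2`.
#' @return Numeric vector of per-site pi values.
#' @examples
#' site_pi(10, 10, 20)  # 10*10 / choose(20, 2)
#' @export
site_pi <- function(ref_count, alt_count, n_chrom) {
  if (n_chrom < 2) stop("n_chrom must be >= 2")
  if (any(ref_count < 0) || any(alt_count < 0)) stop("negative read counts")
  depth <- ref_count + alt_count
  if (any(depth == 0)) stop("site with zero depth: filter before computing pi")
  p <- alt_count / depth
  2 * p * (1 - p) * n_chrom / (n_chrom - 1)
}
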