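toy_windows <- function(n, chrom = "lg01") {
  data.frame(chrom = chrom, start = (seq_len(n) - 1) * 10000,
             end = seq_len(n) * 10000, stringsAsFactors = FALSE)
}

toy_stats <- function(D, chrom = "lg01") {
  w <- toy_windows(length(D), chrom)
  data.frame(w, group = "g", S = 10L, pi = 1, pi_per_bp = 1e-4, D = D,
             n_sites = 10L, stringsAsFactors = FALSE)
}

test_that("observed difference is D_A - D_B with missing propagation", {
  a <- toy_stats(c(1.23, 0.5, NA))
  b <- toy_stats(c(-1.65, 0.5, 0.1))
  d <- observed_difference(a, b)
  expect_equal(d$delta[1], 2.88)       # wild 1.23 vs orchard -1.65
  expect_equal(d$delta[2], 0)
  expect_true(is.na(d$delta[3]))
  expect_equal(observed_difference(a, a)$delta[1:2], c(0, 0))
  b2 <- toy_stats(c(-1.65, 0.5, 0.1), chrom = "lg02")
  expect_error(observed_difference(a, b2), "first at row 1")
})

test_that("constant tracks give p = 1 everywhere under >= counting", {
  a <- toy_stats(rep(0.7, 5))
  b <- toy_stats(rep(-0.2, 5))
  pt <- permutation_test(a, b, n_perm = 50, seed = 1, exact = FALSE)
  expect_true(all(pt$p_value == 1))
  pe <- permutation_test(a, b, exact = TRUE)
  expect_true(all(pe$p_value == 1))
})

test_that("exhaustive enumeration reproduces the 3-window toy exactly", {
  # orchard (0, 0, -3), wild (0, 0, 0): 2 of the 6 orchard assignments put
  # -3 at window 3, so raw p there is 2/6 without the +1 correction.
  wild <- c(0, 0, 0)
  orchard <- c(0, 0, -3)
  pt <- permutation_test(wild, orchard)   # auto-exact at 3 windows
  expect_true(pt$exact)
  expect_equal(pt$p_value[3], 2 / 6, tolerance = 1e-12)
  expect_equal(pt$p_value[1], 1)          # delta 0, >= counting over pairs
})

test_that("Monte-Carlo p agrees with exhaustive p on toy tracks up to 6 windows", {
  set.seed(23)
  for (n in 3:6) {
    a <- round(rnorm(n), 2)
    b <- round(rnorm(n), 2)
    pe <- permutation_test(a, b, exact = TRUE)
    pm <- permutation_test(a, b, n_perm = 5000, seed = n, exact = FALSE)
    se <- sqrt(pe$p_value * (1 - pe$p_value) / 5000)
    expect_true(all(abs(pm$p_value - pe$p_value) <= 3 * se + 1 / 5001))
  }
})

test_that("pooled-null mode compares each window against all shuffled deltas", {
  a <- c(0, 0, 0, 0, 5)
  b <- c(0, 0, 0, 0, 0)
  pt <- permutation_test(a, b, n_perm = 200, seed = 2, mode = "pooled-null",
                         exact = FALSE)
  # the extreme window is exceeded only when 5 lands at it: ~1/5 of draws
  expect_lt(pt$p_value[5], 0.3)
  expect_gt(pt$p_value[5], 0.1)
  expect_error(permutation_test(a, b, n_perm = 0), "n_perm")
})

test_that("permutation p-values are null-uniform (KS) on exchangeable tracks", {
  set.seed(301)
  a <- rnorm(2000)
  b <- rnorm(2000)
  pt <- permutation_test(a, b, n_perm = 500, seed = 302, exact = FALSE)
  ks <- suppressWarnings(ks.test(pt$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("candidate calling applies the run and singleton rules", {
  p <- c(0.5, 0.005, 0.008, 0.2, 0.0009, 0.5)
  w <- toy_windows(6)
  calls <- call_candidates(p, w)
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$rule, c("consecutive_p01", "single_p001"))
  expect_equal(calls$start, c(10000, 40000))
  expect_equal(calls$end, c(30000, 50000))

  expect_equal(nrow(call_candidates(rep(0.5, 6), w)), 0L)

  run3 <- call_candidates(c(0.5, 0.004, 0.004, 0.004, 0.5, 0.5), w)
  expect_equal(nrow(run3), 1L)
  expect_equal(run3$end - run3$start, 30000)
  expect_equal(run3$n_windows, 3L)

  # isolated window at 0.005 (> 0.001) is not called
  lone <- call_candidates(c(0.5, 0.005, 0.5, 0.5, 0.5, 0.5), w)
  expect_equal(nrow(lone), 0L)

  # runs do not leak across chromosome boundaries
  w2 <- rbind(toy_windows(3), toy_windows(3, "lg02"))
  cross <- call_candidates(c(0.5, 0.5, 0.004, 0.004, 0.5, 0.5), w2)
  expect_equal(nrow(cross), 0L)
})

test_that("candidate calls are disjoint after merging", {
  set.seed(55)
  p <- runif(400)^3
  w <- toy_windows(400)
  calls <- call_candidates(p, w)
  if (nrow(calls) > 1) {
    ord <- order(calls$chrom, calls$start)
    calls <- calls[ord, ]
    same <- calls$chrom[-1] == calls$chrom[-nrow(calls)]
    expect_true(all(!same | calls$start[-1] >= calls$end[-nrow(calls)]))
  }
})

test_that("local FDR recovers pi0 and is monotone in p", {
  set.seed(77)
  p_null <- runif(1800)
  p_alt <- rbeta(200, 0.1, 1)
  lf <- local_fdr(c(p_null, p_alt))
  expect_gte(lf$pi0_hat, 0.8)
  expect_lte(lf$pi0_hat, 1.0)
  expect_true(all(diff(lf$bin_lfdr) >= 0))
  expect_true(all(lf$lfdr >= 0 & lf$lfdr <= 1))

  expect_equal(local_fdr(runif(100, 0.51, 1))$pi0_hat, 1)
  half <- c(runif(50, 0, 0.5), runif(50, 0.500001, 1))
  expect_equal(local_fdr(half)$pi0_hat, 1)
  expect_error(local_fdr(c(runif(60), 1.2)), "in \\[0,1\\]")
  expect_error(local_fdr(runif(10)), "at least 50")
})

make_gene_freq <- function(means, n_snps = 5L) {
  n <- length(means)
  data.frame(gene_id = sprintf("g%04d", seq_len(n)), chrom = "lg01",
             start = (seq_len(n) - 1) * 1000, end = seq_len(n) * 1000 - 100,
             annotated = TRUE, group = "x", mean_major_freq = means,
             n_snps = n_snps, stringsAsFactors = FALSE)
}

test_that("fixation scan flags the constructed outlier interval and no other", {
  base <- rep(0.7, 1000)
  a <- make_gene_freq(base)
  b <- make_gene_freq(base)
  # one 10-gene interval (genes 501-510) raised by 0.35 in group A
  a$mean_major_freq[501:510] <- 0.7 + 0.35
  fs <- fixation_scan(a, b, sd_multiplier = 3)
  expect_equal(nrow(fs), 100L)
  expect_equal(sum(fs$flagged), 1L)
  expect_equal(which(fs$flagged), 51L)
  expect_equal(fs$delta[51], 0.35, tolerance = 1e-12)
  mu <- 0.35 / 100
  sigma <- sqrt((99 * mu^2 + (0.35 - mu)^2) / 100)
  expect_equal(fs$z_sd[51], (0.35 - mu) / sigma, tolerance = 1e-9)
  expect_gt(fs$delta[51], mu + 3 * sigma)

  ident <- expect_warning(fixation_scan(a, a), "SD = 0")
  expect_equal(sum(ident$flagged), 0L)
})

test_that("fixation scan is invariant under adding a constant to both groups", {
  set.seed(13)
  means <- runif(300, 0.5, 0.9)
  shift <- rnorm(300, 0, 0.01)
  a <- make_gene_freq(pmin(means + pmax(shift, 0), 1))
  b <- make_gene_freq(means)
  f1 <- fixation_scan(a, b, sd_multiplier = 2, contrast = "regional")
  a2 <- a; b2 <- b
  a2$mean_major_freq <- a$mean_major_freq + 0.05
  b2$mean_major_freq <- b$mean_major_freq + 0.05
  f2 <- fixation_scan(a2, b2, sd_multiplier = 2, contrast = "regional")
  expect_equal(f1$flagged, f2$flagged)
  expect_equal(f1$z_sd, f2$z_sd, tolerance = 1e-9)
})

test_that("fixation scan drops trailing partial intervals and unusable genes", {
  a <- make_gene_freq(rep(0.7, 27))
  b <- make_gene_freq(rep(0.7, 27))
  a$n_snps[3] <- 0L  # unusable gene: excluded before interval formation
  suppressWarnings({
    fs <- fixation_scan(a, b)
  })
  expect_equal(nrow(fs), 2L)  # 26 usable genes -> 2 full intervals of 10
  expect_equal(fs$n_genes, c(10L, 10L))
})
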