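test_that("Tajima constants satisfy their defining identities", {
  for (n in c(4, 10, 20, 37)) {
    k <- tajima_constants(n)
    expect_equal(k$a1, sum(1 / seq_len(n - 1)))
    expect_equal(k$a2, sum(1 / seq_len(n - 1)^2))
    expect_equal(k$e1, (k$b1 - 1 / k$a1) / k$a1)
  }
  expect_error(tajima_constants(1), "n must be")
})

test_that("site_pi matches brute-force pairwise difference counting", {
  expect_equal(site_pi(0, 10, 20), 0)   # p = 1: no variation left
  expect_equal(site_pi(10, 0, 20), 0)   # p = 0
  expect_equal(site_pi(10, 10, 20), 100 / 190)
  set.seed(41)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    j <- sample(0:n, 1)
    expect_equal(site_pi(n - j, j, n), oracle_pairwise_pi(j, n),
                 tolerance = 1e-12)
  }
  expect_error(site_pi(0, 0, 10), "zero depth")
})

test_that("filter_sites applies the variant and coverage rules and tallies", {
  s <- make_sites(pos = c(100, 200, 300, 400),
                  ref_count = c(5, 8, 9, 20),
                  alt_count = c(0, 2, 0, 5))
  # depth 5 (below >6 rule), depth 10 variant, depth 9 non-variant, depth 25
  f <- filter_sites(s, min_depth = 6, min_alt_freq = 0.2)
  expect_equal(f$tally$n_variant, 2L)
  expect_equal(f$tally$n_alt_ge_threshold, 2L)  # 2/10 and 5/25 both >= 0.2
  expect_equal(f$tally$mean_depth_variant, mean(c(10, 25)))
  expect_equal(f$sites$pos, c(200, 400))  # coverage floor 8, alt > 0

  low <- make_sites(5, ref_count = 3, alt_count = 2)  # depth 5 with min 6
  expect_equal(filter_sites(low)$tally$n_variant, 0L)

  empty <- make_sites(integer(0), integer(0), integer(0))
  fe <- filter_sites(empty)
  expect_equal(fe$tally$n_variant, 0L)
  expect_equal(fe$tally$n_alt_ge_threshold, 0L)
  expect_equal(fe$tally$mean_depth_variant, 0)
  expect_equal(nrow(fe$sites), 0L)

  bad <- make_sites(1, ref_count = -1, alt_count = 2)
  expect_error(filter_sites(bad), "negative")
})

test_that("window D equals an independently coded Tajima evaluation", {
  windows <- data.frame(chrom = "lg01", start = 0, end = 10000)
  set.seed(7)
  for (rep in 1:200) {
    n_chrom <- sample(4:40, 1)
    ns <- sample(5:80, 1)
    depth <- rpois(ns, 15) + 8
    alt <- rbinom(ns, depth, runif(ns))
    s <- make_sites(sort(sample.int(10000, ns)), depth - alt, alt)
    ws <- window_stats(s, windows, n_chrom)
    expect_equal(ws$D, oracle_window_d(s$ref_count, s$alt_count, n_chrom),
                 tolerance = 1e-9)
  }
})

test_that("windows with no polymorphism give pi 0 and missing D", {
  windows <- data.frame(chrom = "lg01", start = 0, end = 10000)
  s <- make_sites(c(10, 20), ref_count = c(0, 0), alt_count = c(12, 15))
  ws <- window_stats(s, windows, 20)
  expect_equal(ws$S, 0L)
  expect_equal(ws$pi, 0)
  expect_true(is.na(ws$D))
  expect_equal(ws$n_sites, 2L)
})

test_that("a window engineered with pi equal to S/a1 has D exactly zero", {
  for (n in c(6, 20)) {
    k <- tajima_constants(n)
    expect_equal(tajima_d(5, 5 / k$a1, n), 0)
    expect_equal(tajima_d(1, 1 / k$a1, n), 0)  # denominator sqrt(e1)
  }
})

test_that("D is negative under an excess of rare variants and positive near 0.5", {
  n_chrom <- 20
  windows <- data.frame(chrom = "lg01", start = 0, end = 10000)
  S <- 12
  depth <- 20
  rare_alt <- rep(2L, S)  # p-hat = 1/10, all low frequency
  rare <- make_sites(seq_len(S) * 100, depth - rare_alt, rare_alt)
  mid_alt <- rep(10L, S)  # p-hat = 0.5
  mid <- make_sites(seq_len(S) * 100, depth - mid_alt, mid_alt)
  d_rare <- window_stats(rare, windows, n_chrom)$D
  d_mid <- window_stats(mid, windows, n_chrom)$D
  expect_lt(d_rare, 0)
  expect_gt(d_mid, 0)
})

test_that("every filtered site lands in exactly one window", {
  cfg <- sim_config(seed = 11, n_linkage_groups = 2, lg_length_bp = 1e5,
                    snp_density = 0.01, n_genes = 10)
  exp <- simulate_experiment(cfg)
  sub <- exp$counts[exp$counts$pool_id == "Y1", ]
  flt <- filter_sites(sub)$sites
  w <- exp$windows
  hits <- vapply(seq_len(nrow(flt)), function(i)
    sum(w$chrom == flt$chrom[i] & flt$pos[i] - 1 >= w$start &
          flt$pos[i] - 1 < w$end), 0)
  expect_true(all(hits == 1))
  ws <- window_stats(flt, w, 18)
  expect_equal(sum(ws$n_sites), nrow(flt))
})

test_that("gene major-allele frequency averages max(p, 1-p) over in-gene SNPs", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "lg01",
                      start = c(0, 5000), end = c(1000, 6000),
                      annotated = TRUE, stringsAsFactors = FALSE)
  # g1 SNP frequencies 0.5, 0.9, 0.2 -> major 0.5, 0.9, 0.8 -> mean 0.7333...
  s <- make_sites(c(100, 200, 300), ref_count = c(10, 2, 16),
                  alt_count = c(10, 18, 4))
  gf <- gene_major_allele_freq(s, genes, group = "orchard")
  expect_equal(gf$mean_major_freq[1], mean(c(0.5, 0.9, 0.8)), tolerance = 1e-12)
  expect_equal(gf$n_snps, c(3L, 0L))
  expect_true(is.na(gf$mean_major_freq[2]))  # zero-SNP gene is missing

  fixed <- make_sites(c(100, 200), ref_count = c(0, 0), alt_count = c(9, 12))
  expect_equal(gene_major_allele_freq(fixed, genes)$mean_major_freq[1], 1.0)

  expect_error(gene_major_allele_freq(s, transform(genes, start = end)),
               "malformed")
})

test_that("mean major-allele frequency is >= 0.5 and ref/alt label invariant", {
  genes <- data.frame(gene_id = "g1", chrom = "lg01", start = 0, end = 10000,
                      annotated = TRUE, stringsAsFactors = FALSE)
  set.seed(5)
  for (rep in 1:20) {
    depth <- rpois(30, 20) + 8
    alt <- rbinom(30, depth, runif(30))
    s <- make_sites(seq_len(30) * 10, depth - alt, alt)
    swapped <- s
    swapped$ref_count <- s$alt_count
    swapped$alt_count <- s$ref_count
    a <- gene_major_allele_freq(s, genes)$mean_major_freq
    b <- gene_major_allele_freq(swapped, genes)$mean_major_freq
    expect_gte(a, 0.5)
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("group_counts sums read counts across a group's pools site-wise", {
  s1 <- make_sites(c(10, 20), c(5, 6), c(2, 1), pool_id = "p1")
  s2 <- make_sites(c(10, 20), c(3, 4), c(4, 0), pool_id = "p2")
  s1$group <- "wild"; s2$group <- "wild"
  g <- group_counts(rbind(s1, s2))
  expect_equal(nrow(g), 2L)
  expect_equal(g$ref_count, c(8, 10))
  expect_equal(g$alt_count, c(6, 1))
  nogroup <- rbind(s1, s2)[, setdiff(names(s1), "group")]
  expect_error(group_counts(nogroup, pool_groups = c(p1 = "wild")),
               "without group")
})
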