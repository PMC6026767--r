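#' Pool specification
#'
#' One sequencing pool: a set of diploid trees from a single group,
#' sequenced to a finite expected depth.
#'
#' @param pool_id Pool label.
#' @param group Group label, conventionally one of `"orchard"`,
#'   `"wild_north"`, `"wild_south"`.
#' @param n_individuals Number of diploid individuals pooled (`>= 2`).
#' @param mean_depth Expected reads per site (`> 0`).
#' @return A list of class `pool_spec`.
#' @export
pool_spec <- function(pool_id, group, n_individuals, mean_depth) {
  if (n_individuals < 2) stop("n_individuals must be >= 2")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  structure(list(pool_id = as.character(pool_id), group = as.character(group),
                 n_individuals = as.integer(n_individuals),
                 mean_depth = as.numeric(mean_depth)),
            class = "pool_spec")
}

#' Sweep specification
#'
#' A localized selective sweep: within `[start_bp, end_bp]` on linkage group
#' `lg`, the target group's allele frequencies are pushed toward fixation
#' (`fixation_shift`) and its expected heterozygosity reduced by a factor
#' `diversity_reduction`.
#'
#' @param lg Linkage-group label.
#' @param start_bp,end_bp 1-based inclusive sweep coordinates,
#'   `start_bp < end_bp`.
#' @param target_group Group whose diversity is reduced.
#' @param diversity_reduction Fraction in \[0,1\] by which per-site expected
#'   heterozygosity is reduced.
#' @param fixation_shift Fraction in \[0,1\] moving frequencies toward the
#'   nearer boundary: `p' = p*(1-s)` if `p < 0.5`, else `p + (1-p)*s`.
#' @return A list of class `sweep_spec`.
#' @export
sweep_spec <- function(lg, start_bp, end_bp, target_group,
                       diversity_reduction = 0, fixation_shift = 0) {
  if (start_bp >= end_bp) stop("start_bp must be < end_bp")
  if (diversity_reduction < 0 || diversity_reduction > 1)
    stop("diversity_reduction must be in [0,1]")
  if (fixation_shift < 0 || fixation_shift > 1)
    stop("fixation_shift must be in [0,1]")
  structure(list(lg = as.character(lg), start_bp = as.numeric(start_bp),
                 end_bp = as.numeric(end_bp),
                 target_group = as.character(target_group),
                 diversity_reduction = diversity_reduction,
                 fixation_shift = fixation_shift),
            class = "sweep_spec")
}

#' Default pool set at the scale of the chestnut resequencing design
#'
#' Ten pools of 9-13 diploid trees each at roughly 4.5-15x expected depth,
#' split into orchard, northern-wild and southern-wild groups.
#'
#' @return List of [pool_spec()] objects.
#' @export
default_pools <- function() {
  list(
    pool_spec("Y1",  "wild_south", 9,  9.46),
    pool_spec("Y2",  "wild_south", 10, 14.89),
    pool_spec("GZ",  "wild_south", 10, 11.02),
    pool_spec("S1",  "wild_north", 13, 9.42),
    pool_spec("S2",  "wild_north", 10, 11.06),
    pool_spec("S3",  "wild_north", 10, 7.19),
    pool_spec("S4",  "orchard",    10, 12.68),
    pool_spec("HB",  "orchard",    10, 7.92),
    pool_spec("BY",  "orchard",    10, 6.72),
    pool_spec("ECC", "orchard",    12, 4.49)
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic two-group pool-seq experiment. Ancestral
#' alternate-allele frequencies are Beta(`base_freq_alpha`,
#' `base_freq_beta`) distributed and shared across groups outside sweeps;
#' sweeps perturb the target group only.
#'
#' @param seed Integer seed governing all randomness downstream.
#' @param n_linkage_groups Number of linkage groups (chromosomes).
#' @param lg_length_bp Length of each linkage group in bp.
#' @param snp_density Expected SNPs per bp.
#' @param window_size_bp Analysis window width (default 10000). Trailing
#'   partial windows at linkage-group ends are dropped.
#' @param n_genes Total predicted genes placed evenly across the genome.
#' @param gene_length_bp Length of each gene.
#' @param pools List of [pool_spec()]; defaults to [default_pools()].
#' @param sweeps List of [sweep_spec()].
#' @param base_freq_alpha,base_freq_beta Beta shape parameters of the
#'   ancestral frequency distribution.
#' @param seq_error_rate Per-read symmetric miscall probability, in
#'   \[0, 0.1\].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_linkage_groups = 12L,
                       lg_length_bp = 1e6,
                       snp_density = 0.01,
                       window_size_bp = 10000L,
                       n_genes = 600L,
                       gene_length_bp = 2000L,
                       pools = default_pools(),
                       sweeps = list(),
                       base_freq_alpha = 0.8,
                       base_freq_beta = 0.8,
                       seq_error_rate = 0.001) {
  if (n_linkage_groups < 1 || lg_length_bp < 1 || window_size_bp < 1 ||
      n_genes < 0 || gene_length_bp < 1 || snp_density <= 0)
    stop("counts, lengths and densities must be positive")
  if (seq_error_rate < 0 || seq_error_rate > 0.1)
    stop("seq_error_rate must be in [0, 0.1]")
  if (base_freq_alpha <= 0 || base_freq_beta <= 0)
    stop("Beta shape parameters must be positive")
  if (!length(pools)) stop("at least one pool required")
  cfg <- structure(list(
    seed = as.integer(seed), n_linkage_groups = as.integer(n_linkage_groups),
    lg_length_bp = as.numeric(lg_length_bp), snp_density = snp_density,
    window_size_bp = as.numeric(window_size_bp), n_genes = as.integer(n_genes),
    gene_length_bp = as.numeric(gene_length_bp), pools = pools,
    sweeps = sweeps, base_freq_alpha = base_freq_alpha,
    base_freq_beta = base_freq_beta, seq_error_rate = seq_error_rate),
    class = "sim_config")
  check_sweep_overlap(cfg)
  cfg
}

lg_names <- function(config) {
  sprintf("lg%02d", seq_len(config$n_linkage_groups))
}

check_sweep_overlap <- function(config) {
  sw <- config$sweeps
  if (length(sw) < 2) return(invisible(NULL))
  for (i in seq_along(sw)) for (j in seq_len(i - 1L)) {
    a <- sw[[i]]; b <- sw[[j]]
    if (a$lg == b$lg && a$target_group == b$target_group &&
        a$start_bp <= b$end_bp && b$start_bp <= a$end_bp)
      stop(sprintf(
        "overlapping sweeps on %s for group %s: [%d,%d] overlaps [%d,%d]",
        a$lg, a$target_group, a$start_bp, a$end_bp, b$start_bp, b$end_bp))
  }
  invisible(NULL)
}

# Exact per-site heterozygosity compression: returns q on the same side of
# 0.5 as p with 2q(1-q) = (1-d) * 2p(1-p).
compress_het <- function(p, d) {
  h <- 2 * p * (1 - p) * (1 - d)
  s <- sqrt(pmax(0, 1 - 2 * h))
  ifelse(p < 0.5, (1 - s) / 2, (1 + s) / 2)
}

apply_fixation_shift <- function(p, s) {
  ifelse(p < 0.5, p * (1 - s), p + (1 - p) * s)
}

#' Simulate true group allele frequencies
#'
#' Places SNP sites uniformly along each linkage group at the configured
#' expected density, draws a shared ancestral alternate-allele frequency per
#' site from the configured Beta distribution, and applies each sweep's
#' fixation shift and heterozygosity compression to its target group.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return A list of class `group_freqs`: `sites` (data.frame `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `base_freq`), `freqs` (matrix sites
#'   x groups of true alternate-allele frequencies), `groups`, `config`.
#' @export
simulate_group_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  check_sweep_overlap(config)
  set.seed(config$seed)
  groups <- unique(vapply(config$pools, `[[`, "", "group"))
  bases <- c("A", "C", "G", "T")
  chrom <- character(0); pos <- numeric(0)
  for (lg in lg_names(config)) {
    n <- rpois(1L, config$snp_density * config$lg_length_bp)
    n <- min(n, config$lg_length_bp)
    chrom <- c(chrom, rep(lg, n))
    pos <- c(pos, sort(sample.int(config$lg_length_bp, n)))
  }
  ns <- length(pos)
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  p0 <- rbeta(ns, config$base_freq_alpha, config$base_freq_beta)
  freqs <- matrix(rep(p0, length(groups)), ncol = length(groups),
                  dimnames = list(NULL, groups))
  for (sw in config$sweeps) {
    if (!sw$target_group %in% groups)
      stop("sweep target group not present in pools: ", sw$target_group)
    sel <- chrom == sw$lg & pos >= sw$start_bp & pos <= sw$end_bp
    p <- freqs[sel, sw$target_group]
    p <- apply_fixation_shift(p, sw$fixation_shift)
    p <- compress_het(p, sw$diversity_reduction)
    freqs[sel, sw$target_group] <- p
  }
  structure(list(
    sites = data.frame(chrom = chrom, pos = as.integer(pos),
                       ref_allele = unname(ref), alt_allele = unname(alt),
                       base_freq = p0, stringsAsFactors = FALSE),
    freqs = freqs, groups = groups, config = config),
    class = "group_freqs")
}

#' Simulate pooled read counts for one pool
#'
#' For each site, draws the pool's realized chromosome count from its
#' group's true frequency (binomial over `2 * n_individuals` chromosomes),
#' a Poisson read depth, and alternate read counts from the realized pool
#' frequency with symmetric sequencing error.
#'
#' @param freqs A `group_freqs` object from [simulate_group_frequencies()].
#' @param pool A [pool_spec()]; its `group` must exist in `freqs`.
#' @param config A [sim_config()]; defaults to the one stored in `freqs`.
#' @param seed Integer seed; defaults to a pool-specific offset of
#'   `config$seed`.
#' @return A `SiteCounts` data.frame: `chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `ref_count`, `alt_count`, `pool_id`, `group`.
#' @export
simulate_pool_readcounts <- function(freqs, pool, config = freqs$config,
                                     seed = NULL) {
  stopifnot(inherits(freqs, "group_freqs"), inherits(pool, "pool_spec"))
  if (!pool$group %in% colnames(freqs$freqs))
    stop("pool group not simulated: ", pool$group)
  if (pool$mean_depth <= 0) stop("mean_depth must be > 0")
  if (is.null(seed)) {
    idx <- match(pool$pool_id,
                 vapply(config$pools, `[[`, "", "pool_id"))
    if (is.na(idx)) idx <- 0L
    seed <- (config$seed + 7919L * (idx + 1L)) %% .Machine$integer.max
  }
  set.seed(seed)
  p <- freqs$freqs[, pool$group]
  ns <- length(p)
  n_chrom <- 2L * pool$n_individuals
  k <- rbinom(ns, n_chrom, p)
  f <- k / n_chrom
  depth <- rpois(ns, pool$mean_depth)
  e <- config$seq_error_rate
  alt <- rbinom(ns, depth, f * (1 - e) + (1 - f) * e)
  data.frame(freqs$sites[c("chrom", "pos", "ref_allele", "alt_allele")],
             ref_count = depth - alt, alt_count = alt,
             pool_id = pool$pool_id, group = pool$group,
             stringsAsFactors = FALSE)
}

#' Simulate individual diploid genotypes for one group
#'
#' Genotypes are two independent allele draws per individual per site
#' (Hardy-Weinberg proportions at the group's true frequency).
#'
#' @param freqs A `group_freqs` object.
#' @param group Group label present in `freqs`.
#' @param n_individuals Number of diploids (`>= 1`).
#' @param seed Integer seed.
#' @return Integer matrix (individuals x sites) of alternate-allele dosages
#'   in \{0, 1, 2\}, with site coordinates in `attr(, "sites")`.
#' @export
simulate_individual_genotypes <- function(freqs, group, n_individuals,
                                          seed = freqs$config$seed) {
  stopifnot(inherits(freqs, "group_freqs"))
  if (!group %in% colnames(freqs$freqs)) stop("unknown group: ", group)
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  set.seed(seed)
  p <- freqs$freqs[, group]
  g <- matrix(rbinom(n_individuals * length(p), 2L, rep(p, each = n_individuals)),
              nrow = n_individuals,
              dimnames = list(sprintf("%s_%02d", group, seq_len(n_individuals)),
                              NULL))
  attr(g, "sites") <- freqs$sites[c("chrom", "pos", "ref_allele", "alt_allele")]
  g
}

#' Simulate a pooled chloroplast sample from a haplotype mixture
#'
#' The pool holds `n_copies` chloroplast genomes. Each non-reference
#' haplotype is a set of variant positions at a target frequency; copies
#' are assigned by largest-remainder rounding of `frequency * n_copies`
#' (remaining copies carry the reference). The per-site alternate-allele
#' frequency is the fraction of copies carrying a haplotype containing the
#' site; with `depth` given, frequencies are re-estimated from binomially
#' sampled reads with symmetric `error`.
#'
#' @param haplotypes List of `list(sites = <integer positions>, freq =
#'   <fraction>)`; frequencies must sum to at most 1. Site sets need not be
#'   disjoint.
#' @param n_copies Number of chloroplast genomes in the pool.
#' @param depth Optional per-site read depth for noisy re-estimation.
#' @param error Per-read miscall probability (used only with `depth`).
#' @param seed Seed for the read sampling.
#' @param pool_id Pool label attached to the output.
#' @return A `CpSnp` data.frame: `pos`, `alt_freq` (> 0), `pool_id`.
#' @export
simulate_chloroplast_pool <- function(haplotypes, n_copies, depth = NULL,
                                      error = 0, seed = 1L,
                                      pool_id = "cp_pool") {
  fr <- vapply(haplotypes, `[[`, 0, "freq")
  if (length(fr) && sum(fr) > 1 + 1e-9)
    stop("haplotype frequencies sum to more than 1")
  q <- fr * n_copies
  copies <- floor(q + 1e-9)
  short <- round(sum(q)) - sum(copies)
  if (short > 0) {
    add <- order(q - copies, decreasing = TRUE)[seq_len(short)]
    copies[add] <- copies[add] + 1L
  }
  all_sites <- sort(unique(unlist(lapply(haplotypes, `[[`, "sites"))))
  if (!length(all_sites))
    return(data.frame(pos = integer(0), alt_freq = numeric(0),
                      pool_id = character(0), stringsAsFactors = FALSE))
  carriers <- numeric(length(all_sites))
  for (i in seq_along(haplotypes))
    carriers <- carriers +
      copies[i] * (all_sites %in% haplotypes[[i]]$sites)
  f <- pmin(carriers / n_copies, 1)
  if (!is.null(depth)) {
    set.seed(seed)
    alt <- rbinom(length(f), depth, f * (1 - error) + (1 - f) * error)
    f <- alt / depth
  }
  keep <- f > 0
  data.frame(pos = as.integer(all_sites[keep]), alt_freq = f[keep],
             pool_id = pool_id, stringsAsFactors = FALSE)
}

#' Analysis windows for a simulated genome
#'
#' Non-overlapping windows of `window_size_bp` tiling each linkage group;
#' trailing partial windows are dropped. Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return Data.frame `chrom`, `start`, `end`.
#' @export
make_windows <- function(config) {
  w <- config$window_size_bp
  k <- floor(config$lg_length_bp / w)
  do.call(rbind, lapply(lg_names(config), function(lg)
    data.frame(chrom = lg, start = (seq_len(k) - 1) * w, end = seq_len(k) * w,
               stringsAsFactors = FALSE)))
}

#' Predicted gene intervals for a simulated genome
#'
#' Places `n_genes` genes of length `gene_length_bp`, distributed evenly
#' across linkage groups and evenly spaced within each. Coordinates are
#' 0-based half-open.
#'
#' @param config A [sim_config()].
#' @return Data.frame `gene_id`, `chrom`, `start`, `end`, `annotated`.
#' @export
make_genes <- function(config) {
  lgs <- lg_names(config)
  per <- diff(floor(seq(0, config$n_genes, length.out = length(lgs) + 1)))
  out <- lapply(seq_along(lgs), function(i) {
    n <- per[i]
    if (!n) return(NULL)
    span <- floor(config$lg_length_bp / n)
    if (span <= config$gene_length_bp)
      stop("genes do not fit: reduce n_genes or gene_length_bp")
    start <- (seq_len(n) - 1) * span + floor((span - config$gene_length_bp) / 2)
    data.frame(gene_id = sprintf("%s_g%04d", lgs[i], seq_len(n)),
               chrom = lgs[i], start = start,
               end = start + config$gene_length_bp, annotated = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ground-truth labels for simulated windows and genes
#'
#' Flags every analysis window and every gene exactly once as swept or not,
#' with the responsible sweep's target group and parameters.
#'
#' @param config A [sim_config()].
#' @param windows,genes Optional precomputed [make_windows()] /
#'   [make_genes()] tables.
#' @return List of class `truth_table` with data.frames `windows` and
#'   `genes`, each carrying `swept`, `target_group`, `diversity_reduction`,
#'   `fixation_shift`.
#' @export
truth_table <- function(config, windows = make_windows(config),
                        genes = make_genes(config)) {
  label <- function(df) {
    df$swept <- FALSE
    df$target_group <- NA_character_
    df$diversity_reduction <- NA_real_
    df$fixation_shift <- NA_real_
    for (sw in config$sweeps) {
      hit <- df$chrom == sw$lg & df$start < sw$end_bp & df$end > sw$start_bp - 1
      df$swept[hit] <- TRUE
      df$target_group[hit] <- sw$target_group
      df$diversity_reduction[hit] <- sw$diversity_reduction
      df$fixation_shift[hit] <- sw$fixation_shift
    }
    df
  }
  structure(list(windows = label(windows), genes = label(genes)),
            class = "truth_table")
}
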