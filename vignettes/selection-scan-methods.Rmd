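---
title: "Pool-seq selection scans: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq selection scans: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolsweeps)
```

# The problem

Domestication of a perennial tree crop leaves localized footprints in the
genome: regions where the cultivated lineage has reduced nucleotide
diversity, an excess of rare variants, and alleles pushed toward fixation
relative to wild relatives. When many trees are sequenced as pools rather
than as individuals, allele frequencies must be estimated from read counts,
and the usual individual-based machinery for sweep detection does not apply
directly. `poolsweeps` implements a pooled scan built from four layers:

1. **Windowed diversity statistics** (`pool_stats`): per-site unbiased
   heterozygosity and Tajima's D in 10 kb windows, from pooled read counts.
2. **A permutation null for between-group differences** (`sweep_scan`):
   windows where orchard Tajima's D falls far below wild Tajima's D, judged
   against genome-shuffled re-assignments, with consecutive-window and
   stringent single-window calling rules and a histogram local FDR.
3. **A major-allele fixation outlier scan** over 10-gene intervals.
4. **Independent validation** (`validation_stats`): per-gene D, diversity,
   heterozygosity and Weir–Cockerham F<sub>ST</sub> from individual
   genotypes.

A fifth layer, pooled **chloroplast haplotype deconvolution**
(`chloroplast_haplotypes`), reads the haplotype composition of each pool
off a binned histogram of alternate-allele frequencies.

Because no real sequence data ship with the package, a first-class
synthetic-data generator (`synthetic_data`) provides every input with
ground-truth labels; all pipeline-level tests run against it.

# The generative model

The generator is deliberately the simplest process with the structure the
analysis assumes; it is not a coalescent simulator.

* **Sites.** SNPs are placed uniformly along each linkage group at an
  expected density (default 0.01/bp, matching roughly one variant site per
  80–100 bp as seen in pooled tree resequencing). Each site gets an
  ancestral alternate-allele frequency $p_0 \sim \mathrm{Beta}(0.8, 0.8)$,
  shared across groups: under the null the two gene pools are the same
  population.
* **Sweeps.** Within a sweep interval, the target group's frequency is
  first shifted toward the nearer boundary,
  $p' = p(1-s)$ for $p<0.5$ and $p' = p + (1-p)s$ otherwise
  (`fixation_shift` $s$), then compressed so that per-site expected
  heterozygosity is scaled exactly: $2q(1-q) = (1-d)\,2p'(1-p')$ with $q$
  on the same side of $\tfrac12$ as $p'$ (`diversity_reduction` $d$). The
  downstream statistics respond to the site-frequency spectrum only, so
  parameterizing the sweep directly on the spectrum is sufficient and makes
  the monotonicity of expected $\pi$ in $d$ exact rather than asymptotic.
* **Pools.** A pool of $n$ diploids draws $k \sim \mathrm{Bin}(2n, p)$
  carrier chromosomes, a depth $r \sim \mathrm{Pois}(\lambda)$, and
  alternate reads $\mathrm{Bin}(r,\; f(1-e) + (1-f)e)$ with $f = k/2n$ and
  symmetric error rate $e$ (default 0.001). The default pool set is ten
  pools of 9–13 trees at expected depths between 4.5 and 15, split into
  orchard, northern-wild and southern-wild groups — the scale of a real
  pooled resequencing design for an orchard tree.
* **Individuals.** Genotypes are two independent allele draws per site
  (Hardy–Weinberg), for the validation layer.
* **Chloroplast pools.** A pool of `n_copies` organelle genomes mixes a
  small number of haplotypes, each a set of variant positions at a target
  frequency; copies are assigned by largest-remainder rounding so that grid
  frequencies are reproduced exactly (3 of 10 copies means every haplotype
  site sits at exactly 30%).

**What the generator does not emulate:** linkage disequilibrium and
haplotype structure, recombination, demography and migration, base-quality
variation, indels, reference bias, and mapping artefacts. Tests passing on
this generator therefore demonstrate that the statistics and decision rules
behave as designed on data with the assumed sampling structure; they do not
demonstrate robustness to LD or alignment pathologies in real data.

# Statistics

**Site filters.** A *variant site* needs depth $> 6$ and at least one
alternate read; the tally layer also reports sites with alternate
frequency $\ge 0.2$ and the mean depth at variant sites. Downstream
statistics additionally require depth $\ge 8$ (the coverage floor, applied
identically to both groups to avoid depth-driven bias) and, for a site to
count as segregating, a minor-allele read count of at least 2 (configurable;
singleton reads at 0.1% error and 10–30× depth are mostly errors).

**Per-site $\pi$.** With $\hat p$ = alt reads / depth and $n$ sampled
chromosomes, $\pi_{site} = 2\hat p(1-\hat p)\,n/(n-1)$ — the unbiased
average pairwise difference. For group-level statistics, read counts are
first summed across the group's pools site-wise, and $n$ is twice the
summed number of diploids in the group. The classic estimator on read
frequencies is used, not a pooled-sampling-corrected estimator: the
downstream inference is a permutation test on *differences* of the
statistic between groups computed identically, so a common bias cancels and
calibration is restored by the null itself.

**Tajima's D.** $D = (\pi - S/a_1)\big/\sqrt{e_1 S + e_2 S(S-1)}$ with the
1989 coefficients ($a_1 = \sum_{i<n} 1/i$, etc.). $D$ is undefined (`NA`)
at $S = 0$; at $S = 1$ the denominator reduces to $\sqrt{e_1}$. $\pi$ is
reported both as a per-window sum and per bp; the windowed $D$ uses the
sum, as the two differ only by the constant window width.

# The permutation null

Each permutation independently re-assigns the observed window $D$ values of
each group to random window positions and recomputes
$\Delta_i = D_{A,i} - D_{B,i}$ (convention: A = wild, B = orchard, so
sweep-like windows have large positive $\Delta$). Two counting modes:

* **per-window** (default): $p_i = (1 + \#\{k: \Delta^{(k)}_i \ge
  \Delta_i\}) / (1 + n_{perm})$, with the +1 correction so $p > 0$;
* **pooled-null**: $\Delta_i$ is compared against the shuffled values from
  all windows and permutations jointly.

The test is one-sided in the reduced-orchard-diversity direction by
default; a two-sided option on $|\Delta|$ exists. Shuffling is genome-wide
(the closest reading of re-assignment "to a random base-pair interval of
the genome"); windows with missing $D$ on either side are excluded from the
null and receive `NA`.

**Exact enumeration.** Under independent uniform permutations, the shuffled
difference at any fixed window is distributed exactly as a uniformly drawn
value pair $A_a - B_b$; per-window exceedance probabilities over all
$(n_A!)(n_B!)$ permutation pairs therefore reduce to counting over the
$n^2$ value pairs. The package switches to this exact mode automatically
when $(n!)^2 \le 10{,}000$ and on request via `exact = TRUE`; Monte-Carlo
p-values agree with it to binomial error on small tracks.

**Calibration and conservativeness.** When the two tracks are independent
draws from one process, window exchangeability holds and the fraction of
windows at $p \le 0.01$ sits at the nominal $10/1001$. When the two groups
share ancestral frequencies at the same sites — the realistic null for two
populations of common origin — $D_{A,i}$ and $D_{B,i}$ are positively
correlated within windows, shuffling destroys that correlation, and the
permuted $\Delta$ over-disperses: the test becomes conservative (observed
fractions at $p\le0.01$ closer to 0.005–0.010). This is a property of the
genome-shuffling design itself and is worth knowing when interpreting
genome-wide counts of significant windows.

**Calling rules.** Maximal runs of $\ge 2$ adjacent windows at $p \le 0.01$
merge into one candidate; isolated windows qualify only at $p \le 0.001$.
Calls are disjoint after merging. Local FDRs use Storey's
$\hat\pi_0 = \min(1, \#\{p>0.5\}/(0.5m))$ over a 20-bin histogram density,
clipped to $[0,1]$ and made monotone in $p$ by cumulative maximum — a
deliberately smoothing-parameter-free estimate that is reproducible to the
last digit at $m \sim 10^3$–$10^4$ windows.

# The fixation scan

Per-gene major-allele frequency $\overline{\max(\hat p, 1-\hat p)}$ is
averaged over annotated genes with SNPs in both groups, genes are blocked
into consecutive non-overlapping 10-gene intervals per linkage group
(trailing remainders dropped; a sliding mode exists behind a flag), and the
interval-level difference $\delta$ (orchard − wild, or north − south) is
flagged when it exceeds the genome-wide mean by `sd_multiplier` population
standard deviations. Two presets are kept: the stricter 3 SD cutoff for
the domestication contrast (the default), and 2 SD for regional contrasts,
where differentiation among wild subpopulations is expected to be weaker. With
thousands of intervals the population-vs-sample SD distinction is
negligible; the population SD is used and documented. The flag set is
invariant under adding a constant to every gene in both groups, so
genome-wide frequency offsets cannot create outliers.

# Chloroplast haplotype deconvolution

Chloroplasts are haploid and maternally inherited, so a pool of $m$ trees
holds $m$ organelle genomes and a haplotype carried by $c$ of them puts
*all* of its variant sites at alternate frequency $c/m$. Binning SNP
frequencies at width 0.10 (the natural resolution for pools of ~10 trees)
over centers 0.10–1.00 turns each haplotype into a spike: a bin is called a
peak when it holds at least 30 SNPs and strictly exceeds both neighbors;
the 1.0 bin is always reported when populated (a fixed non-reference
haplotype has no right neighbor to beat). The peak's bin center estimates
the haplotype frequency and its SNP membership is the haplotype's
signature, matched across pools by Jaccard similarity ($\ge 0.5$) with
haplotype groups as connected components of the match graph. The minimum
SNP support and the strict-local-maximum definition are judgment calls (no
formal peak definition exists for this procedure); both are parameters.
Known limitation: sites shared between co-occurring haplotypes stack into
intermediate bins and are not deconvolved — sub-threshold "shoulders" can
be inspected by lowering `min_snps`, at the cost of false peaks.

# Validation statistics

From individual genotypes, per gene and group: per-site
$\pi = 2\hat p\hat q \cdot 2N/(2N-1)$ with $2N$ the called chromosomes,
normalized per interval bp (monomorphic positions count in the
denominator, which is what keeps per-gene values on the $10^{-4}$–$10^{-2}$
scale); Tajima's D at the median called-chromosome count across the gene's
sites (robust to scattered missingness); and mean per-individual
heterozygosity (the per-site average is exposed as an alternative).
Between-group differentiation uses the Weir–Cockerham (1984) two-population
estimator with per-site components a/b/c combined as a gene-level ratio of
sums; monomorphic sites are skipped and negative estimates are reported
raw. A candidate gene is *supported* when D < 0 and both $\pi$/bp and
heterozygosity fall below the genome-wide lower quartiles.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; every written report is
  1-based inclusive (`start_1based`).
* Sync biallelic collapse: the file's reference base is kept as reference;
  the alternate is the highest-count other base, ties broken A<C<G<T;
  N/deletion counts never enter depth; residual third-allele reads are
  dropped and tallied.
* Frequency-bin assignment is lower-edge inclusive with a $10^{-9}$
  guard so that values like 0.35 (not exactly representable in binary)
  land in the bin their decimal value dictates.
* Largest-remainder rounding assigns chloroplast copies, so mixtures on
  the $1/n_{copies}$ grid are reproduced without drift.
* Zero-depth sites are retained by readers and removed by filters; $S=0$
  windows yield `NA` D rather than 0; an all-identical fixation scan warns
  and flags nothing rather than dividing by a zero SD.
* Every simulator is deterministic given its config and seed; identical
  runs are byte-identical.

# Problem sizes used by the test suite

Pipeline-level checks run at sizes chosen to make sampling error small
while keeping the suite quick on a single CPU: null calibration uses 2,000
windows (4 × 5 Mb), one 10-diploid pool per track at depth 12, 1,000
permutations and 5 seeds; sweep recovery uses the ten-pool default design
on a 20 Mb genome with five 50 kb sweeps at `diversity_reduction = 0.9`
and 20 seeds; oracle-equivalence checks use 100–200 random draws each.

# Known limitations

* No pooled-sampling correction of $\theta$ estimators: absolute D values
  from pools are biased at low depth; only between-group comparisons under
  the permutation null are calibrated.
* The fixation scan assumes comparable SNP ascertainment between groups;
  strong depth imbalance shifts major-allele means.
* Chloroplast deconvolution cannot separate haplotypes sharing most sites
  or distinguish two different haplotypes at the same frequency in one
  pool.
* The generator's independence across sites means window statistics are
  better-behaved than in real, LD-structured genomes; real-data candidate
  lists need the validation layer (and annotation) before interpretation.
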