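SYNC_BASES <- c("A", "T", "C", "G")  # column order of sync count strings
TIE_ORDER <- c("A", "C", "G", "T")   # tie-break for biallelic collapse

#' Read a PoPoolation2 sync file
#'
#' Tab-separated `chrom, pos, ref` followed by one `A:T:C:G:N:del` count
#' string per pool. Sites are collapsed to two alleles: the reference base
#' from the file, and the non-reference base with the highest count summed
#' across pools (ties broken in A<C<G<T order). N and deletion counts are
#' excluded from depth; counts of further alleles are dropped.
#'
#' @param path Sync file path.
#' @param pool_ids Pool labels in column order; defaults to
#'   `pool1..poolN`.
#' @return Long `SiteCounts` data.frame (`chrom`, `pos`, `ref_allele`,
#'   `alt_allele`, `ref_count`, `alt_count`, `pool_id`), with the number of
#'   dropped third-allele reads in `attr(, "dropped_reads")`.
#' @export
read_sync <- function(path, pool_ids = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (!length(fields)) stop("empty sync file")
  np <- nf[1] - 3L
  if (np < 1) stop("sync line 1: fewer than 4 columns")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("sync line %d: expected %d count fields, found %d",
                 bad[1], np, nf[bad[1]] - 3L))
  if (is.null(pool_ids)) pool_ids <- sprintf("pool%d", seq_len(np))
  if (length(pool_ids) != np)
    stop(sprintf("declared %d pools but file has %d count columns",
                 length(pool_ids), np))
  ns <- length(fields)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- as.integer(vapply(fields, `[[`, "", 2L))
  ref <- toupper(vapply(fields, `[[`, "", 3L))
  # counts[site, pool, base(A,T,C,G,N,del)]
  counts <- array(0L, dim = c(ns, np, 6L))
  for (j in seq_len(np)) {
    parts <- strsplit(vapply(fields, `[[`, "", 3L + j), ":", fixed = TRUE)
    badlen <- which(lengths(parts) != 6L)
    if (length(badlen))
      stop(sprintf("sync line %d: malformed count string '%s'",
                   badlen[1], vapply(fields, `[[`, "", 3L + j)[badlen[1]]))
    m <- suppressWarnings(
      matrix(as.integer(unlist(parts)), ncol = 6L, byrow = TRUE))
    if (anyNA(m)) {
      badna <- which(apply(is.na(m), 1, any))[1]
      stop(sprintf("sync line %d: non-numeric count string", badna))
    }
    counts[, j, ] <- m
  }
  base_tot <- apply(counts[, , 1:4, drop = FALSE], c(1, 3), sum)
  colnames(base_tot) <- SYNC_BASES
  dropped <- 0L
  out <- vector("list", np)
  alt <- character(ns)
  for (i in seq_len(ns)) {
    cand <- setdiff(TIE_ORDER, ref[i])
    tot <- base_tot[i, cand]
    alt[i] <- cand[order(-tot, match(cand, TIE_ORDER))][1]
    dropped <- dropped + sum(base_tot[i, setdiff(SYNC_BASES, c(ref[i], alt[i]))])
  }
  ri <- match(ref, SYNC_BASES)
  ai <- match(alt, SYNC_BASES)
  if (anyNA(ri)) stop(sprintf("sync line %d: reference base not in ACGT",
                              which(is.na(ri))[1]))
  for (j in seq_len(np)) {
    out[[j]] <- data.frame(
      chrom = chrom, pos = pos, ref_allele = ref, alt_allele = alt,
      ref_count = counts[cbind(seq_len(ns), j, ri)],
      alt_count = counts[cbind(seq_len(ns), j, ai)],
      pool_id = pool_ids[j], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "dropped_reads") <- dropped
  res
}

#' Write pooled site counts as PoPoolation2 sync
#'
#' @param sites Long `SiteCounts` data.frame covering one or more pools
#'   over a shared site set.
#' @param path Output path.
#' @param pool_ids Column order; defaults to order of appearance.
#' @return Invisibly, the pool order written.
#' @export
write_sync <- function(sites, path, pool_ids = unique(sites$pool_id)) {
  key <- paste(sites$chrom, sites$pos)
  first <- !duplicated(key)
  site_tab <- sites[first, c("chrom", "pos", "ref_allele", "alt_allele")]
  ord <- order(site_tab$chrom, site_tab$pos)
  site_tab <- site_tab[ord, ]
  skey <- paste(site_tab$chrom, site_tab$pos)
  cols <- character(nrow(site_tab))
  line <- sprintf("%s\t%d\t%s", site_tab$chrom, site_tab$pos,
                  site_tab$ref_allele)
  ri <- match(site_tab$ref_allele, SYNC_BASES)
  ai <- match(site_tab$alt_allele, SYNC_BASES)
  for (pid in pool_ids) {
    sub <- sites[sites$pool_id == pid, ]
    m <- matrix(0L, nrow(site_tab), 6L)
    idx <- match(paste(sub$chrom, sub$pos), skey)
    m[cbind(idx, ri[idx])] <- sub$ref_count
    m[cbind(idx, ai[idx])] <- sub$alt_count
    line <- paste(line, apply(m, 1, paste, collapse = ":"), sep = "\t")
  }
  writeLines(line, path)
  invisible(pool_ids)
}

#' Read a samtools pileup file for one pool
#'
#' Six-column text pileup (`chrom, pos, ref, depth, bases, quals`). The
#' base string is decoded (read starts `^.`, ends `$`, indel runs
#' `[+-]N<seq>`, deletion placeholders `*` are stripped); `.`/`,` count as
#' reference reads and the most frequent mismatch base becomes the
#' alternate allele (ties A<C<G<T).
#'
#' @param path Pileup file path.
#' @param pool_id Pool label for the output.
#' @return `SiteCounts` data.frame.
#' @export
read_pileup <- function(path, pool_id = "pool1") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad)) stop(sprintf("pileup line %d: fewer than 5 columns", bad[1]))
  parse_bases <- function(s) {
    s <- gsub("\\^.", "", s)          # read-start marker + mapping quality
    s <- gsub("\\$", "", s)
    while (grepl("[+-][0-9]+", s)) {  # indel runs
      m <- regmatches(s, regexpr("[+-][0-9]+", s))
      n <- as.integer(sub("[+-]", "", m))
      s <- sub(sprintf("[+-][0-9]+[ACGTNacgtn]{%d}", n), "", s)
    }
    s <- gsub("\\*", "", s)
    toupper(strsplit(s, "")[[1]])
  }
  out <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    ref <- toupper(f[3])
    ch <- parse_bases(f[5])
    ref_n <- sum(ch %in% c(".", ","))
    cand <- setdiff(TIE_ORDER, ref)
    cnt <- vapply(cand, function(b) sum(ch == b), 0L)
    altb <- cand[order(-cnt, match(cand, TIE_ORDER))][1]
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref_allele = ref,
               alt_allele = altb, ref_count = ref_n,
               alt_count = sum(ch == altb), pool_id = pool_id,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write pooled site counts as a samtools-style pileup
#'
#' @param sites `SiteCounts` data.frame for one pool.
#' @param path Output path.
#' @export
write_pileup <- function(sites, path) {
  depth <- sites$ref_count + sites$alt_count
  bases <- mapply(function(r, a, ab) paste0(
    strrep(".", r), strrep(tolower(ab), a)),
    sites$ref_count, sites$alt_count, sites$alt_allele)
  writeLines(sprintf("%s\t%d\t%s\t%d\t%s\t%s", sites$chrom, sites$pos,
                     sites$ref_allele, depth, bases, strrep("I", depth)),
             path)
}

#' Read individual genotypes from a VCF
#'
#' Biallelic SNP records are kept; multiallelic or non-SNP records are
#' skipped and tallied in `attr(, "n_skipped")`. GT fields map to dosages
#' (phased and unphased alike); missing calls become `NA`.
#'
#' @param path VCF (v4.x) path.
#' @param group_map Named character vector mapping sample ids to groups;
#'   every mapped sample must be in the VCF header.
#' @return A [genotype_set()] restricted to the mapped samples.
#' @export
read_vcf_genotypes <- function(path, group_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1 &
    fix[, "REF"] %in% TIE_ORDER & fix[, "ALT"] %in% TIE_ORDER
  n_skipped <- sum(!keep)
  gtc <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  miss <- setdiff(names(group_map), colnames(gtc))
  if (length(miss))
    stop("samples in group map absent from VCF header: ",
         paste(miss, collapse = ", "))
  gtc <- gtc[, names(group_map), drop = FALSE]
  dosage <- function(x) {
    al <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(al, function(a) {
      if (any(a == "." | is.na(a))) NA_integer_
      else sum(as.integer(a) > 0L)
    }, NA_integer_)
  }
  g <- apply(gtc, 2, dosage)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(group_map)))
  sites <- data.frame(chrom = fix[keep, "CHROM"],
                      pos = as.integer(fix[keep, "POS"]),
                      ref_allele = fix[keep, "REF"],
                      alt_allele = fix[keep, "ALT"], stringsAsFactors = FALSE)
  out <- genotype_set(t(g), sites, group_map)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write a genotype set as VCFv4.2
#'
#' @param gt A [genotype_set()].
#' @param path Output path.
#' @export
write_vcf_genotypes <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_set"))
  ids <- rownames(gt$geno)
  map <- c("0/0", "0/1", "1/1")
  g <- gt$geno
  gt_str <- matrix("./.", nrow(g), ncol(g))
  ok <- !is.na(g)
  gt_str[ok] <- map[g[ok] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  ref <- if (!is.null(gt$sites$ref_allele)) gt$sites$ref_allele else "A"
  alt <- if (!is.null(gt$sites$alt_allele)) gt$sites$alt_allele else "T"
  body <- paste(gt$sites$chrom, gt$sites$pos, ".", ref, alt, ".", "PASS",
                ".", "GT", sep = "\t")
  body <- paste(body, apply(gt_str, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read gene intervals from BED or GFF3
#'
#' BED input (0-based half-open) and GFF3 input (1-based inclusive; `gene`
#' features, id from the `ID` attribute) are unified to the internal
#' 0-based half-open convention and stably sorted by (chrom, start).
#'
#' @param path Interval file path.
#' @param dialect `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Data.frame: `gene_id`, `chrom`, `start`, `end`, `annotated`.
#' @export
read_intervals <- function(path, dialect = c("auto", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.(gff3?|gff)$", path, ignore.case = TRUE))
      "gff3" else "bed"
  gr <- rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3")
  df <- as.data.frame(gr)
  if (dialect == "gff3" && "type" %in% names(df) && any(df$type == "gene"))
    df <- df[df$type == "gene", ]
  id <- if (dialect == "bed") df$name else df$ID
  if (is.null(id) || anyNA(id)) id <- sprintf("feature_%d", seq_len(nrow(df)))
  out <- data.frame(gene_id = as.character(id),
                    chrom = as.character(df$seqnames),
                    start = df$start - 1L, end = df$end, annotated = TRUE,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("interval with start >= end")
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

#' Write gene intervals as BED6
#'
#' @param genes Gene table with internal 0-based half-open coordinates.
#' @param path Output path.
#' @export
write_bed <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t+", genes$chrom,
                     as.integer(genes$start), as.integer(genes$end),
                     genes$gene_id), path)
}

#' Write a tab-separated report
#'
#' Window/gene reports convert internal 0-based half-open starts to the
#' 1-based inclusive convention in a `start_1based` column when a `start`
#' column is present.
#'
#' @param df Data.frame to write.
#' @param path Output path.
#' @param report_1based Add `start_1based` next to `start` (default TRUE).
#' @export
write_tsv_report <- function(df, path, report_1based = TRUE) {
  if (report_1based && "start" %in% names(df) && !"start_1based" %in% names(df)) {
    df <- cbind(df, start_1based = df$start + 1L)
  }
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a tab-separated report written by [write_tsv_report()]
#'
#' @param path Report path.
#' @return Data.frame.
#' @export
read_tsv_report <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

RUN_CONFIG_KEYS <- c(
  "seed", "window_size_bp", "n_perm", "mode", "alpha_run", "alpha_single",
  "min_run", "sd_multiplier", "contrast", "interval_size", "bin_width",
  "min_snps", "jaccard_threshold", "min_depth", "min_alt_freq",
  "coverage_floor", "min_minor_count", "n_linkage_groups", "lg_length_bp",
  "snp_density", "n_genes", "gene_length_bp", "base_freq_alpha",
  "base_freq_beta", "seq_error_rate", "groups", "inputs", "outputs")

#' Read a run configuration file
#'
#' YAML key/value file of subcommand parameters; unknown keys are rejected
#' so typos fail loudly instead of silently using defaults.
#'
#' @param path YAML file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  structure(cfg, class = "run_config")
}
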