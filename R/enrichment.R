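#' Bin genes by typed-SNP count
#'
#' Genes covered by at least one typed SNP are divided into intervals
#' (default 24) based on the distribution of SNPs per gene, so that
#' resampling can match control genes to target genes with a similar SNP
#' count. Edges are count quantiles (type-1, deterministic); duplicate
#' edges collapse, so the number of effective bins can be below `n_bins`.
#' Explicit interior edges can be supplied instead for exact replication of
#' a published binning.
#'
#' @param snp_counts named integer vector, gene -> number of typed SNPs
#'   (all >= 1).
#' @param n_bins requested number of intervals.
#' @param edges optional explicit interior edges (counts); overrides the
#'   quantile rule.
#' @return object of class `"gene_bins"`: list with `bin` (named integer
#'   vector, gene -> bin index), `breaks`, `n_bins` (effective).
#' @export
bin_genes_by_snp_count <- function(snp_counts, n_bins = 24, edges = NULL) {
  if (length(snp_counts) == 0) stop("empty gene universe")
  if (is.null(names(snp_counts)) || anyDuplicated(names(snp_counts)))
    stop("snp_counts must be uniquely named by gene")
  if (any(snp_counts < 1)) stop("all genes in the universe must have >= 1 SNP")
  if (is.null(edges)) {
    probs <- seq_len(n_bins - 1) / n_bins
    edges <- unique(stats::quantile(snp_counts, probs = probs, type = 1,
                                    names = FALSE))
  }
  breaks <- c(-Inf, sort(unique(edges)), Inf)
  bin <- as.integer(cut(snp_counts, breaks = breaks, right = TRUE))
  structure(list(bin = stats::setNames(bin, names(snp_counts)),
                 breaks = breaks, n_bins = length(breaks) - 1L),
            class = "gene_bins")
}

#' SNP-count-matched resampling enrichment test
#'
#' Tests whether a target gene set (e.g. an immune-response catalogue)
#' contains more genes with at least one significant SNP than expected for
#' random gene sets with the same SNP-count profile. Each resample draws,
#' for every target gene, a control gene from the same SNP-count bin
#' (without replacement within the resample by default), then counts drawn
#' genes that are significant and their total SNP count. Empirical
#' p-values use the (1 + k) / (1 + R) estimator: upper-tail for the gene
#' count, two-sided (doubled smaller tail, capped at 1) for the SNP count,
#' which is a matching diagnostic rather than an enrichment statistic.
#'
#' @param target character vector of target gene ids (subset of the
#'   universe).
#' @param snp_counts named integer vector, gene -> typed-SNP count, naming
#'   the universe.
#' @param sig_genes character vector of genes with >= 1 significant SNP.
#' @param bins optional [bin_genes_by_snp_count()] result; computed from
#'   `snp_counts` when omitted.
#' @param R number of resamples (default 10000).
#' @param seed integer seed recorded in the result.
#' @param n_bins bins when `bins` is not supplied.
#' @param replace draw controls with replacement (use when a bin holds
#'   fewer universe genes than target genes).
#' @param exclude_target remove target genes from the control pool.
#' @return object of class `"enrichment_result"`.
#' @export
resample_enrichment <- function(target, snp_counts, sig_genes, bins = NULL,
                                R = 10000, seed = 1, n_bins = 24,
                                replace = FALSE, exclude_target = FALSE) {
  universe <- names(snp_counts)
  if (!all(target %in% universe))
    stop("target genes outside the universe: ",
         paste(utils::head(setdiff(target, universe)), collapse = ", "))
  if (anyDuplicated(target)) stop("duplicate target genes")
  if (is.null(bins)) bins <- bin_genes_by_snp_count(snp_counts, n_bins)
  stopifnot(inherits(bins, "gene_bins"))
  bin <- bins$bin[universe]
  is_sig <- universe %in% sig_genes
  observed_gene <- sum(target %in% sig_genes)
  observed_snp <- sum(snp_counts[target])

  tb <- table(factor(bin[target], levels = seq_len(bins$n_bins)))
  null_gene <- integer(R)
  null_snp <- numeric(R)
  set.seed(seed)
  pools <- lapply(seq_len(bins$n_bins), function(b) {
    pool <- universe[bin == b]
    if (exclude_target) pool <- setdiff(pool, target)
    pool
  })
  for (b in seq_len(bins$n_bins)) {
    k <- as.integer(tb[b])
    if (k == 0) next
    pool <- pools[[b]]
    if (!replace && length(pool) < k)
      stop("bin ", b, " holds ", length(pool), " universe genes but ", k,
           " target genes; use replace = TRUE for with-replacement draws")
    pool_sig <- is_sig[match(pool, universe)]
    pool_cnt <- unname(snp_counts[pool])
    np <- length(pool)
    for (r in seq_len(R)) {
      idx <- if (replace) sample.int(np, k, replace = TRUE)
             else sample.int(np, k)
      null_gene[r] <- null_gene[r] + sum(pool_sig[idx])
      null_snp[r] <- null_snp[r] + sum(pool_cnt[idx])
    }
  }
  p_gene <- (1 + sum(null_gene >= observed_gene)) / (R + 1)
  p_up <- (1 + sum(null_snp >= observed_snp)) / (R + 1)
  p_lo <- (1 + sum(null_snp <= observed_snp)) / (R + 1)
  p_snp <- min(1, 2 * min(p_up, p_lo))
  structure(list(observed_gene_count = observed_gene,
                 observed_snp_count = observed_snp,
                 R = R, null_gene_counts = null_gene,
                 null_snp_counts = null_snp,
                 p_gene = p_gene, p_snp = p_snp,
                 n_target = length(target), bins = bins, seed = seed,
                 replace = replace, exclude_target = exclude_target),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("SNP-count-matched resampling enrichment test\n")
  cat(sprintf("  target: %d genes; observed %d with >= 1 significant SNP\n",
              x$n_target, x$observed_gene_count))
  cat(sprintf("  null (R = %d resamples): mean %.1f significant genes\n",
              x$R, mean(x$null_gene_counts)))
  cat(sprintf("  empirical p (gene count, upper tail) = %.4g\n", x$p_gene))
  cat(sprintf("  SNP-count matching diagnostic: observed %d vs null mean %.0f, two-sided p = %.4g\n",
              x$observed_snp_count, mean(x$null_snp_counts), x$p_snp))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Thin wrapper over [stats::chisq.test()] with the continuity correction
#' off by default, used for the genic-vs-intergenic comparison.
#'
#' @param tab 2x2 contingency table (matrix).
#' @param correct apply Yates continuity correction.
#' @return list with `chi2`, `p`, `table`.
#' @export
genic_table_test <- function(tab, correct = FALSE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2, 2)))
  ct <- stats::chisq.test(tab, correct = correct)
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Genic enrichment of significant SNPs vs MAF-matched controls
#'
#' Draws, for each significant SNP, one non-significant control SNP
#' uniformly from its MAF window (|MAF difference| <= `maf_window`), then
#' compares genic/intergenic composition of the significant and control
#' sets with a Pearson chi-squared test (1 df, two-sided, no continuity
#' correction by default).
#'
#' @param sig_snps character vector of significant SNP ids.
#' @param maf named numeric vector, SNP -> MAF, covering all SNPs.
#' @param genic_flags named logical vector, SNP -> genic status.
#' @param maf_window half-width of the MAF matching window.
#' @param seed integer seed for the control draw.
#' @param correct continuity correction flag, passed through.
#' @return list with `chi2`, `p`, `table` (2x2: set x genic) and `controls`.
#' @export
genic_chisq <- function(sig_snps, maf, genic_flags, maf_window = 0.01,
                        seed = 1, correct = FALSE) {
  if (length(sig_snps) == 0) stop("no significant SNPs")
  all_snps <- names(maf)
  if (!all(sig_snps %in% all_snps)) stop("significant SNPs missing from maf")
  pool <- setdiff(all_snps, sig_snps)
  set.seed(seed)
  controls <- character(length(sig_snps))
  empty <- character(0)
  for (i in seq_along(sig_snps)) {
    w <- pool[abs(maf[pool] - maf[[sig_snps[i]]]) <= maf_window]
    if (length(w) == 0) { empty <- c(empty, sig_snps[i]); next }
    controls[i] <- w[sample.int(length(w), 1)]
  }
  if (length(empty) > 0)
    stop("no MAF-matched control available for: ",
         paste(utils::head(empty), collapse = ", "))
  tab <- rbind(significant = c(genic = sum(genic_flags[sig_snps]),
                               intergenic = sum(!genic_flags[sig_snps])),
               control = c(sum(genic_flags[controls]),
                           sum(!genic_flags[controls])))
  colnames(tab) <- c("genic", "intergenic")
  res <- genic_table_test(tab, correct = correct)
  res$controls <- controls
  res
}
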