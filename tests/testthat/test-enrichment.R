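test_that("quantile binning partitions genes by SNP count", {
  counts <- setNames(1:24, sprintf("g%02d", 1:24))
  b <- bin_genes_by_snp_count(counts, n_bins = 24)
  expect_equal(b$n_bins, 24)
  expect_identical(as.integer(table(b$bin)), rep(1L, 24))

  same <- setNames(rep(7L, 50), sprintf("g%02d", 1:50))
  bs <- bin_genes_by_snp_count(same, n_bins = 24)
  expect_equal(length(unique(bs$bin)), 1)

  # counts {1 x 100, 50 x 100}, 2 bins: split exactly at the count gap
  mixed <- setNames(rep(c(1L, 50L), each = 100), sprintf("g%03d", 1:200))
  bm <- bin_genes_by_snp_count(mixed, n_bins = 2)
  expect_equal(length(unique(bm$bin[mixed == 1])), 1)
  expect_equal(length(unique(bm$bin[mixed == 50])), 1)
  expect_true(all(bm$bin[mixed == 1] != bm$bin[mixed == 50]))

  expect_error(bin_genes_by_snp_count(setNames(integer(0), character(0))),
               "empty")
  expect_error(bin_genes_by_snp_count(setNames(c(0L, 2L), c("a", "b"))),
               ">= 1")
})

test_that("degenerate resampling cases give p = 1", {
  counts <- setNames(rep(3L, 20), sprintf("g%02d", 1:20))
  # target = universe, single bin: every resample permutes the universe
  r <- resample_enrichment(names(counts), counts,
                           sig_genes = names(counts)[1:4], R = 200, seed = 5)
  expect_true(all(r$null_gene_counts == r$observed_gene_count))
  expect_equal(r$p_gene, 1)
  # no significant genes anywhere
  r0 <- resample_enrichment(names(counts)[1:5], counts,
                            sig_genes = character(0), R = 200, seed = 5)
  expect_equal(r0$observed_gene_count, 0)
  expect_true(all(r0$null_gene_counts == 0))
  expect_equal(r0$p_gene, 1)
})

test_that("resampling is seed-reproducible and matches bins exactly", {
  set.seed(41)
  counts <- setNames(c(rep(1L, 40), rep(100L, 40)), sprintf("g%02d", 1:80))
  target <- c(names(counts)[1:3], names(counts)[41:42])  # 3 small + 2 large
  sig <- sample(names(counts), 10)
  r1 <- resample_enrichment(target, counts, sig, R = 300, seed = 9,
                            n_bins = 2)
  r2 <- resample_enrichment(target, counts, sig, R = 300, seed = 9,
                            n_bins = 2)
  expect_identical(r1$null_gene_counts, r2$null_gene_counts)
  expect_false(identical(
    r1$null_gene_counts,
    resample_enrichment(target, counts, sig, R = 300, seed = 10,
                        n_bins = 2)$null_gene_counts))
  # bin composition of each resample equals the target's by construction:
  # 3 genes of count 1 + 2 genes of count 100 -> total SNP count always 203
  expect_true(all(r1$null_snp_counts == 3 * 1 + 2 * 100))
})

test_that("empirical p uses (1+k)/(1+R) and responds to the observed count", {
  counts <- setNames(c(rep(1L, 30), rep(9L, 10)), sprintf("g%02d", 1:40))
  target <- names(counts)[31:35]           # all in the count-9 bin
  sig <- names(counts)[31:40]              # the whole count-9 bin significant
  r <- resample_enrichment(target, counts, sig, R = 100, seed = 3, n_bins = 2)
  # every draw from the count-9 bin is significant: null == observed == 5
  expect_equal(r$observed_gene_count, 5)
  expect_equal(r$p_gene, 1)
  # monotonicity of the estimator in the observed count, null held fixed
  p_at <- function(obs) (1 + sum(r$null_gene_counts >= obs)) / (r$R + 1)
  expect_true(all(diff(sapply(0:6, p_at)) <= 0))
})

test_that("exhausted bins error and with-replacement mode lifts the limit", {
  counts <- setNames(c(1L, 1L, 50L), c("gA", "gB", "gC"))
  expect_error(resample_enrichment(c("gA", "gB", "gC"), counts,
                                   sig_genes = "gA", R = 10, seed = 1,
                                   n_bins = 2, exclude_target = TRUE),
               "replace")
  r <- resample_enrichment(c("gA", "gB", "gC"), counts, sig_genes = "gA",
                           R = 10, seed = 1, n_bins = 2, replace = TRUE)
  expect_length(r$null_gene_counts, 10)
})

test_that("the 2x2 Pearson chi-squared matches hand-computed values", {
  flat <- matrix(c(50, 50, 50, 50), 2)
  expect_equal(genic_table_test(flat)$chi2, 0)
  expect_equal(genic_table_test(flat)$p, 1)
  skewed <- matrix(c(30, 10, 10, 30), 2)
  res <- genic_table_test(skewed)
  expect_equal(res$chi2, 20)
  expect_equal(res$p, pchisq(20, df = 1, lower.tail = FALSE))
  expect_lt(abs(res$p - 7.7e-6), 1e-7)
})

test_that("genic chi-squared draws MAF-matched controls", {
  set.seed(42)
  n <- 400
  maf <- setNames(runif(n, 0.05, 0.5), sprintf("s%03d", 1:n))
  genic <- setNames(runif(n) < 0.4, names(maf))
  sig <- names(maf)[1:30]
  res <- genic_chisq(sig, maf, genic, maf_window = 0.05, seed = 7)
  expect_length(res$controls, 30)
  expect_true(all(abs(maf[res$controls] - maf[sig]) <= 0.05))
  expect_false(any(res$controls %in% sig))
  expect_equal(sum(res$table), 60)
  # an isolated MAF island has no control: named error
  maf2 <- c(maf, lonely = 0.9)  # folded MAF cannot reach 0.9; isolated
  genic2 <- c(genic, lonely = TRUE)
  expect_error(genic_chisq(c(sig, "lonely"), maf2, genic2,
                           maf_window = 0.01, seed = 7), "lonely")
})

test_that("resampling p is calibrated under random significance flags", {
  set.seed(43)
  n_univ <- 600
  counts <- setNames(rpois(n_univ, 5) + 1L, sprintf("g%04d", 1:n_univ))
  rej <- 0
  n_rep <- 60
  for (i in 1:n_rep) {
    sig <- sample(names(counts), 30)
    target <- sample(names(counts), 60)
    r <- resample_enrichment(target, counts, sig, R = 400,
                             seed = 1000 + i, n_bins = 10)
    if (r$p_gene < 0.05) rej <- rej + 1
  }
  # loose binomial band around 0.05 for 60 replicates
  expect_lt(rej / n_rep, 0.15)
})
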