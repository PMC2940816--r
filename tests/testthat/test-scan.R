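make_panel_env <- function(n_countries = 6, pops_per_country = 2) {
  env <- rep(seq_len(n_countries), each = pops_per_country)
  names(env) <- sprintf("c%d_p%d", rep(seq_len(n_countries),
                                       each = pops_per_country),
                        rep(seq_len(pops_per_country), n_countries))
  env
}

test_that("MAF folds the across-population mean frequency", {
  expect_equal(compute_maf(c(0.2, 0.4, 0.6)), 0.4)
  expect_equal(compute_maf(c(0.9, 0.8, 1.0)), 0.1)
  expect_equal(compute_maf(0.5), 0.5)
  expect_equal(compute_maf(c(0.2, NA, 0.4)), 0.3)
  expect_error(compute_maf(rbind(a = c(NA_real_, NA_real_))), "missing")
})

test_that("Bonferroni threshold is alpha over the attempted test count", {
  expect_equal(signif(bonferroni_threshold(660832, 0.05), 2), 7.6e-8)
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(100, 0.01), 1e-4)
  expect_error(bonferroni_threshold(0), ">= 1")
})

test_that("a monotone function of the environment attains the tie-bound tau", {
  env <- make_panel_env(6, 2)   # 12 populations, 6 countries -> ties
  freq <- rbind(mono = plogis(0.5 * env - 2))
  colnames(freq) <- names(env)
  sc <- env_scan(freq, env, scan_config(min_n = 11))
  expect_equal(sc$records$tau_oriented, kendall_cor(env, env)$tau)
  expect_equal(sc$records$tau_oriented, 1)
  expect_identical(sc$records$orientation, "ref")
})

test_that("allele relabelling flips orientation but nothing else", {
  set.seed(21)
  env <- make_panel_env(6, 2)
  f <- matrix(runif(20 * 12), 20, 12,
              dimnames = list(sprintf("s%02d", 1:20), names(env)))
  f2 <- f
  f2[5, ] <- 1 - f2[5, ]
  s1 <- env_scan(f, env)
  s2 <- env_scan(f2, env)
  expect_equal(s2$records$tau_oriented, s1$records$tau_oriented)
  expect_equal(s2$records$p, s1$records$p)
  expect_equal(s2$records$maf, s1$records$maf)
  expect_identical(s2$records$significant, s1$records$significant)
  expect_identical(s2$records$orientation[5],
                   setdiff(c("ref", "alt"), s1$records$orientation[5]))
  expect_identical(s2$records$orientation[-5], s1$records$orientation[-5])
})

test_that("scan output is invariant to SNP and population order", {
  set.seed(22)
  env <- make_panel_env(6, 2)
  f <- matrix(runif(15 * 12), 15, 12,
              dimnames = list(sprintf("s%02d", 1:15), names(env)))
  s1 <- env_scan(f, env)
  perm_snp <- sample(15)
  perm_pop <- sample(12)
  s2 <- env_scan(f[perm_snp, perm_pop], env[perm_pop])
  r1 <- s1$records[order(s1$records$snp), ]
  r2 <- s2$records[order(s2$records$snp), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("degenerate and under-covered SNPs are flagged, not fatal", {
  env <- make_panel_env(6, 2)
  f <- rbind(const = rep(0.4, 12),
             sparse = c(runif(5), rep(NA, 7)),
             ok = runif(12))
  colnames(f) <- names(env)
  sc <- env_scan(f, env, scan_config(min_n = 11))
  r <- sc$records
  expect_true(r$flagged[r$snp == "const"])
  expect_true(r$flagged[r$snp == "sparse"])
  expect_false(r$flagged[r$snp == "ok"])
  expect_false(any(r$significant[r$flagged]))
  expect_equal(r$p[r$snp == "const"], 1)
  # flagged SNPs still counted in the Bonferroni m
  expect_equal(sc$m, 3)
  expect_error(env_scan(f, setNames(numeric(0), character(0))),
               "no overlapping")
})

test_that("the percentile gate is a strict nearest-rank exceedance test", {
  cfg <- scan_config()
  base <- data.frame(snp = sprintf("s%03d", 1:100), maf = 0.3,
                     tau_oriented = seq(0.001, 0.1, length.out = 100),
                     flagged = FALSE, percentile_rank = NA_real_,
                     window_size = NA_integer_, pass_bonferroni = FALSE,
                     pass_percentile = FALSE, significant = FALSE)
  r <- maf_matched_percentile(base, cfg)
  expect_equal(r$percentile_rank[100], 1)
  expect_true(r$pass_percentile[100])
  expect_equal(sum(r$pass_percentile), 5)   # strictly above the 95th of 100

  # all |tau| equal: nothing can strictly exceed the percentile
  tied <- base; tied$tau_oriented <- 0.5
  expect_false(any(maf_matched_percentile(tied, cfg)$pass_percentile))

  # singleton window: cannot exceed its own value
  solo <- base[1:2, ]; solo$maf <- c(0.1, 0.4)
  rs <- maf_matched_percentile(solo, cfg)
  expect_identical(rs$window_size, c(1L, 1L))
  expect_false(any(rs$pass_percentile))
})

test_that("significance is the conjunction of the two gates", {
  rec <- data.frame(pass_bonferroni = c(TRUE, TRUE, FALSE, FALSE),
                    pass_percentile = c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(call_significant(rec)$significant,
                   c(TRUE, FALSE, FALSE, FALSE))
})

test_that("climate re-test reproduces the scan on an identical variable", {
  set.seed(23)
  env <- make_panel_env(8, 2)
  # enough SNPs that the planted one has a well-populated MAF window
  # (nearest-rank 95th percentile of a window of <= 20 is the window max,
  # which no member can strictly exceed)
  f <- matrix(runif(300 * 16), 300, 16,
              dimnames = list(sprintf("s%03d", 1:300), names(env)))
  # force a significant call by planting a monotone SNP
  f[1, ] <- plogis(env - 4) + rnorm(16, sd = 0.001)
  sc <- env_scan(f, env, scan_config(alpha = 0.5, min_n = 11))
  sig <- sc$records$snp[sc$records$significant]
  expect_true(length(sig) >= 1)
  cc <- climate_confound_check(sc, f, list(same = env), alpha = 0.5)
  idx <- match(cc$snp, sc$records$snp)
  expect_equal(cc$p, sc$records$p[idx], tolerance = 1e-12)
  # constant climate vector: everything degenerate, nothing passes
  cc0 <- climate_confound_check(sc, f, list(flat = env * 0), alpha = 0.5)
  expect_false(any(cc0$pass))
  expect_true(all(cc0$p == 1))
})

test_that("scan records round-trip through the TSV writer", {
  set.seed(24)
  env <- make_panel_env(6, 2)
  f <- matrix(runif(8 * 12), 8, 12,
              dimnames = list(sprintf("s%02d", 1:8), names(env)))
  sc <- env_scan(f, env)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scan_tsv(sc, path)
  back <- read.delim(path)
  expect_identical(as.character(back$snp), sc$records$snp)
  expect_equal(back$tau, sc$records$tau, tolerance = 1e-12)
  expect_identical(back$significant, sc$records$significant)
})
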