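#' Scan configuration
#'
#' Tuning parameters of the genome-wide environmental-correlation scan.
#'
#' @param alpha family-wise error rate for the Bonferroni gate: 0.05 for
#'   genome-wide scans; 0.01 was used for the immune-gene-set analysis.
#' @param maf_window half-width of the MAF matching window (absolute,
#'   default 0.01: SNPs with minor allele frequency "in the 1% range").
#' @param percentile empirical-null cut: a SNP must exceed this percentile
#'   of |tau| among its MAF-window peers (default 0.95).
#' @param min_n minimum pairwise-complete populations per SNP; below this
#'   the record is flagged and excluded from the gates. Default 11, the
#'   smallest n for which the normal approximation of tau is considered
#'   valid.
#' @return a list of class `"scan_config"`.
#' @export
scan_config <- function(alpha = 0.05, maf_window = 0.01, percentile = 0.95,
                        min_n = 11) {
  stopifnot(alpha > 0, alpha < 1, percentile > 0, percentile < 1,
            maf_window > 0, min_n >= 3)
  structure(list(alpha = alpha, maf_window = maf_window,
                 percentile = percentile, min_n = as.integer(min_n)),
            class = "scan_config")
}

#' Read a SNP x population frequency matrix
#'
#' TSV with header `snp pop1 pop2 ...`, one row per SNP, cells the
#' reference-allele frequency in that population (may be empty/NA).
#'
#' @param path TSV file path.
#' @return numeric matrix with SNP rownames and population colnames.
#' @export
read_freq_matrix <- function(path) {
  if (!file.exists(path)) stop("frequency matrix not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE)
  if (ncol(d) < 2 || names(d)[1] != "snp")
    stop("malformed frequency matrix ", path, ": first column must be 'snp'")
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(d$snp)
  if (anyDuplicated(rownames(m))) stop("duplicate SNP ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate population ids in ", path)
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("frequencies outside [0, 1] in ", path)
  m
}

#' Minor allele frequency from per-population frequencies
#'
#' The across-population MAF of a SNP is the unweighted mean of its
#' non-missing per-population reference-allele frequencies, folded onto
#' [0, 0.5]: maf = min(mean f, 1 - mean f).
#'
#' @param freq numeric matrix (SNPs x populations) or a single row vector.
#' @return numeric vector of MAFs, one per SNP.
#' @examples
#' compute_maf(rbind(c(0.2, 0.4, 0.6), c(0.9, 0.8, 1.0)))  # 0.4, 0.1
#' @export
compute_maf <- function(freq) {
  if (is.null(dim(freq))) freq <- matrix(freq, nrow = 1)
  n_ok <- rowSums(!is.na(freq))
  if (any(n_ok == 0))
    stop("SNP(s) with all frequencies missing: ",
         paste(utils::head(rownames(freq)[n_ok == 0]), collapse = ", "))
  fbar <- rowMeans(freq, na.rm = TRUE)
  pmin(fbar, 1 - fbar)
}

#' Bonferroni per-test threshold
#'
#' @param m number of tests attempted (for the genome-wide scan, the number
#'   of SNPs, including degenerate/flagged records).
#' @param alpha family-wise error rate.
#' @return the per-test p-value threshold alpha / m.
#' @examples
#' bonferroni_threshold(660832, 0.05)  # 7.6e-8 at two significant figures
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("m must be a count >= 1")
  alpha / m
}

#' Genome-wide environmental-correlation scan
#'
#' For every SNP, computes the tie-corrected Kendall correlation (tau-b)
#' between its per-population reference-allele frequencies and a
#' population-level environmental variable (typically helminth diversity
#' broadcast from countries, so the variable carries ties by construction).
#' Two significance gates are then applied:
#'
#' * **Bonferroni**: two-sided normal-approximation p below `alpha / m`,
#'   with m the number of SNPs attempted;
#' * **MAF-matched empirical null**: |tau| strictly above the
#'   `percentile` (default 95th) nearest-rank percentile of |tau| among
#'   all SNPs whose MAF lies within `maf_window` of the SNP's own. This
#'   gate absorbs the frequency-dependent inflation of correlations that
#'   drift and shared population history produce under the null.
#'
#' A SNP is called significant only if it passes both gates. Orientation is
#' per-SNP arbitrary (which allele is "reference" carries no information),
#' so the gates operate on |tau| and the sign is reported as an orientation
#' flag naming the positively correlated allele.
#'
#' @param freqs numeric matrix, SNPs x populations, reference-allele
#'   frequencies in [0,1]; NA allowed (pairwise deletion per SNP).
#' @param env named numeric vector, population -> environmental value; its
#'   populations must all be columns of `freqs`.
#' @param config a [scan_config()].
#' @return an object of class `"env_scan"`: list with `records` (one row
#'   per SNP: snp, n_used, tau, tau_oriented, orientation, p, maf,
#'   percentile_rank, window_size, pass_bonferroni, pass_percentile,
#'   significant, flagged), `config`, `m`, `p_threshold`, `env_name`.
#' @export
env_scan <- function(freqs, env, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (is.null(colnames(freqs)) || is.null(rownames(freqs)))
    stop("freqs needs SNP rownames and population colnames")
  missing_pops <- setdiff(names(env), colnames(freqs))
  if (length(missing_pops) > 0)
    stop("environment populations absent from the frequency matrix: ",
         paste(missing_pops, collapse = ", "))
  if (length(env) == 0) stop("no overlapping populations")
  f <- freqs[, names(env), drop = FALSE]

  st <- cpp_kendall_scan(f, as.numeric(env))
  n_used <- as.integer(st[, "n"])
  tau <- st[, "tau"]
  var_S <- st[, "var_S"]
  degen <- st[, "degenerate"] == 1 | !is.finite(var_S) | var_S <= 0
  z <- ifelse(degen, NA_real_, st[, "S"] / sqrt(var_S))
  p <- ifelse(degen, 1, 2 * stats::pnorm(-abs(z)))
  p <- pmin(p, 1)

  maf <- compute_maf(f)
  flagged <- degen | n_used < config$min_n

  records <- data.frame(
    snp = rownames(f),
    n_used = n_used,
    tau = tau,
    tau_oriented = abs(tau),
    orientation = ifelse(is.na(tau) | tau >= 0, "ref", "alt"),
    p = p,
    maf = maf,
    percentile_rank = NA_real_,
    window_size = NA_integer_,
    pass_bonferroni = FALSE,
    pass_percentile = FALSE,
    significant = FALSE,
    flagged = flagged,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL

  m <- nrow(records)  # all SNPs attempted, flagged ones included
  thr <- bonferroni_threshold(m, config$alpha)
  records$pass_bonferroni <- !flagged & records$p < thr
  records <- maf_matched_percentile(records, config)
  records <- call_significant(records)

  structure(list(records = records, config = config, m = m,
                 p_threshold = thr, n_populations = length(env)),
            class = "env_scan")
}

#' MAF-matched empirical percentile gate
#'
#' For each usable SNP i the window W(i) collects every usable SNP whose
#' MAF is within `maf_window` of MAF_i (the focal SNP included). The gate
#' passes when |tau_i| strictly exceeds the nearest-rank `percentile`
#' percentile of |tau| over W(i). A window of size 1 cannot be exceeded, so
#' such SNPs fail the gate. Flagged records (degenerate or under-powered)
#' neither receive a rank nor enter anyone's window.
#'
#' @param records the scan record data.frame (needs columns maf,
#'   tau_oriented, flagged).
#' @param config a [scan_config()].
#' @return `records` with percentile_rank, window_size and pass_percentile
#'   filled.
#' @export
maf_matched_percentile <- function(records, config = scan_config()) {
  usable <- which(!records$flagged & !is.na(records$tau_oriented))
  records$pass_percentile <- FALSE
  if (length(usable) < 2) return(records)
  ord <- usable[order(records$maf[usable])]
  res <- cpp_window_percentile(records$maf[ord], records$tau_oriented[ord],
                               config$maf_window, config$percentile)
  records$percentile_rank[ord] <- res$rank
  records$window_size[ord] <- res$window_size
  records$pass_percentile[ord] <- res$window_size > 1 &
    records$tau_oriented[ord] > res$q
  records
}

#' Combine the two significance gates
#'
#' @param records scan records with pass_bonferroni and pass_percentile set.
#' @return `records` with `significant = pass_bonferroni & pass_percentile`.
#' @export
call_significant <- function(records) {
  records$significant <- records$pass_bonferroni & records$pass_percentile
  records
}

#' Re-test significant SNPs against climate variables
#'
#' For every scan-significant SNP and every climate variable (broadcast to
#' populations the same way as the scan variable), computes the Kendall
#' correlation and applies a Bonferroni correction *within this analysis*
#' (m = number of significant SNPs, per variable). A SNP whose association
#' is climate-driven is expected to withstand this correction for some
#' climate variable; in the original analysis none did.
#'
#' @param scan an `"env_scan"` object.
#' @param freqs the frequency matrix the scan was run on.
#' @param climate_envs named list of population-level climate vectors.
#' @param alpha family-wise rate for the within-analysis Bonferroni.
#' @return data.frame with columns snp, variable, tau, p, pass.
#' @export
climate_confound_check <- function(scan, freqs, climate_envs, alpha = 0.05) {
  stopifnot(inherits(scan, "env_scan"))
  sig <- scan$records$snp[scan$records$significant]
  if (length(sig) == 0)
    return(data.frame(snp = character(), variable = character(),
                      tau = numeric(), p = numeric(), pass = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(names(climate_envs)) || any(names(climate_envs) == ""))
    stop("climate_envs must be a named list")
  out <- lapply(names(climate_envs), function(v) {
    env <- climate_envs[[v]]
    f <- freqs[sig, names(env), drop = FALSE]
    st <- cpp_kendall_scan(f, as.numeric(env))
    degen <- st[, "degenerate"] == 1 | !is.finite(st[, "var_S"]) |
      st[, "var_S"] <= 0
    z <- ifelse(degen, NA_real_, st[, "S"] / sqrt(st[, "var_S"]))
    p <- pmin(ifelse(degen, 1, 2 * stats::pnorm(-abs(z))), 1)
    data.frame(snp = sig, variable = v, tau = st[, "tau"], p = p,
               pass = p < alpha / length(sig), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write scan records to TSV
#'
#' Columns `snp tau p maf percentile_rank significant` plus, when a gene
#' annotation has been joined in, `gene distance`.
#'
#' @param scan an `"env_scan"` object or its records data.frame.
#' @param path output TSV path.
#' @export
write_scan_tsv <- function(scan, path) {
  rec <- if (inherits(scan, "env_scan")) scan$records else scan
  cols <- intersect(c("snp", "tau", "p", "maf", "percentile_rank",
                      "significant", "gene", "distance"), names(rec))
  utils::write.table(rec[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.env_scan <- function(x, ...) {
  r <- x$records
  cat("Environmental-correlation selection scan\n")
  cat(sprintf("  %d SNPs x %d populations; Bonferroni alpha = %g (p < %.3g)\n",
              nrow(r), x$n_populations, x$config$alpha, x$p_threshold))
  cat(sprintf("  flagged (degenerate or n < %d): %d\n",
              x$config$min_n, sum(r$flagged)))
  cat(sprintf("  pass Bonferroni: %d; pass %g%% MAF-matched percentile: %d\n",
              sum(r$pass_bonferroni), 100 * x$config$percentile,
              sum(r$pass_percentile)))
  cat(sprintf("  significant (both gates): %d\n", sum(r$significant)))
  invisible(x)
}

#' @export
summary.env_scan <- function(object, ...) {
  r <- object$records
  s <- list(
    n_snps = nrow(r),
    n_flagged = sum(r$flagged),
    p_threshold = object$p_threshold,
    n_bonferroni = sum(r$pass_bonferroni),
    n_percentile = sum(r$pass_percentile),
    n_significant = sum(r$significant),
    top = utils::head(r[order(r$p), c("snp", "tau", "p", "maf",
                                      "percentile_rank", "significant")], 10)
  )
  class(s) <- "summary.env_scan"
  s
}

#' @export
print.summary.env_scan <- function(x, ...) {
  cat(sprintf("env_scan: %d SNPs (%d flagged), p threshold %.3g\n",
              x$n_snps, x$n_flagged, x$p_threshold))
  cat(sprintf("gates: %d Bonferroni, %d percentile, %d significant\n",
              x$n_bonferroni, x$n_percentile, x$n_significant))
  cat("top SNPs by p:\n")
  print(x$top, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Diagnostic plot of a scan
#'
#' |tau| against MAF, with significant SNPs highlighted — the visual
#' counterpart of the MAF-matched percentile gate (the elevated null |tau|
#' at low MAF is the inflation the gate corrects for).
#'
#' @param x an `"env_scan"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.env_scan <- function(x, ...) {
  r <- x$records[!x$records$flagged, ]
  graphics::plot(r$maf, r$tau_oriented, pch = 16, cex = 0.4,
                 col = ifelse(r$significant, "firebrick", "grey60"),
                 xlab = "MAF (across-population mean, folded)",
                 ylab = "|tau|", ...)
  graphics::legend("topright", pch = 16, col = c("grey60", "firebrick"),
                   legend = c("not significant", "significant"), bty = "n")
  invisible(x)
}
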