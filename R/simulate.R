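#' Simulation configuration
#'
#' Parameters of the synthetic study panel. Defaults emulate a worldwide
#' multi-country genotyping panel at desk scale: 10 countries x 5
#' populations, 20,000 neutral SNPs plus 50 SNPs under planted
#' environmental selection, Balding-Nichols drift with F = 0.05 between
#' countries and F = 0.01 between populations within a country, and an
#' integer environmental gradient (one value per country, shared by its
#' populations — the tie structure of a per-country diversity count).
#'
#' @param n_countries number of countries.
#' @param pops_per_country populations sampled per country.
#' @param n_snps number of neutral SNPs.
#' @param n_selected number of planted selected SNPs (frequency a logistic
#'   function of the environment).
#' @param F_country,F_pop Balding-Nichols dispersion between countries and
#'   between populations within a country, each in (0, 1).
#' @param beta logistic slope of planted selection on the standardized
#'   environment.
#' @param env_values per-country environmental values; default the integer
#'   gradient 1..n_countries.
#' @param n_genes,gene_length_range,chrom_length synthetic gene annotation:
#'   non-overlapping genes placed uniformly on one chromosome.
#' @param target_set_size size of the target gene set (the synthetic
#'   "immune gene" list).
#' @param target_enrichment_odds odds with which a planted selected SNP
#'   lands in a target-set gene rather than a background gene (1 = no
#'   enrichment).
#' @param missing_rate fraction of frequency cells set missing.
#' @param seed integer seed; the single seed drives the whole generator.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_countries = 10, pops_per_country = 5,
                       n_snps = 20000, n_selected = 50,
                       F_country = 0.05, F_pop = 0.01, beta = 8,
                       env_values = NULL,
                       n_genes = 2000, gene_length_range = c(5000, 20000),
                       chrom_length = 1e8, target_set_size = 200,
                       target_enrichment_odds = 1, missing_rate = 0,
                       seed = 1) {
  stopifnot(n_selected <= n_snps, n_selected >= 0,
            F_country > 0, F_country < 1, F_pop > 0, F_pop < 1,
            missing_rate >= 0, missing_rate < 1)
  if (length(gene_length_range) != 2 ||
      gene_length_range[1] > gene_length_range[2] || gene_length_range[1] < 1)
    stop("gene_length_range must be c(min, max) with 1 <= min <= max")
  if (is.null(env_values)) env_values <- seq_len(n_countries)
  if (length(env_values) != n_countries)
    stop("env_values must have one value per country")
  structure(list(n_countries = n_countries,
                 pops_per_country = pops_per_country,
                 n_snps = n_snps, n_selected = n_selected,
                 F_country = F_country, F_pop = F_pop, beta = beta,
                 env_values = env_values, n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 chrom_length = chrom_length,
                 target_set_size = target_set_size,
                 target_enrichment_odds = target_enrichment_odds,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# Balding-Nichols draw: Beta around p with dispersion F
.rbn <- function(p, F) {
  a <- p * (1 - F) / F
  b <- (1 - p) * (1 - F) / F
  x <- stats::rbeta(length(p), a, b)
  pmin(pmax(x, 1e-12), 1 - 1e-12)
}

#' Neutral allele frequencies under hierarchical drift
#'
#' Per SNP: ancestral frequency p0 ~ Uniform(0.05, 0.95); per country a
#' Balding-Nichols Beta draw around p0 with dispersion `F_country`; per
#' population a Balding-Nichols draw around its country frequency with
#' `F_pop`. Country-level draws are shared by all populations of a country,
#' which is what correlates allele frequencies with any country-constant
#' variable under the null and motivates the MAF-matched gate.
#'
#' @param n_snps number of SNPs to draw.
#' @param cfg a [sim_config()].
#' @return list with `freq` (n_snps x populations matrix) and `p0`.
#' @export
simulate_neutral_freqs <- function(n_snps, cfg) {
  K <- cfg$n_countries
  P <- cfg$pops_per_country
  p0 <- stats::runif(n_snps, 0.05, 0.95)
  country <- matrix(.rbn(rep(p0, K), cfg$F_country), n_snps, K)
  freq <- matrix(NA_real_, n_snps, K * P)
  for (k in seq_len(K)) {
    cols <- (k - 1) * P + seq_len(P)
    for (j in cols)
      freq[, j] <- .rbn(country[, k], cfg$F_pop)
  }
  list(freq = freq, p0 = p0)
}

#' Planted selected allele frequencies
#'
#' Per selected SNP: intercept a ~ Uniform(-1, 1); country-level mean
#' frequency logistic(a + beta * z) with z the standardized environment;
#' population frequencies Balding-Nichols around the country mean with
#' `F_pop`. With beta = 0 this reduces to the neutral model with
#' p0 = logistic(a) and no between-country drift beyond F_pop.
#'
#' @param n_sel number of selected SNPs.
#' @param cfg a [sim_config()].
#' @return list with `freq` matrix, `intercept`, `slope`.
#' @export
simulate_selected_freqs <- function(n_sel, cfg) {
  K <- cfg$n_countries
  P <- cfg$pops_per_country
  z <- as.numeric(scale(cfg$env_values))
  a <- stats::runif(n_sel, -1, 1)
  country <- stats::plogis(outer(a, cfg$beta * z, `+`))
  freq <- matrix(NA_real_, n_sel, K * P)
  for (k in seq_len(K)) {
    cols <- (k - 1) * P + seq_len(P)
    for (j in cols)
      freq[, j] <- .rbn(country[, k], cfg$F_pop)
  }
  list(freq = freq, intercept = a, slope = rep(cfg$beta, n_sel))
}

#' Synthetic gene annotation, SNP placement and target gene set
#'
#' Places `n_genes` non-overlapping genes of uniform random length uniformly
#' on one chromosome (random strand), samples a target gene set, and places
#' SNPs: neutral SNPs uniformly over the chromosome, selected SNPs inside
#' genes, choosing a target-set gene with odds `target_enrichment_odds` : 1
#' over a background gene (odds 1 makes placement uniform with respect to
#' target membership).
#'
#' @param cfg a [sim_config()].
#' @param snp_ids all SNP ids (neutral then selected).
#' @param selected logical vector parallel to `snp_ids`.
#' @return list with `genes`, `snps` (loci), `target_set`.
#' @export
simulate_annotation <- function(cfg, snp_ids, selected) {
  len <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                cfg$n_genes, replace = TRUE)
  total <- sum(as.numeric(len))
  if (total >= cfg$chrom_length)
    stop("cannot pack ", cfg$n_genes, " genes of total length ", total,
         " into a chromosome of length ", cfg$chrom_length)
  slack <- cfg$chrom_length - total
  gaps <- diff(c(0, sort(stats::runif(cfg$n_genes)), 1)) * slack
  starts <- floor(cumsum(gaps[seq_len(cfg$n_genes)]) +
                    cumsum(c(0, len[-cfg$n_genes])))
  genes <- data.frame(
    gene_id = sprintf("g%04d", seq_len(cfg$n_genes)),
    chrom = "chr1", start = as.integer(starts),
    end = as.integer(starts + len),
    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  target_set <- sort(sample(genes$gene_id, cfg$target_set_size))

  pos <- integer(length(snp_ids))
  n_neutral <- sum(!selected)
  pos[!selected] <- as.integer(floor(stats::runif(n_neutral, 0,
                                                  cfg$chrom_length)))
  n_sel <- sum(selected)
  if (n_sel > 0) {
    w <- ifelse(genes$gene_id %in% target_set,
                cfg$target_enrichment_odds, 1)
    gi <- sample.int(cfg$n_genes, n_sel, replace = TRUE, prob = w)
    pos[selected] <- as.integer(genes$start[gi] +
      floor(stats::runif(n_sel) * (genes$end[gi] - genes$start[gi])))
  }
  snps <- data.frame(snp_id = snp_ids, chrom = "chr1", pos = pos,
                     stringsAsFactors = FALSE)
  list(genes = genes, snps = snps, target_set = target_set)
}

#' Generate a complete synthetic study panel
#'
#' One seeded generator produces every pipeline input: population table,
#' country-level environment, SNP x population frequency matrix (neutral
#' drift plus planted selection), gene annotation, target gene set, and the
#' ground-truth labels. Identical config and seed give identical output.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"synthetic_panel"` with elements `freqs`, `env`
#'   (country -> value), `pops`, `pop_env`, `genes`, `snps`, `target_set`,
#'   `truth` (per-SNP selected flag, ancestral frequency/intercept, slope),
#'   `config`.
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$n_countries
  P <- cfg$pops_per_country
  countries <- sprintf("c%02d", seq_len(K))
  pops <- data.frame(
    population = sprintf("%s_p%d", rep(countries, each = P),
                         rep(seq_len(P), K)),
    country = rep(countries, each = P),
    lat = NA_real_, lon = NA_real_, stringsAsFactors = FALSE)
  env <- stats::setNames(as.numeric(cfg$env_values), countries)

  neu <- simulate_neutral_freqs(cfg$n_snps, cfg)
  sel <- if (cfg$n_selected > 0) simulate_selected_freqs(cfg$n_selected, cfg)
         else list(freq = matrix(NA_real_, 0, K * P), intercept = numeric(0),
                   slope = numeric(0))
  freq <- rbind(neu$freq, sel$freq)
  n_tot <- nrow(freq)
  snp_ids <- sprintf("snp%06d", seq_len(n_tot))
  selected <- c(rep(FALSE, cfg$n_snps), rep(TRUE, cfg$n_selected))
  rownames(freq) <- snp_ids
  colnames(freq) <- pops$population
  if (cfg$missing_rate > 0) {
    drop <- stats::runif(length(freq)) < cfg$missing_rate
    freq[drop] <- NA_real_
  }
  ann <- simulate_annotation(cfg, snp_ids, selected)
  truth <- data.frame(
    snp_id = snp_ids, selected = selected,
    anchor = c(neu$p0, stats::plogis(sel$intercept)),
    slope = c(rep(0, cfg$n_snps), sel$slope),
    stringsAsFactors = FALSE)
  structure(list(freqs = freq, env = env, pops = pops,
                 pop_env = broadcast_to_populations(env, pops),
                 genes = ann$genes, snps = ann$snps,
                 target_set = ann$target_set, truth = truth, config = cfg),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic study panel\n")
  cat(sprintf("  %d countries x %d populations; %d SNPs (%d planted selected, beta = %g)\n",
              x$config$n_countries, x$config$pops_per_country,
              nrow(x$freqs), sum(x$truth$selected), x$config$beta))
  cat(sprintf("  %d genes on one chromosome of %.3g bp; target set: %d genes (odds %g:1)\n",
              x$config$n_genes, x$config$chrom_length,
              length(x$target_set), x$config$target_enrichment_odds))
  invisible(x)
}

#' Write a synthetic panel to disk in the pipeline's input formats
#'
#' Emits `frequencies.tsv`, `populations.tsv`, `env.tsv`, `genes.bed`
#' (BED6), `snp_loci.tsv`, `target_genes.txt`, `truth.tsv` and a
#' `manifest.json` recording the config and seed.
#'
#' @param panel a `"synthetic_panel"`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(panel, out_dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  utils::write.table(
    data.frame(snp = rownames(panel$freqs), panel$freqs,
               check.names = FALSE),
    fp("frequencies.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$pops, fp("populations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(
    data.frame(country = names(panel$env), value = unname(panel$env)),
    fp("env.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  g <- panel$genes
  utils::write.table(
    data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand),
    fp("genes.bed"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(snp = panel$snps$snp_id, chrom = panel$snps$chrom,
               pos = panel$snps$pos),
    fp("snp_loci.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(panel$target_set, fp("target_genes.txt"))
  utils::write.table(panel$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- panel$config
  class(cfg) <- NULL
  jsonlite::write_json(list(config = cfg, seed = cfg$seed,
                            package_version =
                              as.character(utils::packageVersion("helminthscan"))),
                       fp("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Read a synthetic panel (or any pipeline dataset) back from disk
#'
#' @param dir directory written by [write_dataset()].
#' @return list with the same shaped elements (config restored from the
#'   manifest when present).
#' @export
read_dataset <- function(dir) {
  fp <- function(f) file.path(dir, f)
  freqs <- read_freq_matrix(fp("frequencies.tsv"))
  pops <- read_populations(fp("populations.tsv"))
  env <- read_env(fp("env.tsv"))
  genes <- read_genes_bed(fp("genes.bed"))
  snps <- read_snp_loci(fp("snp_loci.tsv"))
  target_set <- readLines(fp("target_genes.txt"))
  truth <- if (file.exists(fp("truth.tsv"))) {
    tr <- utils::read.delim(fp("truth.tsv"))
    tr$selected <- as.logical(tr$selected)
    tr$snp_id <- as.character(tr$snp_id)
    tr
  } else NULL
  cfg <- if (file.exists(fp("manifest.json")))
    jsonlite::read_json(fp("manifest.json"), simplifyVector = TRUE)$config
  else NULL
  list(freqs = freqs, pops = pops, env = env,
       pop_env = broadcast_to_populations(env, pops),
       genes = genes, snps = snps, target_set = target_set,
       truth = truth, config = cfg)
}
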