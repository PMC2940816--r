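.write_manifest <- function(out_dir, inputs, config, seed) {
  inputs <- inputs[file.exists(unlist(inputs))]
  jsonlite::write_json(
    list(inputs = lapply(inputs, function(f)
           list(path = f, md5 = unname(tools::md5sum(f)))),
         config = config, seed = seed,
         package_version = as.character(utils::packageVersion("helminthscan"))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.log <- function(...) message("[helminthscan] ", sprintf(...))

.require_files <- function(...) {
  files <- c(...)
  missing <- files[!file.exists(files)]
  if (length(missing) > 0)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
}

#' Run the simulator stage
#'
#' Generates a synthetic panel and writes it as a pipeline-ready dataset
#' directory.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  panel <- simulate_panel(cfg)
  write_dataset(panel, out_dir)
  .log("simulated %d SNPs x %d populations into %s",
       nrow(panel$freqs), ncol(panel$freqs), out_dir)
  invisible(out_dir)
}

#' Run the scan stage
#'
#' Reads the frequency matrix, country environment and population table,
#' broadcasts the environment to populations, runs [env_scan()], optionally
#' joins nearest-gene annotation, and writes `scan.tsv` plus a
#' `scan_summary.json` with the counts at each gate and a manifest.
#'
#' @param freq_file frequency TSV.
#' @param env_file country environment TSV.
#' @param pop_file population table TSV.
#' @param out_dir output directory.
#' @param config a [scan_config()].
#' @param genes_file optional BED6 gene models for nearest-gene annotation.
#' @param snp_file optional SNP loci file (required with `genes_file`).
#' @return the `"env_scan"` object, invisibly.
#' @export
run_scan <- function(freq_file, env_file, pop_file, out_dir,
                     config = scan_config(), genes_file = NULL,
                     snp_file = NULL) {
  .require_files(freq_file, env_file, pop_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- read_freq_matrix(freq_file)
  env <- read_env(env_file)
  pops <- read_populations(pop_file)
  pop_env <- broadcast_to_populations(env, pops)
  .log("scanning %d SNPs against '%s' over %d populations (%d countries)",
       nrow(freqs), basename(env_file), length(pop_env), length(env))
  scan <- env_scan(freqs, pop_env, config)
  rec <- scan$records
  if (!is.null(genes_file)) {
    if (is.null(snp_file)) stop("snp_file required with genes_file")
    .require_files(genes_file, snp_file)
    genes <- read_genes_bed(genes_file)
    loci <- read_snp_loci(snp_file)
    ng <- nearest_gene(loci, genes)
    idx <- match(rec$snp, ng$snp_id)
    rec$gene <- ng$gene[idx]
    rec$distance <- ng$distance[idx]
    scan$records <- rec
  }
  write_scan_tsv(scan, file.path(out_dir, "scan.tsv"))
  smry <- list(n_snps = scan$m, n_populations = scan$n_populations,
               p_threshold = scan$p_threshold,
               n_flagged = sum(rec$flagged),
               n_pass_bonferroni = sum(rec$pass_bonferroni),
               n_pass_percentile = sum(rec$pass_percentile),
               n_significant = sum(rec$significant))
  if (!is.null(rec$gene))
    smry$n_genes_with_significant <-
      length(unique(stats::na.omit(rec$gene[rec$significant & rec$distance == 0])))
  jsonlite::write_json(smry, file.path(out_dir, "scan_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfgl <- scan$config
  class(cfgl) <- NULL
  .write_manifest(out_dir,
                  list(freq = freq_file, env = env_file, pops = pop_file),
                  cfgl, seed = NA)
  .log("gates: %d Bonferroni, %d percentile, %d significant",
       smry$n_pass_bonferroni, smry$n_pass_percentile, smry$n_significant)
  invisible(scan)
}

#' Run the gene-set enrichment stage
#'
#' Assigns SNPs to genes under the upstream-window rule, counts typed SNPs
#' per gene (the resampling universe is every gene covered by at least one
#' SNP), reads the scan output for significance flags, and runs the
#' SNP-count-matched resampling test of the target gene set. Writes
#' `enrichment.json` and a TSV of the per-bin composition.
#'
#' @param scan_file `scan.tsv` from [run_scan()].
#' @param genes_file BED6 gene models.
#' @param snp_file SNP loci.
#' @param geneset_file target gene set, one gene id per line.
#' @param out_dir output directory.
#' @param R resamples (default 10000).
#' @param n_bins SNP-count intervals (default 24).
#' @param seed resampling seed.
#' @param upstream_bp SNP-to-gene window (default 500 bp).
#' @return the `"enrichment_result"`, invisibly.
#' @export
run_enrich <- function(scan_file, genes_file, snp_file, geneset_file,
                       out_dir, R = 10000, n_bins = 24, seed = 1,
                       upstream_bp = 500) {
  .require_files(scan_file, genes_file, snp_file, geneset_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scan <- utils::read.delim(scan_file)
  genes <- read_genes_bed(genes_file)
  loci <- read_snp_loci(snp_file)
  target <- readLines(geneset_file)
  target <- trimws(target[nzchar(trimws(target))])
  asg <- assign_snps(loci, genes, upstream_bp)
  snp_counts <- table(asg$gene_id)
  snp_counts <- stats::setNames(as.integer(snp_counts), names(snp_counts))
  sig_snps <- as.character(scan$snp[as.logical(scan$significant)])
  sig_genes <- genes_with_significant(asg, sig_snps)
  target_in <- intersect(target, names(snp_counts))
  .log("universe: %d genes with >= 1 of %d assigned SNPs; target: %d/%d in universe",
       length(snp_counts), length(unique(asg$snp_id)), length(target_in),
       length(target))
  res <- resample_enrichment(target_in, snp_counts, sig_genes,
                             R = R, n_bins = n_bins, seed = seed)
  jsonlite::write_json(
    list(observed_gene_count = res$observed_gene_count,
         observed_snp_count = res$observed_snp_count,
         n_target = res$n_target, n_universe = length(snp_counts),
         n_sig_genes = length(sig_genes), R = res$R,
         p_gene = res$p_gene, p_snp = res$p_snp,
         null_gene_mean = mean(res$null_gene_counts),
         null_snp_mean = mean(res$null_snp_counts),
         n_bins = res$bins$n_bins, seed = seed,
         upstream_bp = upstream_bp),
    file.path(out_dir, "enrichment.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  bin_tab <- data.frame(bin = seq_len(res$bins$n_bins),
                        n_universe = as.integer(table(factor(res$bins$bin,
                          levels = seq_len(res$bins$n_bins)))),
                        n_target = as.integer(table(factor(
                          res$bins$bin[target_in],
                          levels = seq_len(res$bins$n_bins)))))
  utils::write.table(bin_tab, file.path(out_dir, "enrichment_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir,
                  list(scan = scan_file, genes = genes_file, snps = snp_file,
                       geneset = geneset_file),
                  list(R = R, n_bins = n_bins, upstream_bp = upstream_bp),
                  seed = seed)
  .log("enrichment: observed %d significant target genes, p_gene = %.4g",
       res$observed_gene_count, res$p_gene)
  invisible(res)
}

#' Run the full pipeline on a dataset directory
#'
#' Chains scan, gene annotation and enrichment on a directory laid out as
#' [write_dataset()] emits (frequencies.tsv, env.tsv, populations.tsv,
#' genes.bed, snp_loci.tsv, target_genes.txt, optionally truth.tsv). When
#' ground truth is present a truth-vs-called confusion matrix is written.
#'
#' @param dataset_dir input dataset directory.
#' @param out_dir output directory.
#' @param scan_cfg a [scan_config()].
#' @param R,n_bins,seed,upstream_bp enrichment parameters.
#' @return list with the scan, the enrichment result and (if truth was
#'   available) the confusion matrix, invisibly.
#' @export
run_all <- function(dataset_dir, out_dir, scan_cfg = scan_config(),
                    R = 10000, n_bins = 24, seed = 1, upstream_bp = 500) {
  fp <- function(f) file.path(dataset_dir, f)
  scan <- run_scan(fp("frequencies.tsv"), fp("env.tsv"),
                   fp("populations.tsv"), out_dir, config = scan_cfg,
                   genes_file = fp("genes.bed"),
                   snp_file = fp("snp_loci.tsv"))
  enr <- run_enrich(file.path(out_dir, "scan.tsv"), fp("genes.bed"),
                    fp("snp_loci.tsv"), fp("target_genes.txt"), out_dir,
                    R = R, n_bins = n_bins, seed = seed,
                    upstream_bp = upstream_bp)
  confusion <- NULL
  if (file.exists(fp("truth.tsv"))) {
    truth <- utils::read.delim(fp("truth.tsv"))
    called <- scan$records$significant[match(truth$snp_id,
                                             scan$records$snp)]
    confusion <- table(truth = as.logical(truth$selected),
                       called = called)
    utils::write.table(as.data.frame(confusion),
                       file.path(out_dir, "confusion.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .log("confusion vs truth: %d/%d planted recovered, %d false calls",
         sum(truth$selected & called), sum(truth$selected),
         sum(!truth$selected & called))
  }
  invisible(list(scan = scan, enrichment = enr, confusion = confusion))
}
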