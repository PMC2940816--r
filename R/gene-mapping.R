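#' Read gene models from BED6
#'
#' Columns `chrom start end gene_id score strand`; coordinates are 0-based
#' half-open (BED convention) and are kept that way internally. One
#' transcript per gene: overlapping transcripts must be pre-merged by the
#' data producer.
#'
#' @param path BED6 file (no header).
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_genes_bed <- function(path) {
  if (!file.exists(path)) stop("gene BED not found: ", path)
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = c("character", "integer", "integer",
                                        "character", "character", "character"))
  if (ncol(d) < 6)
    stop("malformed gene BED ", path, ": need 6 columns (BED6)")
  out <- data.frame(gene_id = d[[4]], chrom = d[[1]], start = d[[2]],
                    end = d[[3]], strand = d[[6]], stringsAsFactors = FALSE)
  if (!all(out$strand %in% c("+", "-")))
    stop("malformed gene BED ", path, ": strand must be + or -")
  if (any(out$start >= out$end))
    stop("malformed gene BED ", path, ": start must be < end")
  if (anyDuplicated(out$gene_id)) stop("duplicate gene ids in ", path)
  out
}

#' Read SNP loci
#'
#' Accepts either a headered TSV `snp chrom pos` (pos 0-based) or a
#' headerless BED (`chrom start end name`; pos taken as start).
#'
#' @param path file path.
#' @return data.frame with columns snp_id, chrom, pos.
#' @export
read_snp_loci <- function(path) {
  if (!file.exists(path)) stop("SNP loci file not found: ", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "snp")) {
    d <- utils::read.delim(path, check.names = FALSE)
    if (!all(c("snp", "chrom", "pos") %in% names(d)))
      stop("malformed SNP loci file ", path, ": need columns snp, chrom, pos")
    out <- data.frame(snp_id = as.character(d$snp),
                      chrom = as.character(d$chrom),
                      pos = as.integer(d$pos), stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE)
    if (ncol(d) < 4)
      stop("malformed SNP BED ", path, ": need chrom start end name")
    out <- data.frame(snp_id = as.character(d[[4]]),
                      chrom = as.character(d[[1]]),
                      pos = as.integer(d[[2]]), stringsAsFactors = FALSE)
  }
  if (any(out$pos < 0)) stop("negative SNP positions in ", path)
  if (anyDuplicated(out$snp_id)) stop("duplicate SNP ids in ", path)
  out
}

# window [ws, we) of a gene extended upstream_bp past its TSS, strand-aware
.gene_windows <- function(genes, upstream_bp) {
  ws <- ifelse(genes$strand == "+", pmax(genes$start - upstream_bp, 0),
               genes$start)
  we <- ifelse(genes$strand == "+", genes$end, genes$end + upstream_bp)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom, ws = ws, we = we,
             stringsAsFactors = FALSE)
}

#' Assign SNPs to genes
#'
#' A SNP belongs to a gene when it lies in the transcribed region or at most
#' `upstream_bp` upstream of the transcription start site. The upstream
#' window is strand-aware: TSS = tx_start on the + strand (window extends
#' left) and tx_end on the - strand (window extends right). The original
#' analyses used 500 bp for per-SNP gene assignment and 25 kb for pathway
#' analyses. A SNP may be assigned to several overlapping genes; SNPs on
#' chromosomes without genes are simply unassigned.
#'
#' @param snps data.frame with snp_id, chrom, pos (0-based).
#' @param genes data.frame with gene_id, chrom, start, end (0-based
#'   half-open), strand.
#' @param upstream_bp upstream window in bp (>= 0).
#' @return data.frame of assignment pairs, columns snp_id, gene_id.
#' @export
assign_snps <- function(snps, genes, upstream_bp = 500) {
  stopifnot(upstream_bp >= 0)
  win <- .gene_windows(genes, upstream_bp)
  out <- vector("list", 0L)
  for (chr in intersect(unique(snps$chrom), unique(win$chrom))) {
    s <- snps[snps$chrom == chr, , drop = FALSE]
    g <- win[win$chrom == chr, , drop = FALSE]
    ord <- order(s$pos)
    pos <- s$pos[ord]
    ids <- s$snp_id[ord]
    # per gene window, locate covered SNPs in the sorted position vector
    lo <- findInterval(g$ws - 1L, pos) + 1L       # first pos >= ws
    hi <- findInterval(g$we - 1L, pos)            # last pos  <= we - 1
    keep <- which(hi >= lo)
    if (length(keep) == 0) next
    idx <- sequence(hi[keep] - lo[keep] + 1L, from = lo[keep])
    out[[length(out) + 1L]] <- data.frame(
      snp_id = ids[idx],
      gene_id = rep(g$gene_id[keep], hi[keep] - lo[keep] + 1L),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(snp_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$snp_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Nearest gene and distance for each SNP
#'
#' Distance is 0 for SNPs inside a transcribed region; otherwise the number
#' of bases between the SNP and the nearer transcript boundary under the
#' half-open convention (tx_start - pos upstream, pos - tx_end downstream).
#' Ties are broken by the lexicographically smaller gene_id. SNPs on a
#' chromosome with no genes are flagged with `gene = NA`.
#'
#' @inheritParams assign_snps
#' @return data.frame with columns snp_id, gene (NA when no gene shares the
#'   chromosome), distance.
#' @export
nearest_gene <- function(snps, genes) {
  n <- nrow(snps)
  res_gene <- rep(NA_character_, n)
  res_dist <- rep(NA_real_, n)
  inside <- assign_snps(snps, genes, upstream_bp = 0)
  if (nrow(inside) > 0) {
    # lexicographic tie-break: first gene per snp after sorting
    first <- inside[!duplicated(inside$snp_id), , drop = FALSE]
    hit <- match(first$snp_id, snps$snp_id)
    res_gene[hit] <- first$gene_id
    res_dist[hit] <- 0
  }
  todo <- which(is.na(res_gene))
  for (chr in unique(snps$chrom[todo])) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    si <- todo[snps$chrom[todo] == chr]
    if (nrow(g) == 0) next
    pos <- snps$pos[si]
    # left side: largest tx_end <= pos (half-open: gene fully before pos)
    ends <- sort(unique(g$end))
    min_gene_by_end <- vapply(ends, function(e)
      min(g$gene_id[g$end == e]), character(1))
    ei <- findInterval(pos, ends)
    dl <- ifelse(ei >= 1, pos - ends[pmax(ei, 1)], Inf)
    gl <- ifelse(ei >= 1, min_gene_by_end[pmax(ei, 1)], NA_character_)
    # right side: smallest tx_start > pos
    starts <- sort(unique(g$start))
    min_gene_by_start <- vapply(starts, function(s)
      min(g$gene_id[g$start == s]), character(1))
    si2 <- findInterval(pos, starts) + 1L
    dr <- ifelse(si2 <= length(starts), starts[pmin(si2, length(starts))] - pos,
                 Inf)
    gr <- ifelse(si2 <= length(starts),
                 min_gene_by_start[pmin(si2, length(starts))], NA_character_)
    use_left <- dl < dr | (dl == dr & !is.na(gl) & !is.na(gr) & gl <= gr)
    res_dist[si] <- ifelse(use_left, dl, dr)
    res_gene[si] <- ifelse(use_left, gl, gr)
  }
  data.frame(snp_id = snps$snp_id, gene = res_gene, distance = res_dist,
             stringsAsFactors = FALSE)
}

#' Classify SNPs as genic or intergenic
#'
#' Genic means assigned to at least one gene under the transcribed-region
#' rule with an optional upstream window (`upstream_bp = 0` restricts to
#' the transcribed region itself).
#'
#' @inheritParams assign_snps
#' @return named logical vector, one entry per SNP.
#' @export
classify_genic <- function(snps, genes, upstream_bp = 0) {
  asg <- assign_snps(snps, genes, upstream_bp)
  stats::setNames(snps$snp_id %in% asg$snp_id, snps$snp_id)
}

#' Genes carrying at least one significant SNP
#'
#' @param assignments data.frame from [assign_snps()].
#' @param sig_snp_ids character vector of significant SNP ids.
#' @return sorted character vector of distinct gene ids.
#' @export
genes_with_significant <- function(assignments, sig_snp_ids) {
  sort(unique(assignments$gene_id[assignments$snp_id %in% sig_snp_ids]))
}
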