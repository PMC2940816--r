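# Independent oracles: brute-force pair enumeration for tau-b and full
# permutation enumeration for the exact p, plus small fixture builders.

oracle_tau <- function(x, y) {
  n <- length(x)
  C <- D <- tx <- ty <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0) tx <- tx + 1L
      if (dy == 0) ty <- ty + 1L
      if (dx != 0 && dy != 0) {
        if (dx == dy) C <- C + 1L else D <- D + 1L
      }
    }
  }
  n0 <- n * (n - 1) / 2
  denom <- (n0 - tx) * (n0 - ty)
  list(C = C, D = D, S = C - D, n1 = tx, n2 = ty,
       tau = if (denom > 0) (C - D) / sqrt(denom) else NA_real_)
}

all_perms <- function(v) {
  if (length(v) == 1) return(matrix(v, 1, 1))
  do.call(rbind, lapply(seq_along(v), function(i)
    cbind(v[i], all_perms(v[-i]))))
}

oracle_exact_p <- function(x, y) {
  s_obs <- abs(oracle_tau(x, y)$S)
  pm <- all_perms(y)
  mean(apply(pm, 1, function(py) abs(oracle_tau(x, py)$S) >= s_obs))
}

# random instance with ties and non-constant margins
rand_tied_instance <- function(n, kmax = max(2L, n - 1L)) {
  repeat {
    k <- sample(2:max(2, kmax), 1)
    x <- sample(seq_len(k), n, replace = TRUE)
    y <- sample(seq_len(k), n, replace = TRUE)
    if (length(unique(x)) > 1 && length(unique(y)) > 1)
      return(list(x = as.numeric(x), y = as.numeric(y)))
  }
}

toy_presence <- function() {
  m <- matrix(c(TRUE, TRUE, FALSE,   # c1: sp1, sp2
                TRUE, FALSE, FALSE), # c2: sp1
              nrow = 3, ncol = 2,
              dimnames = list(c("sp1", "sp2", "sp3"), c("c1", "c2")))
  m
}

toy_genes <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
             start = c(1000L, 5000L), end = c(2000L, 6000L),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

toy_snps <- function(pos, chrom = "chr1") {
  data.frame(snp_id = sprintf("s%02d", seq_along(pos)), chrom = chrom,
             pos = as.integer(pos), stringsAsFactors = FALSE)
}
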