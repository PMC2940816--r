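#' Tie-corrected Kendall rank correlation
#'
#' Computes Kendall's tau-b between two numeric vectors with full tie
#' bookkeeping, and a p-value either from the tie-corrected normal
#' approximation of the S statistic or from exact enumeration of all
#' permutations of `y` (small n only).
#'
#' tau-b = S / sqrt((n0 - n1)(n0 - n2)) where S = C - D (concordant minus
#' discordant pairs), n0 = n(n-1)/2 and n1, n2 are the tied-pair counts of
#' `x` and `y`. The variance of S under the null uses the standard
#' tie-adjusted formula, so the normal deviate z = S / sqrt(var_S) is valid
#' in the presence of ties for n larger than about 10.
#'
#' Constant input (all values tied in either vector) yields a *degenerate*
#' result: `tau = NA`, `p = 1`, `degenerate = TRUE`. No error is thrown, so
#' genome scans over many SNPs proceed past uninformative rows.
#'
#' @param x,y numeric vectors of equal length (n >= 3), no missing values;
#'   callers are expected to filter to pairwise-complete observations first.
#' @param p_method `"normal"` for the tie-corrected normal approximation,
#'   `"exact"` for full permutation enumeration (n <= 10), `"none"` to skip
#'   inference.
#' @param continuity apply a continuity correction (|S| - 1) to the normal
#'   deviate. Off by default.
#' @return An object of class `"kendall_cor"`: a list with elements `n`,
#'   `C`, `D`, `S`, `tau`, `n1`, `n2` (tied-pair counts), `var_S`, `z`,
#'   `p.value`, `degenerate`, `method`.
#' @examples
#' kendall_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))           # tau = 1/3
#' kendall_cor(c(1, 1, 2, 3), c(1, 2, 3, 4))$tau       # 5 / sqrt(30)
#' @export
kendall_cor <- function(x, y, p_method = c("normal", "exact", "none"),
                        continuity = FALSE) {
  p_method <- match.arg(p_method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (anyNA(x) || anyNA(y))
    stop("missing values not allowed; filter to pairwise-complete pairs first")
  if (length(x) < 3)
    stop("need at least 3 observations")
  st <- cpp_kendall_pair(x, y)
  res <- list(
    n = as.integer(st[["n"]]), C = st[["C"]], D = st[["D"]], S = st[["S"]],
    tau = st[["tau"]], n1 = st[["tie_pairs_x"]],
    n2 = st[["tie_pairs_y"]], var_S = st[["var_S"]],
    z = NA_real_, p.value = NA_real_,
    degenerate = st[["degenerate"]] == 1, method = p_method
  )
  if (res$degenerate) {
    res$p.value <- 1
    class(res) <- "kendall_cor"
    return(res)
  }
  if (p_method == "normal") {
    res <- tau_pvalue_normal(res, continuity = continuity)
  } else if (p_method == "exact") {
    res$p.value <- tau_pvalue_exact(x, y)
  }
  class(res) <- "kendall_cor"
  res
}

#' Normal-approximation p-value for a Kendall correlation
#'
#' Fills `z` and `p.value` of a [kendall_cor()] result using the
#' tie-corrected variance of S already stored in the object. Exposed so scan
#' code can batch the pair counting and vectorise the tail probability.
#'
#' @param r a `"kendall_cor"` object (or compatible list with `S`, `var_S`,
#'   `degenerate`).
#' @param continuity apply the continuity correction (|S| - 1).
#' @return the object with `z` and two-sided `p.value` filled; if
#'   `var_S <= 0` (everything tied) the result is flagged degenerate with
#'   `p = 1`.
#' @export
tau_pvalue_normal <- function(r, continuity = FALSE) {
  if (isTRUE(r$degenerate) || !is.finite(r$var_S) || r$var_S <= 0) {
    r$degenerate <- TRUE
    r$p.value <- 1
    r$z <- NA_real_
    return(r)
  }
  s <- r$S
  if (continuity && s != 0) s <- s - sign(s)
  r$z <- s / sqrt(r$var_S)
  r$p.value <- 2 * stats::pnorm(-abs(r$z))
  if (r$p.value > 1) r$p.value <- 1
  r
}

#' Exact permutation p-value for Kendall's tau
#'
#' Enumerates all n! permutations of `y` and returns the fraction whose
#' |tau-b| is at least the observed |tau-b|. Because the tie structure of
#' `y` is invariant under permutation, the comparison is carried out on the
#' integer S statistic and is exact. Only enumerable for n <= 10; larger n
#' errors, directing callers to the normal approximation.
#'
#' @inheritParams kendall_cor
#' @return the two-sided exact p-value in (0, 1].
#' @export
tau_pvalue_exact <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n > 10)
    stop("n = ", n, " too large for exact enumeration; ",
         "use the normal approximation (tau_pvalue_normal)")
  if (n < 2) stop("need at least 2 observations")
  cpp_kendall_exact_p(x, y)
}

#' @export
print.kendall_cor <- function(x, ...) {
  cat("Kendall rank correlation (tau-b)\n")
  cat(sprintf("  n = %d, C = %d, D = %d, S = %d (tied pairs: x %d, y %d)\n",
              x$n, as.integer(x$C), as.integer(x$D), as.integer(x$S),
              as.integer(x$n1), as.integer(x$n2)))
  if (x$degenerate) {
    cat("  degenerate: constant input, tau undefined, p = 1\n")
  } else {
    cat(sprintf("  tau = %.4f", x$tau))
    if (x$method == "normal" && is.finite(x$z))
      cat(sprintf(", z = %.3f, p = %.3g (normal approximation)", x$z, x$p.value))
    else if (x$method == "exact")
      cat(sprintf(", p = %.3g (exact permutation)", x$p.value))
    cat("\n")
  }
  invisible(x)
}
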