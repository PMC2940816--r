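#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

namespace {

struct TieStats {
  double pairs;   // sum t(t-1)/2
  double v;       // sum t(t-1)(2t+5)
  double p2;      // sum t(t-1)
  double p3;      // sum t(t-1)(t-2)
};

TieStats tie_stats(std::vector<double> v) {
  std::sort(v.begin(), v.end());
  TieStats s = {0.0, 0.0, 0.0, 0.0};
  size_t i = 0, n = v.size();
  while (i < n) {
    size_t j = i;
    while (j + 1 < n && v[j + 1] == v[i]) ++j;
    double t = (double)(j - i + 1);
    s.pairs += t * (t - 1.0) / 2.0;
    s.v += t * (t - 1.0) * (2.0 * t + 5.0);
    s.p2 += t * (t - 1.0);
    s.p3 += t * (t - 1.0) * (t - 2.0);
    i = j + 1;
  }
  return s;
}

// Kendall S = sum over pairs of sign(dx)*sign(dy); C/D concordant/discordant.
void count_pairs(const std::vector<double>& x, const std::vector<double>& y,
                 double& C, double& D) {
  C = 0.0; D = 0.0;
  size_t n = x.size();
  for (size_t i = 0; i + 1 < n; ++i)
    for (size_t j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx == 0.0 || dy == 0.0) continue;
      if ((dx > 0.0) == (dy > 0.0)) C += 1.0; else D += 1.0;
    }
}

// tau-b with tie-corrected variance of S; fills a 9-slot row:
// n, C, D, S, tau, var_S, n1(tie pairs x), n2(tie pairs y), degenerate
void kendall_core(const std::vector<double>& x, const std::vector<double>& y,
                  double* out) {
  double n = (double)x.size();
  double C, D;
  count_pairs(x, y, C, D);
  TieStats tx = tie_stats(x), ty = tie_stats(y);
  double n0 = n * (n - 1.0) / 2.0;
  double S = C - D;
  double denom = (n0 - tx.pairs) * (n0 - ty.pairs);
  bool degen = denom <= 0.0;
  double tau = degen ? NA_REAL : S / std::sqrt(denom);
  double v0 = n * (n - 1.0) * (2.0 * n + 5.0);
  double v1 = tx.p2 * ty.p2 / (2.0 * n * (n - 1.0));
  double v2 = (n > 2.0) ? tx.p3 * ty.p3 / (9.0 * n * (n - 1.0) * (n - 2.0)) : 0.0;
  double var_S = (v0 - tx.v - ty.v) / 18.0 + v1 + v2;
  out[0] = n; out[1] = C; out[2] = D; out[3] = S; out[4] = tau;
  out[5] = var_S; out[6] = tx.pairs; out[7] = ty.pairs;
  out[8] = degen ? 1.0 : 0.0;
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_kendall_pair(NumericVector x, NumericVector y) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  NumericVector out(9);
  kendall_core(xv, yv, REAL(out));
  out.names() = CharacterVector::create("n", "C", "D", "S", "tau", "var_S",
                                        "tie_pairs_x", "tie_pairs_y",
                                        "degenerate");
  return out;
}

// Per-SNP scan: rows of `freq` against the shared `env`; NA frequencies are
// dropped pairwise per row. Rows with fewer than 3 complete pairs come back
// all-NA with degenerate = 1.
// [[Rcpp::export]]
NumericMatrix cpp_kendall_scan(NumericMatrix freq, NumericVector env) {
  int nsnp = freq.nrow(), npop = freq.ncol();
  NumericMatrix out(nsnp, 9);
  colnames(out) = CharacterVector::create("n", "C", "D", "S", "tau", "var_S",
                                          "tie_pairs_x", "tie_pairs_y",
                                          "degenerate");
  std::vector<double> xv, yv;
  for (int i = 0; i < nsnp; ++i) {
    xv.clear(); yv.clear();
    for (int j = 0; j < npop; ++j) {
      double f = freq(i, j);
      if (!NumericVector::is_na(f)) { xv.push_back(f); yv.push_back(env[j]); }
    }
    double row[9];
    if ((int)xv.size() < 3) {
      for (int k = 0; k < 9; ++k) row[k] = NA_REAL;
      row[0] = (double)xv.size(); row[8] = 1.0;
    } else {
      kendall_core(xv, yv, row);
    }
    for (int k = 0; k < 9; ++k) out(i, k) = row[k];
  }
  return out;
}

// Exact permutation p for |tau|: fraction of the n! permutations of y whose
// |S| >= |S_observed|. The tie structure of y (hence the tau-b denominator)
// is permutation-invariant, so S comparisons are exact.
// [[Rcpp::export]]
double cpp_kendall_exact_p(NumericVector x, NumericVector y) {
  int n = x.size();
  if (n > 10) stop("exact permutation p only enumerable for n <= 10");
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  double C, D;
  count_pairs(xv, yv, C, D);
  double s_obs = std::fabs(C - D);
  std::vector<double> p(yv);
  std::vector<int> c(n, 0);
  double total = 0.0, hits = 0.0;
  count_pairs(xv, p, C, D);
  total += 1.0; if (std::fabs(C - D) >= s_obs) hits += 1.0;
  int i = 0;  // Heap's algorithm, iterative
  while (i < n) {
    if (c[i] < i) {
      if (i % 2 == 0) std::swap(p[0], p[i]); else std::swap(p[c[i]], p[i]);
      count_pairs(xv, p, C, D);
      total += 1.0; if (std::fabs(C - D) >= s_obs) hits += 1.0;
      ++c[i]; i = 0;
    } else {
      c[i] = 0; ++i;
    }
  }
  return hits / total;
}

// MAF-window empirical gate. Inputs are sorted by `maf` (caller's job).
// For record i the window is all j with |maf_j - maf_i| <= window (i
// included). q = nearest-rank `pct` percentile of |tau| in the window
// (k = ceil(pct * w) th smallest); rank = fraction of window |tau| <= own.
// [[Rcpp::export]]
List cpp_window_percentile(NumericVector maf, NumericVector abstau,
                           double window, double pct) {
  int n = maf.size();
  NumericVector q(n), rank(n);
  IntegerVector wsize(n);
  int lo = 0, hi = 0;
  std::vector<double> buf;
  for (int i = 0; i < n; ++i) {
    while (lo < n && maf[lo] < maf[i] - window) ++lo;
    if (hi < i + 1) hi = i + 1;
    while (hi < n && maf[hi] <= maf[i] + window) ++hi;
    int w = hi - lo;
    wsize[i] = w;
    buf.assign(abstau.begin() + lo, abstau.begin() + hi);
    int k = (int)std::ceil(pct * (double)w);
    if (k < 1) k = 1;
    std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end());
    q[i] = buf[k - 1];
    int le = 0;
    for (int j = lo; j < hi; ++j) if (abstau[j] <= abstau[i]) ++le;
    rank[i] = (double)le / (double)w;
  }
  return List::create(_["q"] = q, _["rank"] = rank, _["window_size"] = wsize);
}
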