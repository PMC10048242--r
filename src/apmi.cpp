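#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Adaptive-partitioning mutual information on copula-transformed data.
//
// The unit square is split recursively at cell midpoints into four
// quadrants while a chi-squared uniformity statistic over the quadrant
// counts exceeds `chi_crit` and the cell holds at least `min_pts` points.
// Each leaf contributes (n_c/n) * log(n_c * n / (n_x * n_y)) where n_x and
// n_y are the marginal counts of points falling in the leaf's x- and
// y-range; with uniform (copula) marginals this is the standard
// marginal-count-corrected plug-in estimate. MI is clamped at zero.

namespace {

struct ApmiCtx {
  const std::vector<double>* x;
  const std::vector<double>* y;
  int n;
  double chi_crit;
  int min_pts;
  double mi;
};

inline int count_range(const std::vector<double>& sorted, double lo, double hi) {
  // points v with lo < v <= hi
  return static_cast<int>(std::upper_bound(sorted.begin(), sorted.end(), hi) -
                          std::upper_bound(sorted.begin(), sorted.end(), lo));
}

void apmi_rec(ApmiCtx& ctx, std::vector<int>& idx,
              double xlo, double xhi, double ylo, double yhi,
              const std::vector<double>& xs, const std::vector<double>& ys,
              int depth) {
  const int nc = static_cast<int>(idx.size());
  if (nc == 0) return;
  const std::vector<double>& x = *ctx.x;
  const std::vector<double>& y = *ctx.y;

  if (nc >= ctx.min_pts) {
    const double mx = 0.5 * (xlo + xhi), my = 0.5 * (ylo + yhi);
    std::vector<int> q1, q2, q3, q4;
    for (int i : idx) {
      const bool right = x[i] > mx, top = y[i] > my;
      if (right && top) q1.push_back(i);
      else if (!right && top) q2.push_back(i);
      else if (!right && !top) q3.push_back(i);
      else q4.push_back(i);
    }
    const double e = nc / 4.0;
    const double chi2 =
        ((q1.size() - e) * (q1.size() - e) + (q2.size() - e) * (q2.size() - e) +
         (q3.size() - e) * (q3.size() - e) + (q4.size() - e) * (q4.size() - e)) / e;
    // the root cell is always split (standard adaptive-partitioning
    // convention; keeps the null MI distribution continuous), deeper
    // cells only while uniformity is rejected
    if (depth == 0 || chi2 > ctx.chi_crit) {
      apmi_rec(ctx, q1, mx, xhi, my, yhi, xs, ys, depth + 1);
      apmi_rec(ctx, q2, xlo, mx, my, yhi, xs, ys, depth + 1);
      apmi_rec(ctx, q3, xlo, mx, ylo, my, xs, ys, depth + 1);
      apmi_rec(ctx, q4, mx, xhi, ylo, my, xs, ys, depth + 1);
      return;
    }
  }
  // leaf
  const int nx = count_range(xs, xlo, xhi);
  const int ny = count_range(ys, ylo, yhi);
  ctx.mi += (static_cast<double>(nc) / ctx.n) *
            std::log(static_cast<double>(nc) * ctx.n /
                     (static_cast<double>(nx) * static_cast<double>(ny)));
}

double apmi_one(const std::vector<double>& x, const std::vector<double>& y,
                double chi_crit, int min_pts) {
  ApmiCtx ctx;
  ctx.x = &x; ctx.y = &y; ctx.n = static_cast<int>(x.size());
  ctx.chi_crit = chi_crit; ctx.min_pts = min_pts; ctx.mi = 0.0;
  std::vector<double> xs(x), ys(y);
  std::sort(xs.begin(), xs.end());
  std::sort(ys.begin(), ys.end());
  std::vector<int> idx(ctx.n);
  for (int i = 0; i < ctx.n; ++i) idx[i] = i;
  // cells are (lo, hi]; copula values lie strictly inside (0, 1)
  apmi_rec(ctx, idx, 0.0, 1.0, 0.0, 1.0, xs, ys, 0);
  return ctx.mi > 0.0 ? ctx.mi : 0.0;
}

} // namespace

// [[Rcpp::export]]
double apmi_cpp(NumericVector x, NumericVector y, double chi_crit, int min_pts) {
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  return apmi_one(xv, yv, chi_crit, min_pts);
}

// Cross MI between every row of `reg` and every row of `tgt`
// (rows already copula-transformed). Returns a n_reg x n_tgt matrix.
// [[Rcpp::export]]
NumericMatrix apmi_cross_cpp(NumericMatrix reg, NumericMatrix tgt,
                             double chi_crit, int min_pts) {
  const int nr = reg.nrow(), nt = tgt.nrow(), n = reg.ncol();
  NumericMatrix out(nr, nt);
  std::vector<double> xv(n), yv(n);
  for (int i = 0; i < nr; ++i) {
    for (int k = 0; k < n; ++k) xv[k] = reg(i, k);
    for (int j = 0; j < nt; ++j) {
      for (int k = 0; k < n; ++k) yv[k] = tgt(j, k);
      out(i, j) = apmi_one(xv, yv, chi_crit, min_pts);
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Null MI draws: APMI between the fixed copula grid and an independently
// shuffled copy, one estimate per pair. Uses R's RNG for reproducibility.
// [[Rcpp::export]]
NumericVector apmi_null_cpp(int n, int n_pairs, double chi_crit, int min_pts) {
  NumericVector out(n_pairs);
  std::vector<double> x(n), y(n);
  for (int k = 0; k < n; ++k) x[k] = (k + 1.0) / (n + 1.0);
  for (int p = 0; p < n_pairs; ++p) {
    IntegerVector perm = Rcpp::sample(n, n, false);
    for (int k = 0; k < n; ++k) y[k] = perm[k] / (n + 1.0);
    out[p] = apmi_one(x, y, chi_crit, min_pts);
    if (p % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
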