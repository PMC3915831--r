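#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Adaptive-partitioning mutual information on rank-transformed data.
//
// The unit square of (x, y) ranks is subdivided recursively into quadrants
// at the cell midpoint; a cell is split while its four quadrant counts
// deviate from uniformity by a chi-square test (df = 3), otherwise it
// contributes its plug-in term to the MI sum.  Because both marginals are
// uniform on (0, 1) after rank transformation, the marginal mass of a cell
// equals its side length, so MI = sum n_c/N * log(n_c/N / (w_x * w_y)).

static const double CHI2_CRIT = 7.814728;  // qchisq(0.95, df = 3)
static const int    MIN_SPLIT = 8;         // do not split sparser cells

namespace {

struct APWorker {
  const double* x;
  const double* y;
  int n;
  int max_depth;
  std::vector<int> idx;

  double run() {
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    return recurse(0, n, 0.0, 1.0, 0.0, 1.0, 0);
  }

  double term(int count, double w) const {
    if (count == 0) return 0.0;
    double p = static_cast<double>(count) / n;
    return p * std::log(p / w);
  }

  double recurse(int lo, int hi, double x0, double x1, double y0, double y1,
                 int depth) {
    int nc = hi - lo;
    double wx = x1 - x0, wy = y1 - y0;
    if (nc < MIN_SPLIT || depth >= max_depth) return term(nc, wx * wy);

    double xm = 0.5 * (x0 + x1), ym = 0.5 * (y0 + y1);

    // in-place partition: x < xm first, then y < ym within each half
    int mid = lo;
    for (int i = lo; i < hi; ++i)
      if (x[idx[i]] < xm) std::swap(idx[i], idx[mid++]);
    int q1 = lo;
    for (int i = lo; i < mid; ++i)
      if (y[idx[i]] < ym) std::swap(idx[i], idx[q1++]);
    int q3 = mid;
    for (int i = mid; i < hi; ++i)
      if (y[idx[i]] < ym) std::swap(idx[i], idx[q3++]);

    // quadrant counts (ll, ul, lr, ur)
    double e = nc / 4.0;
    int cnt[4] = {q1 - lo, mid - q1, q3 - mid, hi - q3};
    double chi2 = 0.0;
    for (int q = 0; q < 4; ++q) {
      double d = cnt[q] - e;
      chi2 += d * d / e;
    }
    if (chi2 <= CHI2_CRIT) return term(nc, wx * wy);

    return recurse(lo, q1, x0, xm, y0, ym, depth + 1) +
           recurse(q1, mid, x0, xm, ym, y1, depth + 1) +
           recurse(mid, q3, xm, x1, y0, ym, depth + 1) +
           recurse(q3, hi, xm, x1, ym, y1, depth + 1);
  }
};

inline int depth_for(int n) {
  return static_cast<int>(std::ceil(std::log2(static_cast<double>(n)))) + 4;
}

}  // namespace

// [[Rcpp::export(name = ".ap_mi_cpp")]]
double ap_mi_cpp(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  if (ry.size() != n) stop("rank vectors must have equal length");
  APWorker w;
  w.x = REAL(rx);
  w.y = REAL(ry);
  w.n = n;
  w.max_depth = depth_for(n);
  double mi = w.run();
  return mi > 0.0 ? mi : 0.0;
}

// Batch MI over column pairs of a rank matrix (n x g); pairs is 2 x P,
// 1-based column indices.
// [[Rcpp::export(name = ".ap_mi_pairs_cpp")]]
NumericVector ap_mi_pairs_cpp(NumericMatrix ranks, IntegerMatrix pairs) {
  int n = ranks.nrow();
  int P = pairs.ncol();
  NumericVector out(P);
  APWorker w;
  w.n = n;
  w.max_depth = depth_for(n);
  for (int p = 0; p < P; ++p) {
    int i = pairs(0, p) - 1, j = pairs(1, p) - 1;
    w.x = &ranks(0, i);
    w.y = &ranks(0, j);
    double mi = w.run();
    out[p] = mi > 0.0 ? mi : 0.0;
  }
  return out;
}
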