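// Two-sample two-dimensional Kolmogorov-Smirnov statistic in the
// Fasano-Franceschini sense: at every data point of a conditioning sample,
// the four axis-aligned quadrant probabilities of the two samples are
// compared; the statistic conditions on each sample in turn and averages the
// two maxima. The permutation loop lives here because the statistic is
// O(n^2) and is re-evaluated hundreds of times per test.

#include <Rcpp.h>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

// max over points of `cx,cy` (conditioning sample) of the max quadrant
// difference between samples A and B given pooled coords and labels
double max_quadrant_diff(const std::vector<double>& x,
                         const std::vector<double>& y,
                         const std::vector<int>& lab,
                         int na, int nb, int cond_lab) {
  const int n = (int)x.size();
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != cond_lab) continue;
    int a11 = 0, a12 = 0, a21 = 0, a22 = 0;
    int b11 = 0, b12 = 0, b21 = 0, b22 = 0;
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      // strict quadrants: points on either anchor line (including the
      // anchor itself) lie on a quadrant boundary and count for neither
      if (x[j] == xi || y[j] == yi) continue;
      const bool lx = x[j] < xi, ly = y[j] < yi;
      if (lab[j] == 0) {
        if (lx) { if (ly) ++a11; else ++a12; }
        else    { if (ly) ++a21; else ++a22; }
      } else {
        if (lx) { if (ly) ++b11; else ++b12; }
        else    { if (ly) ++b21; else ++b22; }
      }
    }
    const double ia = 1.0 / na, ib = 1.0 / nb;
    double d;
    d = std::fabs(a11 * ia - b11 * ib); if (d > best) best = d;
    d = std::fabs(a12 * ia - b12 * ib); if (d > best) best = d;
    d = std::fabs(a21 * ia - b21 * ib); if (d > best) best = d;
    d = std::fabs(a22 * ia - b22 * ib); if (d > best) best = d;
  }
  return best;
}

double mks_stat(const std::vector<double>& x, const std::vector<double>& y,
                const std::vector<int>& lab, int na, int nb) {
  double da = max_quadrant_diff(x, y, lab, na, nb, 0);
  double db = max_quadrant_diff(x, y, lab, na, nb, 1);
  return 0.5 * (da + db);
}

} // namespace

// [[Rcpp::export(name = ".mks_cpp")]]
List mks_cpp(NumericVector xa, NumericVector ya,
             NumericVector xb, NumericVector yb,
             int n_perm, int seed) {
  const int na = xa.size(), nb = xb.size(), n = na + nb;
  std::vector<double> x(n), y(n);
  std::vector<int> lab(n);
  for (int i = 0; i < na; ++i) { x[i] = xa[i]; y[i] = ya[i]; lab[i] = 0; }
  for (int i = 0; i < nb; ++i) { x[na + i] = xb[i]; y[na + i] = yb[i]; lab[na + i] = 1; }

  const double obs = mks_stat(x, y, lab, na, nb);

  NumericVector perm(n_perm);
  std::mt19937 rng((unsigned int)seed);
  std::vector<int> plab = lab;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle of the labels
    for (int i = n - 1; i > 0; --i) {
      std::uniform_int_distribution<int> u(0, i);
      int j = u(rng);
      std::swap(plab[i], plab[j]);
    }
    perm[p] = mks_stat(x, y, plab, na, nb);
  }
  return List::create(_["k"] = obs, _["perm"] = perm);
}
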