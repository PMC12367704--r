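#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Fuzzy entropy of a single window.
//
// Subsequences of length m (and m+1) are baseline-corrected by their own
// mean before the Chebyshev distance is taken; membership of a pair is
// exp(-ln2 * (d/r)^2); the similarity degree at each dimension averages
// memberships over all ordered pairs i != j, with i running over the
// N - m subsequences at BOTH dimensions so the pair counts match.
// FuzEn = ln O_m - ln O_{m+1}.
//
// Memberships below ~3e-20 (c*d*d > 45) are skipped: their total over a
// window is < N * 3e-20, far beneath the 1e-10 agreement the brute-force
// oracle is held to.
// [[Rcpp::export]]
double fuzen_cpp(NumericVector x, int m, double r) {
  const int N = x.size();
  const int n = N - m;
  if (n < 2) stop("signal too short for embedding dimension m");
  if (!(r > 0)) stop("tolerance r must be positive");

  std::vector<double> vm(static_cast<size_t>(n) * m);
  std::vector<double> vm1(static_cast<size_t>(n) * (m + 1));
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < m; ++k) s += x[i + k];
    const double mu = s / m;
    for (int k = 0; k < m; ++k) vm[static_cast<size_t>(i) * m + k] = x[i + k] - mu;
    s = 0.0;
    for (int k = 0; k <= m; ++k) s += x[i + k];
    const double mu1 = s / (m + 1);
    for (int k = 0; k <= m; ++k)
      vm1[static_cast<size_t>(i) * (m + 1) + k] = x[i + k] - mu1;
  }

  const double c = std::log(2.0) / (r * r);
  double om = 0.0, om1 = 0.0;
  std::vector<double> rowm(n, 0.0), rowm1(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const double *vi = &vm[static_cast<size_t>(i) * m];
    const double *vi1 = &vm1[static_cast<size_t>(i) * (m + 1)];
    for (int j = i + 1; j < n; ++j) {
      const double *vj = &vm[static_cast<size_t>(j) * m];
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double t = std::fabs(vi[k] - vj[k]);
        if (t > d) d = t;
      }
      double e = c * d * d;
      if (e <= 45.0) {
        const double w = std::exp(-e);
        rowm[i] += w;
        rowm[j] += w;
      }
      const double *vj1 = &vm1[static_cast<size_t>(j) * (m + 1)];
      d = 0.0;
      for (int k = 0; k <= m; ++k) {
        const double t = std::fabs(vi1[k] - vj1[k]);
        if (t > d) d = t;
      }
      e = c * d * d;
      if (e <= 45.0) {
        const double w = std::exp(-e);
        rowm1[i] += w;
        rowm1[j] += w;
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    om += rowm[i] / (n - 1);
    om1 += rowm1[i] / (n - 1);
  }
  om /= n;
  om1 /= n;
  if (om <= 0.0 || om1 <= 0.0)
    return R_PosInf;
  return std::log(om) - std::log(om1);
}
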