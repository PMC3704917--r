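#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Hit-and-run chain over {x >= 0} intersected with an affine subspace
// x0 + span(N), where N has orthonormal columns (a null-space basis of the
// sort matrix restricted to sampled cells). Each step draws a uniformly
// random direction d = N g / ||N g||, computes the feasible segment
// [tlo, thi] from x + t d >= 0 and samples t ~ Uniform(tlo, thi). Uses R's
// RNG so set.seed() controls reproducibility. Returns the thinned
// post-burn-in draws, one row per kept sample.
// [[Rcpp::export(name = ".hitAndRunChain")]]
NumericMatrix hitAndRunChain(NumericVector x0, NumericMatrix N,
                             int nBurn, int nIter, int thin) {
  const int n = x0.size();
  const int k = N.ncol();
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> d(n);
  const int nKeep = nIter / thin;
  NumericMatrix out(nKeep > 0 ? nKeep : 0, n);
  int kept = 0;
  RNGScope scope;
  for (int it = 0; it < nBurn + nIter; ++it) {
    double nrm = 0.0;
    {
      NumericVector g = rnorm(k);
      for (int j = 0; j < n; ++j) {
        double s = 0.0;
        for (int c = 0; c < k; ++c) s += N(j, c) * g[c];
        d[j] = s;
        nrm += s * s;
      }
    }
    nrm = std::sqrt(nrm);
    if (nrm > 1e-300) {
      double tlo = -std::numeric_limits<double>::infinity();
      double thi = std::numeric_limits<double>::infinity();
      for (int j = 0; j < n; ++j) {
        const double dj = d[j] / nrm;
        d[j] = dj;
        if (dj > 1e-13) {
          const double t = -x[j] / dj;
          if (t > tlo) tlo = t;
        } else if (dj < -1e-13) {
          const double t = -x[j] / dj;
          if (t < thi) thi = t;
        }
      }
      if (std::isfinite(tlo) && std::isfinite(thi) && thi > tlo) {
        const double t = R::runif(tlo, thi);
        for (int j = 0; j < n; ++j) x[j] += t * d[j];
      }
    }
    if (it >= nBurn && ((it - nBurn + 1) % thin == 0) && kept < nKeep) {
      for (int j = 0; j < n; ++j) out(kept, j) = x[j];
      ++kept;
    }
  }
  return out;
}
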