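#include <Rcpp.h>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

// Approximate entropy (Pincus), Chebyshev distance, self-matches included.
// A single pass counts template matches for m and m+1 simultaneously.
// Pairs are enumerated in order of the templates' first coordinate, so the
// inner Chebyshev check runs only for pairs already within r on that
// coordinate; this prunes most pairs without changing the result.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) return 0.0;
  int nm = n - m + 1;   // number of length-m templates
  int nm1 = n - m;      // number of length-(m+1) templates
  std::vector<double> cm(nm, 1.0), cm1(nm1, 1.0);  // self-matches included
  std::vector<int> ord(nm);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return x[a] < x[b]; });
  for (int a = 0; a < nm; ++a) {
    int i = ord[a];
    double xi = x[i];
    for (int b = a + 1; b < nm; ++b) {
      int j = ord[b];
      if (x[j] - xi > r) break;  // sorted: no further first-coord match
      double d = x[j] - xi;
      if (d < 0) d = -d;
      for (int k = 1; k < m; ++k) {
        double t = std::fabs(x[i + k] - x[j + k]);
        if (t > d) d = t;
      }
      if (d <= r) {
        cm[i] += 1.0; cm[j] += 1.0;
        if (i < nm1 && j < nm1) {
          double t = std::fabs(x[i + m] - x[j + m]);
          if (t > d) d = t;
          if (d <= r) { cm1[i] += 1.0; cm1[j] += 1.0; }
        }
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int i = 0; i < nm; ++i) phim += std::log(cm[i] / nm);
  phim /= nm;
  for (int i = 0; i < nm1; ++i) phim1 += std::log(cm1[i] / nm1);
  phim1 /= nm1;
  return phim - phim1;
}
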