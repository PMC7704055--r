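#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation of two
// rank vectors (average ranks for ties), by full enumeration of the
// distinct permutations of ry. Intended for n <= 10.
// [[Rcpp::export]]
double spearman_perm_pvalue(NumericVector rx, NumericVector ry) {
  int n = rx.size();
  std::vector<double> a(rx.begin(), rx.end());
  std::vector<double> b(ry.begin(), ry.end());

  double sab = 0.0;
  for (int i = 0; i < n; ++i) sab += a[i] * b[i];
  const double obs = sab;                 // rho is monotone in sum(a*b)
  double sa = 0.0, sb = 0.0, saa = 0.0, sbb = 0.0;
  for (int i = 0; i < n; ++i) { sa += a[i]; sb += b[i]; saa += a[i]*a[i]; sbb += b[i]*b[i]; }
  const double mean_s = sa * sb / n;      // E-style centring term
  const double obs_dev = std::fabs(obs - mean_s);

  std::sort(b.begin(), b.end());
  long long total = 0, extreme = 0;
  const double eps = 1e-9;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += a[i] * b[i];
    if (std::fabs(s - mean_s) >= obs_dev - eps) ++extreme;
    ++total;
  } while (std::next_permutation(b.begin(), b.end()));

  return (double) extreme / (double) total;
}
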