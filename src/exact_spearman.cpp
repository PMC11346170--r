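#include <Rcpp.h>
#include <cmath>
#include <vector>

// Exact two-sided permutation p-value for the Spearman correlation of two
// (possibly tied, average-rank) rank vectors. With the rank marginals
// fixed, rho is an increasing affine function of S = sum(a_i * b_perm(i)),
// so |rho_perm| >= |rho_obs| iff |S - c0| >= |S_obs - c0| where
// c0 = n * mean(a) * mean(b). Full enumeration of all n! assignments;
// intended for n <= 10 (10! = 3,628,800).

static void permRec(std::vector<double> &b, int k,
                    const std::vector<double> &a, double c0, double dev,
                    long long &cnt) {
  const int n = (int)b.size();
  if (k == n) {
    double S = 0.0;
    for (int i = 0; i < n; ++i) S += a[i] * b[i];
    if (std::fabs(S - c0) >= dev - 1e-9) ++cnt;
    return;
  }
  for (int i = k; i < n; ++i) {
    std::swap(b[k], b[i]);
    permRec(b, k + 1, a, c0, dev, cnt);
    std::swap(b[k], b[i]);
  }
}

// [[Rcpp::export]]
double exactSpearmanPermP(Rcpp::NumericVector a, Rcpp::NumericVector b) {
  const int n = a.size();
  if (n != b.size()) Rcpp::stop("rank vectors must have equal length");
  if (n < 2) Rcpp::stop("need at least 2 observations");
  if (n > 10) Rcpp::stop("exact enumeration supported for n <= 10 only");
  double ma = 0.0, mb = 0.0;
  for (int i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double c0 = n * ma * mb, Sobs = 0.0;
  for (int i = 0; i < n; ++i) Sobs += a[i] * b[i];
  const double dev = std::fabs(Sobs - c0);
  std::vector<double> bv(b.begin(), b.end());
  std::vector<double> av(a.begin(), a.end());
  long long cnt = 0;
  permRec(bv, 0, av, c0, dev, cnt);
  double total = 1.0;
  for (int i = 2; i <= n; ++i) total *= i;
  return (double)cnt / total;
}
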