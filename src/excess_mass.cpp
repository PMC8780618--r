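#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Empirical excess mass functional E_n(lambda, j): the maximum, over systems
// of at most j disjoint closed intervals with endpoints at data points, of
// sum_i [ P_n(I_i) - lambda * |I_i| ].
//
// Dynamic program over the sorted sample. With
//   w(s, m) = (m - s + 1)/n - lambda * (x[m] - x[s])
// the recursion
//   f_j(m) = max( f_j(m-1), max_{s <= m} f_{j-1}(s-1) + w(s, m) )
// rewrites as a running maximum over g(s) = f_{j-1}(s-1) + lambda*x[s] - s/n,
// giving O(n * j) per lambda. Interval systems are index-disjoint, so tied
// observations are each counted exactly once.
//
// Returns E_n(lambda, j) for j = 1..jmax.
static void excess_mass_profile(const std::vector<double>& x, double lambda,
                                int jmax, std::vector<double>& out) {
  const int n = (int)x.size();
  std::vector<double> prev(n + 1, 0.0), cur(n + 1, 0.0);
  for (int j = 1; j <= jmax; ++j) {
    double run = R_NegInf;
    cur[0] = 0.0;
    for (int m = 1; m <= n; ++m) {
      // candidate start s = m enters the running max
      double g = prev[m - 1] + lambda * x[m - 1] - (double)m / n;
      if (g > run) run = g;
      double open_here = (double)(m + 1) / n - lambda * x[m - 1] + run;
      cur[m] = std::max(cur[m - 1], open_here);
    }
    out[j - 1] = cur[n];
    std::swap(prev, cur);
  }
}

// Candidate lambda values: 0, all difference quotients of the empirical CDF
// over pairs of distinct data points, and one value beyond the largest
// quotient (where only singleton systems remain optimal). E_n(., j) is the
// upper envelope of linear functions of lambda, so the piecewise-linear
// difference E_n(., k+1) - E_n(., k) attains its maximum on this finite set.
static std::vector<double> candidate_lambdas(const std::vector<double>& x) {
  const int n = (int)x.size();
  std::vector<double> lam;
  lam.push_back(0.0);
  double lmax = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = x[j] - x[i];
      if (dx > 0) {
        double l = (double)(j - i) / n / dx;
        lam.push_back(l);
        if (l > lmax) lmax = l;
      }
    }
  }
  lam.push_back(2.0 * lmax + 1.0);
  std::sort(lam.begin(), lam.end());
  lam.erase(std::unique(lam.begin(), lam.end()), lam.end());
  return lam;
}

// [[Rcpp::export(name = ".excess_mass_cpp")]]
double excess_mass_cpp(NumericVector xs, int k) {
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  const int n = (int)x.size();
  if (n == 0) return 0.0;
  if (n == 1) return 0.0;
  std::vector<double> lam = candidate_lambdas(x);
  std::vector<double> prof(k + 1);
  double best = 0.0;
  for (size_t t = 0; t < lam.size(); ++t) {
    excess_mass_profile(x, lam[t], k + 1, prof);
    double d = prof[k] - prof[k - 1];
    if (d > best) best = d;
  }
  if (best < 0) best = 0.0;
  return best;
}

// [[Rcpp::export(name = ".excess_mass_fixed_lambda_cpp")]]
NumericVector excess_mass_fixed_lambda_cpp(NumericVector xs, double lambda,
                                           int jmax) {
  std::vector<double> x(xs.begin(), xs.end());
  std::sort(x.begin(), x.end());
  std::vector<double> prof(jmax);
  excess_mass_profile(x, lambda, jmax, prof);
  return NumericVector(prof.begin(), prof.end());
}
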