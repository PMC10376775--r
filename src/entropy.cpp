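#include <Rcpp.h>
using namespace Rcpp;

// Chebyshev distance between templates starting at i and j, length m.
static inline double cheb(const NumericVector& x, int i, int j, int m) {
  double d = 0.0;
  for (int k = 0; k < m; ++k) {
    double a = std::fabs(x[i + k] - x[j + k]);
    if (a > d) d = a;
  }
  return d;
}

// Pincus Phi_m: mean over templates of log(self-inclusive match fraction).
static double phi_m(const NumericVector& x, int m, double r) {
  int N = x.size();
  int M = N - m + 1;
  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    int cnt = 0;
    for (int j = 0; j < M; ++j)
      if (cheb(x, i, j, m) <= r) ++cnt;
    acc += std::log((double)cnt / M);
  }
  return acc / M;
}

// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  return phi_m(x, m, r) - phi_m(x, m + 1, r);
}

// Richman-Moorman counts: pairs (i < j) over the N - m templates whose
// length-m (B) and length-(m+1) (A) vectors match within r; self-matches
// excluded by construction.
// [[Rcpp::export]]
NumericVector sampen_counts_cpp(NumericVector x, int m, double r) {
  int N = x.size();
  int M = N - m;  // both template sets run over i = 0..M-1
  double A = 0.0, B = 0.0;
  for (int i = 0; i < M - 1; ++i) {
    for (int j = i + 1; j < M; ++j) {
      double d = cheb(x, i, j, m);
      if (d <= r) {
        B += 1.0;
        double a = std::fabs(x[i + m] - x[j + m]);
        if (std::max(d, a) <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(A, B);
}
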