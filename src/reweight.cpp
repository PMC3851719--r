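#include <Rcpp.h>
using namespace Rcpp;

// Log-denominator of the Jarzynski/WHAM frame weights.
// For frame (t, i) with steered-CV value q:
//   log sum_{t' in slices} [ log N + beta*f[t'] - beta*V(q, lambda[t']) ],
// V(q, l) = k/2 (q - l)^2.  `stride` decimates the t' sum (>= 1).
// Terms more than ~45 log-units below the running maximum are dropped
// (exp underflows double precision long before that).
// [[Rcpp::export]]
NumericMatrix cpp_log_denominator(NumericMatrix q, NumericVector lambda,
                                  NumericVector f, double beta, double k,
                                  int stride) {
  const int T = q.nrow(), N = q.ncol();
  if (lambda.size() != T || f.size() != T)
    stop("lambda/f length must equal the number of time slices");
  std::vector<int> sl;
  for (int t = 0; t < T; t += stride) sl.push_back(t);
  const double logN = std::log((double)N);
  std::vector<double> expo(sl.size());
  NumericMatrix out(T, N);
  for (int i = 0; i < N; ++i) {
    for (int t = 0; t < T; ++t) {
      const double qv = q(t, i);
      double mx = R_NegInf;
      for (size_t s = 0; s < sl.size(); ++s) {
        const double d = qv - lambda[sl[s]];
        expo[s] = logN + beta * f[sl[s]] - 0.5 * beta * k * d * d;
        if (expo[s] > mx) mx = expo[s];
      }
      double acc = 0.0;
      for (size_t s = 0; s < sl.size(); ++s)
        if (expo[s] > mx - 45.0) acc += std::exp(expo[s] - mx);
      out(t, i) = mx + std::log(acc);
    }
  }
  return out;
}
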