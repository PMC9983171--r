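#include <Rcpp.h>
using namespace Rcpp;

// Log-domain forward-backward over one observation sequence.
// logB: T x S per-bin log emission likelihoods; logPi: S; logA: S x S.
// Returns forward and backward total log-likelihoods (equal up to
// rounding), posterior state probabilities gamma and expected transition
// counts xi.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logB, NumericVector logPi, NumericMatrix logA) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix la(T, S), lb(T, S);

  for (int s = 0; s < S; s++) la(0, s) = logPi[s] + logB(0, s);
  for (int t = 1; t < T; t++) {
    for (int s = 0; s < S; s++) {
      double m = R_NegInf;
      for (int r = 0; r < S; r++) {
        double v = la(t - 1, r) + logA(r, s);
        if (v > m) m = v;
      }
      double acc = 0.0;
      for (int r = 0; r < S; r++) acc += std::exp(la(t - 1, r) + logA(r, s) - m);
      la(t, s) = m + std::log(acc) + logB(t, s);
    }
  }
  double m = R_NegInf;
  for (int s = 0; s < S; s++) if (la(T - 1, s) > m) m = la(T - 1, s);
  double acc = 0.0;
  for (int s = 0; s < S; s++) acc += std::exp(la(T - 1, s) - m);
  const double loglik = m + std::log(acc);

  for (int s = 0; s < S; s++) lb(T - 1, s) = 0.0;
  for (int t = T - 2; t >= 0; t--) {
    for (int s = 0; s < S; s++) {
      double mm = R_NegInf;
      for (int r = 0; r < S; r++) {
        double v = logA(s, r) + logB(t + 1, r) + lb(t + 1, r);
        if (v > mm) mm = v;
      }
      double a2 = 0.0;
      for (int r = 0; r < S; r++)
        a2 += std::exp(logA(s, r) + logB(t + 1, r) + lb(t + 1, r) - mm);
      lb(t, s) = mm + std::log(a2);
    }
  }
  double mb = R_NegInf;
  for (int s = 0; s < S; s++) {
    double v = logPi[s] + logB(0, s) + lb(0, s);
    if (v > mb) mb = v;
  }
  double ab = 0.0;
  for (int s = 0; s < S; s++)
    ab += std::exp(logPi[s] + logB(0, s) + lb(0, s) - mb);
  const double loglik_b = mb + std::log(ab);

  NumericMatrix gamma(T, S);
  for (int t = 0; t < T; t++)
    for (int s = 0; s < S; s++)
      gamma(t, s) = std::exp(la(t, s) + lb(t, s) - loglik);

  NumericMatrix xi(S, S);
  for (int t = 0; t < T - 1; t++)
    for (int r = 0; r < S; r++)
      for (int s = 0; s < S; s++)
        xi(r, s) += std::exp(la(t, r) + logA(r, s) + logB(t + 1, s) +
                             lb(t + 1, s) - loglik);

  return List::create(_["loglik"] = loglik, _["loglik_backward"] = loglik_b,
                      _["gamma"] = gamma, _["xi"] = xi);
}

// Max-probability (Viterbi) state path, 1-based state ids.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(NumericMatrix logB, NumericVector logPi,
                          NumericMatrix logA) {
  const int T = logB.nrow(), S = logB.ncol();
  NumericMatrix d(T, S);
  IntegerMatrix psi(T, S);
  for (int s = 0; s < S; s++) d(0, s) = logPi[s] + logB(0, s);
  for (int t = 1; t < T; t++) {
    for (int s = 0; s < S; s++) {
      double best = R_NegInf;
      int arg = 0;
      for (int r = 0; r < S; r++) {
        double v = d(t - 1, r) + logA(r, s);
        if (v > best) { best = v; arg = r; }
      }
      d(t, s) = best + logB(t, s);
      psi(t, s) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int s = 0; s < S; s++) if (d(T - 1, s) > best) { best = d(T - 1, s); arg = s; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; t--) path[t] = psi(t + 1, path[t + 1]);
  for (int t = 0; t < T; t++) path[t] += 1;
  return path;
}
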