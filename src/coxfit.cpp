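#include <Rcpp.h>
using namespace Rcpp;

// Stratified Cox log partial likelihood with Efron tie handling, plus
// gradient and observed information. Subjects must be sorted by stratum and,
// within stratum, by increasing follow-up time; sstart/send give 0-based
// inclusive index ranges per stratum. When want_baseline is true, per-event-
// time risk-set sums are returned for the Breslow baseline cumulative hazard
// and its delta-method variance components.
//
// [[Rcpp::export]]
List cox_ll(NumericVector time, IntegerVector event, NumericMatrix X,
            IntegerVector sstart, IntegerVector send, NumericVector beta,
            bool want_baseline) {
  const int p = X.ncol();
  const int n = X.nrow();
  const int nstrata = sstart.size();
  const double *tm = REAL(time);
  const int *ev = INTEGER(event);
  std::vector<const double *> xc(p);
  for (int j = 0; j < p; ++j) xc[j] = &X(0, j);

  double ll = 0.0;
  std::vector<double> grad(p, 0.0), infom(p * p, 0.0);

  std::vector<int> bl_stratum;
  std::vector<double> bl_time, bl_d, bl_s0;
  std::vector<double> bl_s1; // row-major, p per record

  std::vector<double> w(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += xc[j][i] * beta[j];
    w[i] = std::exp(e);
  }

  std::vector<double> S1(p), S2(p * p), S1D(p), S2D(p * p), xD(p), xi(p);

  for (int s = 0; s < nstrata; ++s) {
    double S0 = 0.0;
    std::fill(S1.begin(), S1.end(), 0.0);
    std::fill(S2.begin(), S2.end(), 0.0);
    int i = send[s];
    while (i >= sstart[s]) {
      // block of tied times [i0, i]
      int i0 = i;
      while (i0 > sstart[s] && tm[i0 - 1] == tm[i]) --i0;
      int d = 0;
      double wD = 0.0, llD = 0.0;
      std::fill(S1D.begin(), S1D.end(), 0.0);
      std::fill(S2D.begin(), S2D.end(), 0.0);
      std::fill(xD.begin(), xD.end(), 0.0);
      for (int k = i0; k <= i; ++k) {
        const double wk = w[k];
        S0 += wk;
        for (int a = 0; a < p; ++a) xi[a] = xc[a][k];
        for (int a = 0; a < p; ++a) {
          S1[a] += wk * xi[a];
          for (int b = 0; b <= a; ++b) S2[a * p + b] += wk * xi[a] * xi[b];
        }
        if (ev[k] == 1) {
          ++d;
          wD += wk;
          llD += std::log(wk);
          for (int a = 0; a < p; ++a) {
            xD[a] += xi[a];
            S1D[a] += wk * xi[a];
            for (int b = 0; b <= a; ++b) S2D[a * p + b] += wk * xi[a] * xi[b];
          }
        }
      }
      if (d > 0) {
        ll += llD;
        for (int a = 0; a < p; ++a) grad[a] += xD[a];
        for (int l = 0; l < d; ++l) {
          double f = (double)l / (double)d;
          double denom = S0 - f * wD;
          ll -= std::log(denom);
          for (int a = 0; a < p; ++a) {
            double s1a = S1[a] - f * S1D[a];
            grad[a] -= s1a / denom;
            for (int b = 0; b <= a; ++b) {
              double s1b = S1[b] - f * S1D[b];
              double s2ab = S2[a * p + b] - f * S2D[a * p + b];
              infom[a * p + b] += s2ab / denom - (s1a * s1b) / (denom * denom);
            }
          }
        }
        if (want_baseline) {
          bl_stratum.push_back(s + 1);
          bl_time.push_back(tm[i]);
          bl_d.push_back((double)d);
          bl_s0.push_back(S0);
          for (int a = 0; a < p; ++a) bl_s1.push_back(S1[a]);
        }
      }
      i = i0 - 1;
    }
  }

  NumericVector gradR(p);
  NumericMatrix infoR(p, p);
  for (int a = 0; a < p; ++a) {
    gradR[a] = grad[a];
    for (int b = 0; b <= a; ++b) {
      infoR(a, b) = infom[a * p + b];
      infoR(b, a) = infom[a * p + b];
    }
  }
  List out = List::create(Named("loglik") = ll, Named("grad") = gradR,
                          Named("info") = infoR);
  if (want_baseline) {
    int m = bl_time.size();
    NumericMatrix S1m(m, p);
    for (int r = 0; r < m; ++r)
      for (int a = 0; a < p; ++a) S1m(r, a) = bl_s1[r * p + a];
    out["baseline"] = List::create(
        Named("stratum") = wrap(bl_stratum), Named("time") = wrap(bl_time),
        Named("d") = wrap(bl_d), Named("S0") = wrap(bl_s0),
        Named("S1") = S1m);
  }
  return out;
}
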