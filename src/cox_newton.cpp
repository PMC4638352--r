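#include <Rcpp.h>
using namespace Rcpp;

// Univariate Cox partial-likelihood Newton iterations per column of x
// (Breslow tie handling). Inputs are pre-sorted by decreasing time so the
// risk set for an event is the prefix of rows up to the end of its tied
// block. Returns per-column coefficient and observed information.
// [[Rcpp::export(name = ".cox_newton")]]
List cox_newton(NumericVector time, IntegerVector event, NumericMatrix x,
                int max_iter, double tol) {
  const int n = x.nrow(), G = x.ncol();
  NumericVector coef(G), info(G);
  for (int j = 0; j < G; ++j) {
    const double* xj = &x(0, j);
    double b = 0.0, I = NA_REAL;
    for (int iter = 0; iter < max_iter; ++iter) {
      double s0 = 0.0, s1 = 0.0, s2 = 0.0, U = 0.0;
      I = 0.0;
      int i = 0;
      while (i < n) {
        int j2 = i;
        while (j2 + 1 < n && time[j2 + 1] == time[i]) ++j2;
        for (int k = i; k <= j2; ++k) {
          double w = std::exp(b * xj[k]);
          s0 += w;
          s1 += w * xj[k];
          s2 += w * xj[k] * xj[k];
        }
        for (int k = i; k <= j2; ++k) {
          if (event[k] == 1) {
            double eb = s1 / s0;
            U += xj[k] - eb;
            I += s2 / s0 - eb * eb;
          }
        }
        i = j2 + 1;
      }
      double step = (I > 1e-12) ? U / I : 0.0;
      if (step > 5.0) step = 5.0;
      if (step < -5.0) step = -5.0;
      b += step;
      if (std::abs(step) < tol) break;
    }
    coef[j] = b;
    info[j] = I;
  }
  return List::create(_["coef"] = coef, _["info"] = info);
}
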