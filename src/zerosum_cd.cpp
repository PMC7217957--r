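#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise coordinate descent for the zero-sum elastic net on CENTERED data:
//   min (1/(2n)) ||yc - Xc b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
//   s.t. sum(b) = 0.
// The constraint is maintained exactly by moving coefficient pairs
// (b_j, b_k) -> (b_j + d, b_k - d), where d minimizes the 1-D piecewise
// quadratic restriction exactly (stationary points of the four sign regions
// plus the two kinks). All bookkeeping lives in Gram space: with
// G = Xc'Xc, cy = Xc'yc, h = Xc'r and rss = ||yc - Xc b||^2 maintained
// incrementally, a pair attempt is O(1) and an accepted move O(p).
// With centered inputs the per-sweep intercept refresh b0 = mean(y - X b)
// is identically zero; the R wrapper restores b0 = ybar - xbar' b.

static inline double pair_gain(double d, double a, double c0, double la,
                               double bj, double bk) {
  // objective change g(d) - g(0); negative = improvement
  return 0.5 * a * d * d - c0 * d +
         la * (std::abs(bj + d) + std::abs(bk - d) -
               std::abs(bj) - std::abs(bk));
}

// [[Rcpp::export(name = ".zerosum_cd_path")]]
List zerosum_cd_path(NumericMatrix Xc, NumericVector yc, NumericVector lambdas,
                     double alpha, double tol, int maxSweeps,
                     NumericVector betaInit) {
  const int n = Xc.nrow(), p = Xc.ncol(), L = lambdas.size();
  if (p < 2) stop("zero-sum constraint needs at least two features");

  std::vector<double> G((size_t)p * p), cy(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += Xc(i, j) * yc[i];
    cy[j] = s;
    for (int k = j; k < p; ++k) {
      double g = 0.0;
      for (int i = 0; i < n; ++i) g += Xc(i, j) * Xc(i, k);
      G[(size_t)j * p + k] = G[(size_t)k * p + j] = g;
    }
  }
  double yy = 0.0;
  for (int i = 0; i < n; ++i) yy += yc[i] * yc[i];

  std::vector<double> beta(betaInit.begin(), betaInit.end()), h(p), Gb(p);

  NumericMatrix betaPath(p, L);
  NumericVector objOut(L);
  IntegerVector sweepsOut(L);
  LogicalVector convOut(L);

  for (int l = 0; l < L; ++l) {
    const double lambda = lambdas[l];
    const double la = lambda * alpha;
    const double lr = lambda * (1.0 - alpha);

    // refresh rss and h from scratch at each lambda (guards against the
    // slow accumulation of floating-point drift along the path)
    double rss = yy;
    for (int j = 0; j < p; ++j) {
      double s = 0.0;
      for (int k = 0; k < p; ++k) s += G[(size_t)j * p + k] * beta[k];
      Gb[j] = s;
      h[j] = cy[j] - s;
      rss += beta[j] * (s - 2.0 * cy[j]);
    }
    if (rss < 0.0) rss = 0.0;

    double l1 = 0.0, l2 = 0.0;
    for (int j = 0; j < p; ++j) {
      l1 += std::abs(beta[j]);
      l2 += beta[j] * beta[j];
    }
    double obj = rss / (2.0 * n) + la * l1 + 0.5 * lr * l2;

    int sweep = 0;
    bool converged = false;
    for (; sweep < maxSweeps; ++sweep) {
      for (int j = 0; j < p - 1; ++j) {
        const double Gjj = G[(size_t)j * p + j];
        for (int k = j + 1; k < p; ++k) {
          const double zz = Gjj + G[(size_t)k * p + k] -
                            2.0 * G[(size_t)j * p + k];
          const double a = zz / n + 2.0 * lr;
          if (a <= 0.0) continue;  // identical columns: no direction
          const double bj = beta[j], bk = beta[k];
          const double c0 = (h[j] - h[k]) / n - lr * (bj - bk);
          if (bj == 0.0 && bk == 0.0 && std::abs(c0) <= 2.0 * la)
            continue;  // zero pair already optimal

          double bestD = 0.0, bestG = 0.0;
          static const double s1s[4] = {1.0, 1.0, -1.0, -1.0};
          static const double s2s[4] = {1.0, -1.0, 1.0, -1.0};
          for (int q = 0; q < 4; ++q) {
            const double d = (c0 - la * (s1s[q] - s2s[q])) / a;
            if ((bj + d) * s1s[q] < 0.0 || (bk - d) * s2s[q] < 0.0) continue;
            const double g = pair_gain(d, a, c0, la, bj, bk);
            if (g < bestG) { bestG = g; bestD = d; }
          }
          for (int q = 0; q < 2; ++q) {
            const double d = (q == 0) ? -bj : bk;
            const double g = pair_gain(d, a, c0, la, bj, bk);
            if (g < bestG) { bestG = g; bestD = d; }
          }
          if (bestG < 0.0) {
            const double d = bestD;
            beta[j] = bj + d;
            beta[k] = bk - d;
            rss += d * d * zz - 2.0 * d * (h[j] - h[k]);
            if (rss < 0.0) rss = 0.0;
            for (int m = 0; m < p; ++m)
              h[m] -= d * (G[(size_t)j * p + m] - G[(size_t)k * p + m]);
          }
        }
      }
      double l1s = 0.0, l2s = 0.0;
      for (int j = 0; j < p; ++j) {
        l1s += std::abs(beta[j]);
        l2s += beta[j] * beta[j];
      }
      const double objNew = rss / (2.0 * n) + la * l1s + 0.5 * lr * l2s;
      const double dec = obj - objNew;
      obj = objNew;
      if (dec < tol) { converged = true; ++sweep; break; }
    }

    // exact zero-sum restoration against floating-point drift; spread over
    // the nonzero coordinates only so exact zeros stay exact
    double s = 0.0;
    int nz = 0;
    for (int j = 0; j < p; ++j) {
      s += beta[j];
      if (beta[j] != 0.0) ++nz;
    }
    if (s != 0.0 && nz > 0) {
      const double adj = s / nz;
      for (int j = 0; j < p; ++j)
        if (beta[j] != 0.0) beta[j] -= adj;
    }
    for (int j = 0; j < p; ++j) betaPath(j, l) = beta[j];
    objOut[l] = obj;
    sweepsOut[l] = sweep;
    convOut[l] = converged;
  }

  return List::create(_["beta"] = betaPath, _["objective"] = objOut,
                      _["nSweeps"] = sweepsOut, _["converged"] = convOut);
}
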