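#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Exhaustive grid search for the periodic step-function half-life.
//
// For each tuple (theta1, theta2, t0, K) the degradation-rate vector on the
// closed grid is theta1 inside the wrapped closed window [t0, t0+K] and
// theta2 outside.  One sweep of the generalized trapezoidal recurrence is an
// affine map R(T) = A*R(0) + p; tracking (A_n, p_n) at the measured indices
// during a single pass gives the exact periodic trajectory there once
// R(0) = p/(1-A) is known.  Scores: 0 = SSE between unit-mean profiles,
// 1 = 1 - Pearson r.  Ties broken toward the lexicographically smallest
// tuple (strict improvement required, loops ordered theta1, theta2, t0, K).

// [[Rcpp::export]]
List cpp_fit_step(NumericVector m, double dt, NumericVector theta1s,
                  NumericVector theta2s, NumericVector t0s, NumericVector Ks,
                  double period, IntegerVector meas_idx,
                  NumericVector meas_norm, int score_code,
                  bool keep_surface) {
  const int N = m.size() - 1;
  const int M = meas_idx.size();
  const int n1 = theta1s.size(), n2 = theta2s.size();
  const int nt = t0s.size(), nk = Ks.size();
  const double eps = 1e-9;

  // window membership of each grid point, per (t0, K) pair
  std::vector<unsigned char> member((size_t)nt * nk * (N + 1));
  for (int it = 0; it < nt; ++it) {
    for (int ik = 0; ik < nk; ++ik) {
      const double t0 = t0s[it], wend = t0 + Ks[ik];
      unsigned char *mem = &member[((size_t)it * nk + ik) * (N + 1)];
      for (int i = 0; i <= N; ++i) {
        // grid times span exactly one period: only t = T wraps, to 0
        double tm = i * dt;
        if (tm >= period) tm -= period;
        bool ins = (wend <= period + eps)
          ? (tm >= t0 - eps && tm <= wend + eps)
          : (tm >= t0 - eps || tm <= wend - period + eps);
        mem[i] = ins ? 1 : 0;
      }
    }
  }

  double best = R_PosInf;
  int b1 = 0, b2 = 0, bt = 0, bk = 0;
  NumericVector surface;
  if (keep_surface) surface = NumericVector((R_xlen_t)n1 * n2 * nt * nk);

  std::vector<double> kd(N + 1), Acum(M), pcum(M), pred(M);
  R_xlen_t q = 0;
  for (int i1 = 0; i1 < n1; ++i1) {
    const double kd1 = M_LN2 / theta1s[i1];
    for (int i2 = 0; i2 < n2; ++i2) {
      const double kd2 = M_LN2 / theta2s[i2];
      for (int it = 0; it < nt; ++it) {
        for (int ik = 0; ik < nk; ++ik) {
          const unsigned char *mem = &member[((size_t)it * nk + ik) * (N + 1)];
          for (int i = 0; i <= N; ++i) kd[i] = mem[i] ? kd1 : kd2;

          double A = 1.0, p = 0.0;
          int mi = 0;
          while (mi < M && meas_idx[mi] == 0) { Acum[mi] = 1.0; pcum[mi] = 0.0; ++mi; }
          for (int n = 0; n < N; ++n) {
            const double denom = 2.0 + kd[n + 1] * dt;
            const double a = (2.0 - kd[n] * dt) / denom;
            p = a * p + dt / denom * (m[n + 1] + m[n]);
            A *= a;
            while (mi < M && meas_idx[mi] == n + 1) { Acum[mi] = A; pcum[mi] = p; ++mi; }
          }
          const double R0 = p / (1.0 - A);

          double mean = 0.0;
          for (int j = 0; j < M; ++j) { pred[j] = Acum[j] * R0 + pcum[j]; mean += pred[j]; }
          mean /= M;

          double sc;
          if (score_code == 0) {
            sc = 0.0;
            for (int j = 0; j < M; ++j) {
              const double d = pred[j] / mean - meas_norm[j];
              sc += d * d;
            }
          } else {
            double my = 0.0;
            for (int j = 0; j < M; ++j) my += meas_norm[j];
            my /= M;
            double sxy = 0.0, sxx = 0.0, syy = 0.0;
            for (int j = 0; j < M; ++j) {
              const double dx = pred[j] - mean, dy = meas_norm[j] - my;
              sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
            }
            const double r = (sxx > 0.0 && syy > 0.0)
              ? sxy / std::sqrt(sxx * syy) : 0.0;
            sc = 1.0 - r;
          }
          if (keep_surface) surface[q] = sc;
          ++q;
          if (sc < best) { best = sc; b1 = i1; b2 = i2; bt = it; bk = ik; }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  List out = List::create(
    _["theta1"] = theta1s[b1], _["theta2"] = theta2s[b2],
    _["t0"] = t0s[bt], _["K"] = Ks[bk], _["score"] = best,
    _["evaluations"] = (double)q);
  if (keep_surface) out["surface"] = surface;
  return out;
}

// Two-sided exact permutation p-value for the Pearson correlation of x
// against all n! orderings of y (pass ranks for the Spearman version).
// [[Rcpp::export]]
double cpp_perm_pvalue(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n > 10) stop("exact permutation p-value limited to n <= 10");
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  auto corr = [&](const std::vector<int> &id) {
    double mx = 0, my = 0;
    for (int i = 0; i < n; ++i) { mx += x[i]; my += y[id[i]]; }
    mx /= n; my /= n;
    double sxy = 0, sxx = 0, syy = 0;
    for (int i = 0; i < n; ++i) {
      const double dx = x[i] - mx, dy = y[id[i]] - my;
      sxy += dx * dy; sxx += dx * dx; syy += dy * dy;
    }
    return sxy / std::sqrt(sxx * syy);
  };
  const double obs = std::fabs(corr(idx));
  long long count = 0, total = 0;
  std::sort(idx.begin(), idx.end());
  do {
    if (std::fabs(corr(idx)) >= obs - 1e-12) ++count;
    ++total;
  } while (std::next_permutation(idx.begin(), idx.end()));
  return (double)count / (double)total;
}
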