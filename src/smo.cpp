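// SMO solver for the soft-margin SVM dual with a precomputed kernel.
//
//   min_alpha  0.5 * alpha' Q alpha - 1' alpha
//   s.t.       0 <= alpha_i <= C,  y' alpha = 0,   Q_ij = y_i y_j K_ij
//
// Maximal-violating-pair selection with second-order (curvature) tie
// ranking, the standard stopping rule m(alpha) - M(alpha) <= eps, and a bias
// from the free support vectors (midpoint of the KKT bounds when none are
// free). Hard margin is the large-C limit of the same problem, so no
// separate formulation is needed.
//
// Pair update: with alpha_i(t) = alpha_i + y_i t, alpha_j(t) = alpha_j - y_j t
// the equality constraint is preserved, the directional derivative is
// y_i G_i - y_j G_j and the curvature is K_ii + K_jj - 2 K_ij; the Newton
// step is clipped to the exact feasible t-interval from both box constraints.

#include <Rcpp.h>
#include <cfloat>
using namespace Rcpp;

// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C, double eps,
               int max_iter, Nullable<NumericVector> alpha0 = R_NilValue,
               Nullable<NumericVector> grad0 = R_NilValue) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n)
    stop("kernel must be square and aligned with labels");
  for (int t = 0; t < n; ++t)
    if (y[t] != 1 && y[t] != -1) stop("labels must be coded -1 / +1");

  std::vector<double> alpha(n, 0.0);
  std::vector<double> G(n, -1.0);  // gradient of the dual objective
  if (alpha0.isNotNull()) {
    // intended for ascending-C warm starts, where the previous optimum is
    // already feasible; anything infeasible falls back to the zero start
    NumericVector a0(alpha0);
    if (a0.size() == n) {
      double viol = 0.0;
      bool ok = true;
      for (int t = 0; t < n; ++t) {
        if (a0[t] < 0 || a0[t] > C) { ok = false; break; }
        viol += y[t] * a0[t];
      }
      if (ok && std::abs(viol) <= 1e-9 * std::max(1.0, C)) {
        for (int t = 0; t < n; ++t) alpha[t] = a0[t];
        if (grad0.isNotNull() && NumericVector(grad0).size() == n) {
          // caller-maintained gradient (e.g. O(n)-updated across rank-one
          // kernel growth); trusted as consistent with alpha0
          NumericVector g0(grad0);
          for (int t = 0; t < n; ++t) G[t] = g0[t];
        } else {
          for (int t = 0; t < n; ++t) {
            double g = -1.0;
            for (int s = 0; s < n; ++s)
              if (alpha[s] != 0) g += y[t] * y[s] * K(t, s) * alpha[s];
            G[t] = g;
          }
        }
      }
    }
  }
  const double TAU = 1e-12;

  int iter = 0, stalled = 0;
  double gap = R_PosInf, Gmax = 0.0, Gmin = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    int i = -1;
    Gmax = -DBL_MAX;  // m(alpha) = max_{t in I_up} -y_t G_t
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      if (in_up) {
        double v = -y[t] * G[t];
        if (v > Gmax) { Gmax = v; i = t; }
      }
    }
    int j = -1;
    Gmin = DBL_MAX;  // M(alpha) = min_{t in I_low} -y_t G_t
    double best = 0.0;
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] == -1 && alpha[t] < C) || (y[t] == 1 && alpha[t] > 0);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < Gmin) Gmin = v;
      double viol = Gmax - v;
      if (i >= 0 && viol > TAU) {
        double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (a <= TAU) a = TAU;
        double dec = viol * viol / a;  // objective decrease of the pair
        if (dec > best) { best = dec; j = t; }
      }
    }
    gap = Gmax - Gmin;
    if (gap <= eps || i < 0 || j < 0) break;

    double a = K(i, i) + K(j, j) - 2.0 * K(i, j);
    if (a <= TAU) a = TAU;
    double tstep = (-y[i] * G[i] + y[j] * G[j]) / a;  // unconstrained optimum

    // feasible interval for t from 0 <= alpha_i + y_i t <= C and
    // 0 <= alpha_j - y_j t <= C
    double lo = -DBL_MAX, hi = DBL_MAX;
    if (y[i] == 1) { lo = std::max(lo, -alpha[i]); hi = std::min(hi, C - alpha[i]); }
    else           { lo = std::max(lo, alpha[i] - C); hi = std::min(hi, alpha[i]); }
    if (y[j] == 1) { lo = std::max(lo, alpha[j] - C); hi = std::min(hi, alpha[j]); }
    else           { lo = std::max(lo, -alpha[j]); hi = std::min(hi, C - alpha[j]); }
    if (tstep < lo) tstep = lo;
    if (tstep > hi) tstep = hi;

    double dai = y[i] * tstep, daj = -y[j] * tstep;
    double ai = alpha[i] + dai, aj = alpha[j] + daj;
    // snap to exact bounds so box membership stays crisp (floating dust at a
    // bound otherwise yields pairs with vanishing feasible steps)
    double snap = 1e-12 * std::max(1.0, C);
    if (ai < snap) ai = 0; else if (ai > C - snap) ai = C;
    if (aj < snap) aj = 0; else if (aj > C - snap) aj = C;
    dai = ai - alpha[i];
    daj = aj - alpha[j];
    if (dai == 0 && daj == 0) {
      if (++stalled > n) break;  // no representable progress left
      continue;
    }
    stalled = 0;
    alpha[i] = ai;
    alpha[j] = aj;
    for (int t = 0; t < n; ++t) {
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
    }
  }

  // bias: for free SVs, b = -y_t G_t exactly; otherwise the KKT inequalities
  // bracket b between m and M
  double b_sum = 0.0; int b_cnt = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 0 && alpha[t] < C) { b_sum += -y[t] * G[t]; ++b_cnt; }
  }
  double bias = b_cnt > 0 ? b_sum / b_cnt : (Gmax + Gmin) / 2.0;

  NumericVector coef(n), alph(n), grad(n);
  for (int t = 0; t < n; ++t) {
    alph[t] = alpha[t]; coef[t] = y[t] * alpha[t]; grad[t] = G[t];
  }
  return List::create(_["alpha"] = alph, _["coef"] = coef, _["b"] = bias,
                      _["iterations"] = iter, _["gap"] = gap,
                      _["converged"] = gap <= eps, _["gradient"] = grad);
}
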