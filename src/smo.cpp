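#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Binary C-SVC solved by SMO with first-order (maximal violating pair)
// working-set selection, the scheme used by LIBSVM.  The full kernel
// matrix is precomputed: training problems here are a few hundred
// samples, so memory is not a concern and the dense matrix is fastest.
//
// Dual problem: min 1/2 a' Q a - e' a,  0 <= a_i <= C,  y' a = 0,
// with Q_ij = y_i y_j K(x_i, x_j).  Gradient G_i = (Q a)_i - 1.

static inline double kernel_eval(const double *xi, const double *xj, int d,
                                 int kernel_type, double gamma) {
  double acc = 0.0;
  if (kernel_type == 0) { // RBF
    for (int t = 0; t < d; ++t) {
      double diff = xi[t] - xj[t];
      acc += diff * diff;
    }
    return std::exp(-gamma * acc);
  }
  for (int t = 0; t < d; ++t) acc += xi[t] * xj[t]; // linear
  return acc;
}

// [[Rcpp::export(name = ".smo_train")]]
List smo_train(NumericMatrix X, NumericVector y, double C,
               int kernel_type, double gamma,
               double eps = 1e-3, int max_iter = 100000) {
  const int n = X.nrow(), d = X.ncol();
  std::vector<const double *> rows(n);
  std::vector<std::vector<double>> Xr(n, std::vector<double>(d));
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < d; ++t) Xr[i][t] = X(i, t);
    rows[i] = Xr[i].data();
  }

  // Dense kernel matrix (symmetric).
  std::vector<double> K(static_cast<size_t>(n) * n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = kernel_eval(rows[i], rows[j], d, kernel_type, gamma);
      K[static_cast<size_t>(i) * n + j] = v;
      K[static_cast<size_t>(j) * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double m_val = 0.0, M_val = 0.0;

  while (iter < max_iter) {
    // working-set selection: maximal violating pair
    int i = -1, j = -1;
    m_val = -std::numeric_limits<double>::infinity();
    M_val = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double yG = -y[t] * G[t];
      bool in_up  = (y[t] > 0 && alpha[t] < C) || (y[t] < 0 && alpha[t] > 0);
      bool in_low = (y[t] > 0 && alpha[t] > 0) || (y[t] < 0 && alpha[t] < C);
      if (in_up && yG > m_val) { m_val = yG; i = t; }
      if (in_low && yG < M_val) { M_val = yG; j = t; }
    }
    if (i < 0 || j < 0 || m_val - M_val < eps) break;

    // two-variable subproblem on (i, j)
    const size_t in = static_cast<size_t>(i) * n, jn = static_cast<size_t>(j) * n;
    double quad = K[in + i] + K[jn + j] - 2.0 * K[in + j];
    if (quad <= 0) quad = 1e-12;
    double ai_old = alpha[i], aj_old = alpha[j];
    double delta = (m_val - M_val) / quad; // step along y_i e_i - y_j e_j

    // box constraints for alpha_i (direction +y_i*delta) and alpha_j
    double ai_new = ai_old + y[i] * delta;
    double aj_new = aj_old - y[j] * delta;
    // clip to [0, C] preserving y'a = 0
    double lo, hi; // feasible range for delta
    lo = -std::numeric_limits<double>::infinity();
    hi = std::numeric_limits<double>::infinity();
    if (y[i] > 0) { lo = std::max(lo, -ai_old); hi = std::min(hi, C - ai_old); }
    else          { lo = std::max(lo, ai_old - C); hi = std::min(hi, ai_old); }
    if (y[j] > 0) { lo = std::max(lo, aj_old - C); hi = std::min(hi, aj_old); }
    else          { lo = std::max(lo, -aj_old); hi = std::min(hi, C - aj_old); }
    if (delta > hi) delta = hi;
    if (delta < lo) delta = lo;
    ai_new = ai_old + y[i] * delta;
    aj_new = aj_old - y[j] * delta;

    double dai = ai_new - ai_old, daj = aj_new - aj_old;
    alpha[i] = ai_new;
    alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[in + t] * dai + y[j] * K[jn + t] * daj);
    ++iter;
  }

  // rho such that decision(x) = sum_i alpha_i y_i K(x_i, x) - rho
  double rho;
  {
    double sum = 0.0; int nfree = 0;
    double ub = std::numeric_limits<double>::infinity();
    double lb = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      double yG = y[t] * G[t];
      if (alpha[t] > 0 && alpha[t] < C) { sum += yG; ++nfree; }
      else if ((y[t] > 0 && alpha[t] <= 0) || (y[t] < 0 && alpha[t] >= C))
        ub = std::min(ub, yG);
      else
        lb = std::max(lb, yG);
    }
    rho = nfree > 0 ? sum / nfree : (ub + lb) / 2.0;
  }

  // keep support vectors only
  std::vector<int> sv_idx;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 1e-12) sv_idx.push_back(t);
  const int nsv = static_cast<int>(sv_idx.size());
  NumericMatrix SV(nsv, d);
  NumericVector coef(nsv);
  for (int s = 0; s < nsv; ++s) {
    int t = sv_idx[s];
    coef[s] = alpha[t] * y[t];
    for (int c = 0; c < d; ++c) SV(s, c) = Xr[t][c];
  }

  return List::create(_["sv"] = SV, _["coef"] = coef, _["rho"] = rho,
                      _["iterations"] = iter,
                      _["kkt_gap"] = m_val - M_val,
                      _["n_sv"] = nsv);
}

// [[Rcpp::export(name = ".smo_decision")]]
NumericVector smo_decision(NumericMatrix Xnew, NumericMatrix SV,
                           NumericVector coef, double rho,
                           int kernel_type, double gamma) {
  const int m = Xnew.nrow(), nsv = SV.nrow(), d = Xnew.ncol();
  NumericVector out(m);
  std::vector<double> xi(d), sv(d);
  for (int i = 0; i < m; ++i) {
    for (int t = 0; t < d; ++t) xi[t] = Xnew(i, t);
    double acc = 0.0;
    for (int s = 0; s < nsv; ++s) {
      for (int t = 0; t < d; ++t) sv[t] = SV(s, t);
      acc += coef[s] * kernel_eval(xi.data(), sv.data(), d, kernel_type, gamma);
    }
    out[i] = acc - rho;
  }
  return out;
}
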