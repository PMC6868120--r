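#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact SMO solver for the binary C-SVC dual over a precomputed Gram matrix:
//   min_a 0.5 a'Qa - e'a   s.t. 0 <= a_i <= C,  y'a = 0,   Q_ij = y_i y_j K_ij.
// Working-set selection is the maximal-violating-pair rule; termination when the
// KKT violation gap drops below eps. Linear kernel throughout, so the Gram matrix
// of an RFE step can be downdated in place when features are eliminated.

struct SmoFit {
  std::vector<double> alpha;
  double b;
  int iter;
  bool converged;
};

static SmoFit smo_train(const std::vector<double>& K, int n,
                        const std::vector<double>& y,
                        double C, double eps, int max_iter) {
  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int it = 0;
  double gmax = 0.0, gmin = 0.0;
  bool converged = false;
  for (it = 0; it < max_iter; ++it) {
    gmax = -HUGE_VAL; gmin = HUGE_VAL;
    int i = -1, j = -1;
    for (int t = 0; t < n; ++t) {
      bool up = (y[t] > 0.0) ? (alpha[t] < C) : (alpha[t] > 0.0);
      bool lo = (y[t] > 0.0) ? (alpha[t] > 0.0) : (alpha[t] < C);
      double v = -y[t] * G[t];
      if (up && v > gmax) { gmax = v; i = t; }
      if (lo && v < gmin) { gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || gmax - gmin < eps) { converged = true; break; }

    // analytic two-variable update (Platt), variables i and j
    double Kii = K[(size_t)i * n + i];
    double Kjj = K[(size_t)j * n + j];
    double Kij = K[(size_t)i * n + j];
    double eta = Kii + Kjj - 2.0 * Kij;
    if (eta <= 1e-12) eta = 1e-12;
    // E_t = f_t - y_t with f_t = sum_s a_s y_s K_st;  G_t = y_t f_t - 1
    double Ei = y[i] * (G[i] + 1.0) - y[i];
    double Ej = y[j] * (G[j] + 1.0) - y[j];
    double ai_old = alpha[i], aj_old = alpha[j];
    double L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj_old - ai_old);
      H = std::min(C, C + aj_old - ai_old);
    } else {
      L = std::max(0.0, ai_old + aj_old - C);
      H = std::min(C, ai_old + aj_old);
    }
    double aj_new = aj_old + y[j] * (Ei - Ej) / eta;
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    // snap to the box: dust-sized residues would keep variables spuriously
    // "interior" and stall the maximal-violating-pair selection
    const double tol = 1e-12 * C;
    if (aj_new < tol) aj_new = 0.0; else if (aj_new > C - tol) aj_new = C;
    double ai_new = ai_old + y[i] * y[j] * (aj_old - aj_new);
    if (ai_new < tol) ai_new = 0.0; else if (ai_new > C - tol) ai_new = C;
    double dai = ai_new - ai_old, daj = aj_new - aj_old;
    if (std::fabs(dai) < 1e-15 && std::fabs(daj) < 1e-15) { converged = true; break; }
    alpha[i] = ai_new; alpha[j] = aj_new;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                      y[j] * K[(size_t)j * n + t] * daj);
  }
  // bias: exact on free SVs (y_t - f_t = b there); else midpoint of KKT bounds
  double bsum = 0.0; int nfree = 0;
  for (int t = 0; t < n; ++t) {
    if (alpha[t] > 1e-10 && alpha[t] < C - 1e-10) {
      bsum += -y[t] * G[t];  // equals y_t - f_t
      ++nfree;
    }
  }
  SmoFit fit;
  fit.b = nfree > 0 ? bsum / nfree : 0.5 * (gmax + gmin);
  fit.alpha = alpha;
  fit.iter = it;
  fit.converged = converged;
  return fit;
}

static std::vector<double> flatten(const NumericMatrix& M) {
  return std::vector<double>(M.begin(), M.end());
}

// [[Rcpp::export]]
List cpp_svm_train(NumericMatrix K, NumericVector y, double C,
                   double eps = 1e-6, int max_iter = 200000) {
  int n = K.nrow();
  std::vector<double> yv(y.begin(), y.end());
  SmoFit fit = smo_train(flatten(K), n, yv, C, eps, max_iter);
  return List::create(_["alpha"] = NumericVector(fit.alpha.begin(), fit.alpha.end()),
                      _["b"] = fit.b, _["iter"] = fit.iter,
                      _["converged"] = fit.converged);
}

// SVM-RFE over a linear kernel. Trains on X (n x p), optionally scoring a held-out
// block Xtest at every elimination step using the model fitted *before* that step's
// elimination. Removes floor(frac * p_active) features per step (at least 1, never
// the last survivor); ties in w^2 are broken by index, the higher index leaving first.
// Returns the full ranking (rank 1 = last survivor), the active-set size at each
// recorded step, and the per-step decision values on Xtest.
// [[Rcpp::export]]
List cpp_svm_rfe(NumericMatrix X, NumericVector y, double C, double frac,
                 NumericMatrix Xtest, double eps = 1e-6, int max_iter = 200000) {
  int n = X.nrow(), p = X.ncol(), ntest = Xtest.nrow();
  std::vector<double> yv(y.begin(), y.end());

  std::vector<double> K((size_t)n * n, 0.0), Kt((size_t)n * ntest, 0.0);
  for (int a = 0; a < n; ++a)
    for (int b = a; b < n; ++b) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) s += X(a, f) * X(b, f);
      K[(size_t)a * n + b] = s; K[(size_t)b * n + a] = s;
    }
  for (int a = 0; a < n; ++a)
    for (int u = 0; u < ntest; ++u) {
      double s = 0.0;
      for (int f = 0; f < p; ++f) s += X(a, f) * Xtest(u, f);
      Kt[(size_t)a * ntest + u] = s;
    }

  std::vector<int> active(p);
  for (int f = 0; f < p; ++f) active[f] = f;
  std::vector<int> ranking(p, 0);
  std::vector<int> sizes;
  std::vector< std::vector<double> > test_dec;
  int next_rank = p;

  while (!active.empty()) {
    int pa = (int)active.size();
    SmoFit fit = smo_train(K, n, yv, C, eps, max_iter);

    sizes.push_back(pa);
    std::vector<double> dec(ntest, fit.b);
    for (int t = 0; t < n; ++t) {
      double c = fit.alpha[t] * yv[t];
      if (c == 0.0) continue;
      for (int u = 0; u < ntest; ++u) dec[u] += c * Kt[(size_t)t * ntest + u];
    }
    test_dec.push_back(dec);

    if (pa == 1) { ranking[0] = active[0] + 1; break; }

    // squared-weight scores on the active features
    std::vector< std::pair<double, int> > score(pa);
    for (int k = 0; k < pa; ++k) {
      int f = active[k];
      double w = 0.0;
      for (int t = 0; t < n; ++t) w += fit.alpha[t] * yv[t] * X(t, f);
      score[k] = std::make_pair(w * w, f);
    }
    int n_elim = (int)std::floor(frac * pa);
    if (n_elim < 1) n_elim = 1;
    if (n_elim > pa - 1) n_elim = pa - 1;
    // worst first: smaller w^2 first, ties -> higher index first
    std::sort(score.begin(), score.end(),
              [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
                if (a.first != b.first) return a.first < b.first;
                return a.second > b.second;
              });
    std::vector<int> elim(n_elim);
    for (int k = 0; k < n_elim; ++k) {
      elim[k] = score[k].second;
      ranking[next_rank - 1] = score[k].second + 1;  // worst gets highest rank
      --next_rank;
    }
    // downdate Gram blocks and shrink the active set
    for (int k = 0; k < n_elim; ++k) {
      int f = elim[k];
      for (int a = 0; a < n; ++a) {
        double xa = X(a, f);
        if (xa == 0.0) continue;
        for (int b = 0; b < n; ++b) K[(size_t)a * n + b] -= xa * X(b, f);
        for (int u = 0; u < ntest; ++u) Kt[(size_t)a * ntest + u] -= xa * Xtest(u, f);
      }
    }
    std::vector<int> keep;
    keep.reserve(pa - n_elim);
    for (int k = 0; k < pa; ++k) {
      int f = active[k];
      if (std::find(elim.begin(), elim.end(), f) == elim.end()) keep.push_back(f);
    }
    active.swap(keep);
  }

  NumericMatrix D((int)test_dec.size(), ntest);
  for (int s = 0; s < (int)test_dec.size(); ++s)
    for (int u = 0; u < ntest; ++u) D(s, u) = test_dec[s][u];
  return List::create(_["ranking"] = IntegerVector(ranking.begin(), ranking.end()),
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()),
                      _["test_decisions"] = D);
}
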