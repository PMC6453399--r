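#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Dual coordinate descent for the L2-regularized hinge-loss (L1) linear
// SVM (Hsieh et al., ICML 2008), with the standard shrinking heuristic
// and projected-gradient-gap stopping rule of liblinear-style solvers.
// The intercept is handled by an augmented constant feature supplied by
// the caller, so the dual has simple box constraints 0 <= alpha_i <= C
// and the weight vector is maintained explicitly, keeping one sweep at
// O(n p) independent of C.
//
// Deterministic: coordinate order is reshuffled each epoch with a fixed
// xorshift generator, so fits are bit-reproducible.

// [[Rcpp::export(name = ".dcdLinearSvm")]]
Rcpp::List dcdLinearSvm(const arma::mat& X, const arma::vec& y, double C,
                        double tol, int maxEpochs) {
  const arma::mat Xt = X.t();          // p x n: contiguous per-sample columns
  const int n = X.n_rows, p = X.n_cols;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec w(p, arma::fill::zeros);
  arma::vec Qii(n);
  for (int i = 0; i < n; ++i) Qii[i] = arma::dot(Xt.col(i), Xt.col(i));

  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  int nActive = n;
  unsigned long long state = 88172645463325252ULL;
  auto nextRand = [&state]() {
    state ^= state << 13; state ^= state >> 7; state ^= state << 17;
    return state;
  };
  const double inf = std::numeric_limits<double>::infinity();
  double pgMaxOld = inf, pgMinOld = -inf;
  bool converged = false;
  int epoch = 0;

  for (; epoch < maxEpochs; ++epoch) {
    for (int i = nActive - 1; i > 0; --i) {
      int j = static_cast<int>(nextRand() % static_cast<unsigned long long>(i + 1));
      std::swap(active[i], active[j]);
    }
    double pgMax = -inf, pgMin = inf;
    for (int k = 0; k < nActive; ++k) {
      const int i = active[k];
      if (Qii[i] <= 0.0) continue;
      const double G = y[i] * arma::dot(w, Xt.col(i)) - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0) {
        if (G > pgMaxOld) {            // shrink: stuck at lower bound
          std::swap(active[k], active[--nActive]); --k; continue;
        }
        PG = std::min(G, 0.0);
      } else if (alpha[i] >= C) {
        if (G < pgMinOld) {            // shrink: stuck at upper bound
          std::swap(active[k], active[--nActive]); --k; continue;
        }
        PG = std::max(G, 0.0);
      }
      pgMax = std::max(pgMax, PG);
      pgMin = std::min(pgMin, PG);
      if (std::fabs(PG) > 1e-12) {
        const double aOld = alpha[i];
        alpha[i] = std::min(std::max(alpha[i] - G / Qii[i], 0.0), C);
        if (alpha[i] != aOld) w += (alpha[i] - aOld) * y[i] * Xt.col(i);
      }
    }
    if (pgMax - pgMin <= tol) {
      if (nActive == n) { converged = true; break; }
      // optimal on the active set: take a final full pass over all points
      nActive = n; pgMaxOld = inf; pgMinOld = -inf;
      continue;
    }
    pgMaxOld = (pgMax <= 0.0) ? inf : pgMax;
    pgMinOld = (pgMin >= 0.0) ? -inf : pgMin;
  }
  return Rcpp::List::create(
    Rcpp::_["w"] = w, Rcpp::_["alpha"] = alpha,
    Rcpp::_["epochs"] = epoch + 1,
    Rcpp::_["converged"] = converged);
}
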