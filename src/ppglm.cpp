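// Point-process GLM core: spike-history features, forward simulation of the
// generative model, Newton (IRLS) maximum-likelihood fitting, and the
// shuffle-refit loops used by the permutation nulls.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// History window layout (in 1-ms lags): five single-bin lags 1..5, then six
// 25-bin windows 6-30, 31-55, 56-80, 81-105, 106-130, 131-155.
static const int H1_LAGS = 5;
static const int HW_N = 6;
static const int HW_LEN = 25;

static inline double histFeature(const IntegerVector& y, int i, int k) {
  // k in 0..10; i is the current bin (0-based). Uses only bins < i.
  if (k < H1_LAGS) {
    int j = i - (k + 1);
    return j >= 0 ? y[j] : 0.0;
  }
  int w = k - H1_LAGS;
  int a = H1_LAGS + 1 + w * HW_LEN;      // first lag of window (6, 31, ...)
  int b = a + HW_LEN - 1;                // last lag (30, 55, ...)
  double s = 0.0;
  int lo = i - b, hi = i - a;
  if (lo < 0) lo = 0;
  for (int j = lo; j <= hi; ++j) s += y[j];
  return (hi >= 0) ? s : 0.0;
}

// [[Rcpp::export]]
NumericMatrix cpp_history_matrix(IntegerVector y) {
  int n = y.size();
  NumericMatrix H(n, 11);
  // incremental window sums for the six 25-ms windows
  std::vector<double> wsum(HW_N, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < H1_LAGS; ++k) {
      int j = i - (k + 1);
      H(i, k) = j >= 0 ? y[j] : 0.0;
    }
    for (int w = 0; w < HW_N; ++w) {
      int a = H1_LAGS + 1 + w * HW_LEN;
      int b = a + HW_LEN - 1;
      // update running sum when advancing from bin i-1 to i:
      // window covers y[i-b .. i-a]
      int add = i - a, drop = i - b - 1;
      if (add >= 0) wsum[w] += y[add];
      if (drop >= 0) wsum[w] -= y[drop];
      H(i, H1_LAGS + w) = wsum[w];
    }
  }
  return H;
}

// Forward simulation of the generative point-process model: per 1-ms bin,
// counts are Poisson with mean Delta * exp(eta), where eta encodes the
// constant, the spike history emitted so far, the recording indicator, the
// touch indicator and (optionally) the partner-sex indicator. Uses R's RNG.
// [[Rcpp::export]]
List cpp_simulate_glm_train(NumericVector touch, NumericVector sex,
                            IntegerVector rec, int nRec,
                            double beta0, NumericVector h,
                            NumericVector betaRec, double betaTouch,
                            double betaSex, double delta) {
  int n = touch.size();
  if (h.size() != 11) stop("h must have 11 entries");
  if (betaRec.size() != nRec - 1) stop("betaRec must have nRec - 1 entries");
  IntegerVector y(n);
  std::vector<double> wsum(HW_N, 0.0);
  RNGScope scope;
  int warned = 0;
  for (int i = 0; i < n; ++i) {
    double eta = beta0;
    for (int k = 0; k < H1_LAGS; ++k) {
      int j = i - (k + 1);
      if (j >= 0 && y[j]) eta += h[k] * y[j];
    }
    for (int w = 0; w < HW_N; ++w) {
      int a = H1_LAGS + 1 + w * HW_LEN;
      int b = a + HW_LEN - 1;
      int add = i - a, drop = i - b - 1;
      if (add >= 0) wsum[w] += y[add];
      if (drop >= 0) wsum[w] -= y[drop];
      eta += h[H1_LAGS + w] * wsum[w];
    }
    if (rec[i] > 1) eta += betaRec[rec[i] - 2];
    eta += betaTouch * touch[i];
    eta += betaSex * sex[i];
    double mu = delta * std::exp(eta);
    if (mu > 1.0) ++warned;
    y[i] = (int) R::rpois(mu);
  }
  return List::create(_["counts"] = y, _["denseBins"] = warned);
}

struct FitResult {
  arma::vec beta;
  double ll;
  bool converged;
  int iter;
  double gradNorm;
};

static double ppLL(const arma::vec& eta, const arma::vec& y, double logDelta,
                   double lgamConst) {
  // sum(y * (eta + logDelta)) - sum(lgamma(y+1)) - sum(exp(eta + logDelta))
  return arma::dot(y, eta + logDelta) - lgamConst - arma::accu(arma::exp(eta + logDelta));
}

static FitResult newtonFit(const arma::mat& X, const arma::vec& y,
                           double logDelta, arma::vec beta,
                           int maxIter, double tol) {
  int n = X.n_rows;
  double lgamConst = 0.0;
  for (int i = 0; i < n; ++i) lgamConst += std::lgamma(y[i] + 1.0);
  double sy = arma::accu(y);
  double gtol = tol * (1.0 + sy);
  arma::vec eta = X * beta;
  double ll = ppLL(eta, y, logDelta, lgamConst);
  FitResult res{beta, ll, false, 0, NA_REAL};
  for (int it = 1; it <= maxIter; ++it) {
    arma::vec mu = arma::exp(eta + logDelta);
    arma::vec grad = X.t() * (y - mu);
    res.gradNorm = arma::abs(grad).max();
    if (res.gradNorm < gtol) {
      res.converged = true;
      res.iter = it - 1;
      res.beta = beta;
      res.ll = ll;
      return res;
    }
    arma::mat H = X.t() * (X.each_col() % mu);
    // tiny scale-aware ridge: keeps the solve stable when a history column
    // separates (its rate driven to ~0, Hessian block to ~0)
    H.diag() += 1e-10 * (1.0 + H.diag().max());
    arma::vec step;
    bool ok = arma::solve(step, H, grad,
                          arma::solve_opts::likely_sympd + arma::solve_opts::no_approx);
    if (!ok || !step.is_finite()) {
      res.iter = it;
      res.beta = beta;
      res.ll = ll;
      return res; // singular Hessian: flagged non-converged
    }
    // step-halving: Poisson log-link likelihood is concave, so the full
    // Newton step is accepted except near numerically extreme coefficients
    double t = 1.0;
    arma::vec betaNew, etaNew;
    double llNew = -arma::datum::inf;
    for (int hcount = 0; hcount < 30; ++hcount) {
      betaNew = beta + t * step;
      etaNew = X * betaNew;
      if (etaNew.max() + logDelta < 30.0) { // guard exp overflow
        llNew = ppLL(etaNew, y, logDelta, lgamConst);
        if (llNew >= ll - 1e-12) break;
      }
      t *= 0.5;
    }
    if (!std::isfinite(llNew) || llNew < ll - 1e-8) {
      res.iter = it;
      res.beta = beta;
      res.ll = ll;
      return res;
    }
    bool stalled = (llNew - ll) < 1e-12 * (1.0 + std::abs(ll));
    beta = betaNew;
    eta = etaNew;
    ll = llNew;
    res.iter = it;
    if (stalled) {
      // concave, bounded likelihood: a stalled objective is at its optimum
      // (or on a separation plateau whose limit it has numerically reached)
      res.converged = true;
      res.beta = beta;
      res.ll = ll;
      arma::vec muS = arma::exp(eta + logDelta);
      res.gradNorm = arma::abs(X.t() * (y - muS)).max();
      return res;
    }
  }
  res.beta = beta;
  res.ll = ll;
  return res;
}

// [[Rcpp::export]]
List cpp_pp_fit(const arma::mat& X, const arma::vec& y, double logDelta,
                NumericVector betaInit, int maxIter = 50, double tol = 1e-9) {
  arma::vec b0(betaInit.begin(), betaInit.size());
  FitResult r = newtonFit(X, y, logDelta, b0, maxIter, tol);
  return List::create(
    _["beta"] = NumericVector(r.beta.begin(), r.beta.end()),
    _["logLik"] = r.ll, _["converged"] = r.converged,
    _["iter"] = r.iter, _["gradNorm"] = r.gradNorm);
}

// Log likelihood (with constants) at a fixed beta.
// [[Rcpp::export]]
double cpp_pp_loglik(const arma::mat& X, const arma::vec& y, double logDelta,
                     const arma::vec& beta) {
  arma::vec eta = X * beta;
  if (!eta.is_finite()) stop("non-finite linear predictor");
  double lgamConst = 0.0;
  for (arma::uword i = 0; i < y.n_elem; ++i) lgamConst += std::lgamma(y[i] + 1.0);
  return ppLL(eta, y, logDelta, lgamConst);
}

// Refit with the column at colIdx (0-based) circularly shifted over the
// retained-bin axis; returns the maximized log likelihood per shift.
// Warm-started from betaInit (typically the unshuffled fit).
// [[Rcpp::export]]
NumericVector cpp_shuffle_shift_ll(const arma::mat& X, const arma::vec& y,
                                   double logDelta, int colIdx,
                                   IntegerVector shifts,
                                   NumericVector betaInit,
                                   int maxIter = 50, double tol = 1e-9) {
  arma::mat Xs = X;
  arma::vec col = X.col(colIdx);
  int n = X.n_rows;
  arma::vec warm(betaInit.begin(), betaInit.size());
  NumericVector out(shifts.size());
  for (int s = 0; s < shifts.size(); ++s) {
    int k = ((shifts[s] % n) + n) % n;
    arma::vec shifted(n);
    // shifted[i] = col[(i - k) mod n]
    if (k > 0) {
      shifted.head(k) = col.tail(k);
      shifted.tail(n - k) = col.head(n - k);
    } else {
      shifted = col;
    }
    Xs.col(colIdx) = shifted;
    FitResult r = newtonFit(Xs, y, logDelta, warm, maxIter, tol);
    out[s] = r.converged ? r.ll : NA_REAL;
  }
  return out;
}

// Refit with the column at colIdx replaced by each column of newCols.
// [[Rcpp::export]]
NumericVector cpp_shuffle_col_ll(const arma::mat& X, const arma::vec& y,
                                 double logDelta, int colIdx,
                                 const arma::mat& newCols,
                                 NumericVector betaInit,
                                 int maxIter = 50, double tol = 1e-9) {
  arma::mat Xs = X;
  arma::vec warm(betaInit.begin(), betaInit.size());
  NumericVector out(newCols.n_cols);
  for (arma::uword s = 0; s < newCols.n_cols; ++s) {
    Xs.col(colIdx) = newCols.col(s);
    FitResult r = newtonFit(Xs, y, logDelta, warm, maxIter, tol);
    out[s] = r.converged ? r.ll : NA_REAL;
  }
  return out;
}

// Spike totals per stimulus category for each circular shift of the
// category labels along the retained-bin axis (occupancy is shift-invariant).
// cat is 0-based; returns nShifts x nCat matrix of spike sums.
// [[Rcpp::export]]
NumericMatrix cpp_category_spikes_shifted(IntegerVector y, IntegerVector cat,
                                          int nCat, IntegerVector shifts) {
  int n = y.size();
  NumericMatrix out(shifts.size(), nCat);
  for (int s = 0; s < shifts.size(); ++s) {
    int k = ((shifts[s] % n) + n) % n;
    for (int i = 0; i < n; ++i) {
      if (y[i]) {
        int j = i - k; // label aligned to bin i after shifting labels by k
        if (j < 0) j += n;
        out(s, cat[j]) += y[i];
      }
    }
  }
  return out;
}
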