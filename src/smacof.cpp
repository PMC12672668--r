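// SMACOF majorization engine for interval MDS with pairwise weights.
// Zero-weight pairs (never co-presented items) are excluded from both the
// disparity regression and the Guttman transform.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat pair_dist(const arma::mat& X) {
  const int n = X.n_rows;
  const int k = X.n_cols;
  arma::mat d(n, n, arma::fill::zeros);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int c = 0; c < k; ++c) {
        double v = X(i, c) - X(j, c);
        s += v * v;
      }
      d(i, j) = d(j, i) = std::sqrt(s);
    }
  }
  return d;
}

struct SmacofResult {
  arma::mat X;
  double stress1;
  double a;
  double b;
  arma::vec trace;
  int iterations;
  bool converged;
};

// One SMACOF run from a given start. delta and w are symmetric with zero
// diagonal; disparities follow the interval model dhat = a + b*delta with
// b >= 0 and dhat clamped at zero, rescaled each sweep so that
// sum_{i<j} w * dhat^2 equals sum_{i<j} w (the de Leeuw normalization).
static SmacofResult smacof_run(const arma::mat& delta, const arma::mat& w,
                               const arma::mat& X0, int max_iter, double tol) {
  const int n = delta.n_rows;
  arma::mat X = X0;
  // row means removed up front; Guttman transform preserves centering
  X.each_row() -= arma::mean(X, 0);

  // weighted sums over the upper triangle
  double C = 0.0, sw = 0.0, swd = 0.0, swdd = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      C += w(i, j);
      sw += w(i, j);
      swd += w(i, j) * delta(i, j);
      swdd += w(i, j) * delta(i, j) * delta(i, j);
    }

  // Moore-Penrose inverse of V = diag(rowsum(w)) - w via the rank-completion
  // identity Vinv = inv(V + J/n) - J/n
  arma::mat V = arma::diagmat(arma::sum(w, 1)) - w;
  arma::mat J(n, n);
  J.fill(1.0 / n);
  arma::mat Vinv = arma::inv_sympd(V + J) - J;

  arma::vec trace(max_iter, arma::fill::zeros);
  double a = 0.0, b = 1.0, a_eff = 0.0, b_eff = 1.0;
  double s_prev = arma::datum::inf, s_cur = arma::datum::inf;
  bool converged = false;
  int iter = 0;

  arma::mat dhat(n, n, arma::fill::zeros);

  for (iter = 0; iter < max_iter; ++iter) {
    arma::mat d = pair_dist(X);

    // interval disparity update: weighted least squares of d on delta
    double swx = 0.0;  // sum w * d
    double swdx = 0.0; // sum w * delta * d
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        swx += w(i, j) * d(i, j);
        swdx += w(i, j) * delta(i, j) * d(i, j);
      }
    double denom = swdd - swd * swd / sw;
    if (denom > 1e-300) {
      b = (swdx - swd * swx / sw) / denom;
    } else {
      b = 0.0;
    }
    if (b < 0.0) b = 0.0;
    a = (swx - b * swd) / sw;

    double ss = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double v = a + b * delta(i, j);
        if (v < 0.0) v = 0.0;
        dhat(i, j) = dhat(j, i) = v;
        ss += w(i, j) * v * v;
      }
    if (ss <= 1e-300) {
      // disparities collapsed; bail out with current state
      break;
    }
    double lambda = std::sqrt(C / ss);
    dhat *= lambda;

    // Guttman transform
    arma::mat B(n, n, arma::fill::zeros);
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (w(i, j) > 0.0 && d(i, j) > 1e-300) {
          double bij = -w(i, j) * dhat(i, j) / d(i, j);
          B(i, j) = B(j, i) = bij;
        }
      }
    for (int i = 0; i < n; ++i) B(i, i) = -arma::accu(B.row(i));
    X = Vinv * (B * X);

    // normalized stress after the full sweep
    d = pair_dist(X);
    double sigma = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r = dhat(i, j) - d(i, j);
        sigma += w(i, j) * r * r;
      }
    s_cur = std::sqrt(sigma / C);
    trace(iter) = s_cur;

    if (std::isfinite(s_prev) &&
        (s_prev - s_cur) < tol * std::max(s_prev, 1e-12)) {
      converged = true;
      ++iter;
      break;
    }
    s_prev = s_cur;
  }

  // Kruskal stress-1 at the final configuration, with the interval
  // transform refit by weighted least squares (no normalization): this is
  // the conventional stress-1 the diagnostics report
  arma::mat d = pair_dist(X);
  {
    double swx = 0.0, swdx = 0.0;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        swx += w(i, j) * d(i, j);
        swdx += w(i, j) * delta(i, j) * d(i, j);
      }
    double denom = swdd - swd * swd / sw;
    double bf = (denom > 1e-300) ? (swdx - swd * swx / sw) / denom : 0.0;
    if (bf < 0.0) bf = 0.0;
    double af = (swx - bf * swd) / sw;
    a_eff = af;
    b_eff = bf;
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        double v = af + bf * delta(i, j);
        if (v < 0.0) v = 0.0;
        dhat(i, j) = dhat(j, i) = v;
      }
  }
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double r = dhat(i, j) - d(i, j);
      num += w(i, j) * r * r;
      den += w(i, j) * d(i, j) * d(i, j);
    }
  double stress1 = (den > 0.0) ? std::sqrt(num / den) : NA_REAL;

  X.each_row() -= arma::mean(X, 0);

  SmacofResult out;
  out.X = X;
  out.stress1 = stress1;
  out.a = a_eff;
  out.b = b_eff;
  out.trace = trace.head(std::max(iter, 1));
  out.iterations = iter;
  out.converged = converged;
  return out;
}

// [[Rcpp::export(name = ".smacof_engine")]]
List smacof_engine(const arma::mat& delta, const arma::mat& w,
                   const arma::mat& X0, int max_iter = 1000,
                   double tol = 1e-6) {
  SmacofResult r = smacof_run(delta, w, X0, max_iter, tol);
  return List::create(
      _["X"] = r.X, _["stress1"] = r.stress1, _["a"] = r.a, _["b"] = r.b,
      _["trace"] = NumericVector(r.trace.begin(), r.trace.end()),
      _["iterations"] = r.iterations, _["converged"] = r.converged);
}

// Multi-start driver: starts is a list of n x k matrices generated (seeded)
// on the R side. Returns the lowest-stress solution and its start index.
// [[Rcpp::export(name = ".smacof_multistart")]]
List smacof_multistart(const arma::mat& delta, const arma::mat& w,
                       const List& starts, int max_iter = 1000,
                       double tol = 1e-6) {
  const int ns = starts.size();
  SmacofResult best;
  best.stress1 = arma::datum::inf;
  int best_idx = -1;
  for (int s = 0; s < ns; ++s) {
    arma::mat X0 = as<arma::mat>(starts[s]);
    SmacofResult r = smacof_run(delta, w, X0, max_iter, tol);
    if (std::isfinite(r.stress1) && r.stress1 < best.stress1) {
      best = r;
      best_idx = s;
    }
  }
  if (best_idx < 0) stop("no start produced a finite stress value");
  return List::create(
      _["X"] = best.X, _["stress1"] = best.stress1, _["a"] = best.a,
      _["b"] = best.b,
      _["trace"] = NumericVector(best.trace.begin(), best.trace.end()),
      _["iterations"] = best.iterations, _["converged"] = best.converged,
      _["start_index"] = best_idx + 1);
}
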