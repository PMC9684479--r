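#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Solve Q[P,P] z = b[P] for the current passive set. Q is symmetric
// positive semi-definite; fall back to a tiny ridge, then pinv, when the
// passive block is numerically singular (heavily correlated columns).
static vec solve_passive(const mat& Q, const vec& b, const uvec& P) {
  mat Qpp = Q.submat(P, P);
  vec bp = b.elem(P);
  vec z;
  bool ok = solve(z, Qpp, bp, solve_opts::likely_sympd + solve_opts::no_approx);
  if (!ok || !z.is_finite()) {
    double ridge = 1e-12 * trace(Qpp) / std::max<uword>(Qpp.n_rows, 1) + 1e-300;
    ok = solve(z, Qpp + ridge * eye(Qpp.n_rows, Qpp.n_cols), bp,
               solve_opts::likely_sympd + solve_opts::no_approx);
    if (!ok || !z.is_finite()) z = pinv(Qpp) * bp;
  }
  return z;
}

static uvec passive_index(const std::vector<bool>& passive) {
  uvec P(std::count(passive.begin(), passive.end(), true));
  uword k = 0;
  for (uword j = 0; j < passive.size(); ++j)
    if (passive[j]) P(k++) = j;
  return P;
}

// Non-negative least squares on the normal equations (Bro & de Jong FNNLS):
// minimise ||C x - d||^2 subject to x >= 0, given Q = C'C and b = C'd.
// Working on the normal equations lets callers amortise Q across many
// right-hand sides, which the offline ensemble computation relies on.
// [[Rcpp::export]]
Rcpp::NumericVector fnnls_cpp(const arma::mat& Q, const arma::vec& b,
                              double tol = -1.0, int maxit = -1) {
  const uword n = Q.n_cols;
  if (Q.n_rows != n || b.n_elem != n)
    Rcpp::stop("Q must be square and conformable with b");
  if (tol <= 0.0) {
    double scale = b.n_elem ? norm(b, "inf") : 1.0;
    if (scale <= 0.0) scale = 1.0;
    tol = 10.0 * datum::eps * scale * static_cast<double>(n);
  }
  if (maxit <= 0) maxit = 30 * static_cast<int>(n) + 100;

  vec x(n, fill::zeros);
  std::vector<bool> passive(n, false);
  vec w = b;  // negative gradient of 1/2 x'Qx - b'x at x = 0

  int outer = 0;
  while (outer++ < maxit) {
    double wmax = -datum::inf;
    sword jmax = -1;
    for (uword j = 0; j < n; ++j)
      if (!passive[j] && w(j) > wmax) { wmax = w(j); jmax = static_cast<sword>(j); }
    if (jmax < 0 || wmax <= tol) break;
    passive[static_cast<uword>(jmax)] = true;

    int inner = 0;
    for (;;) {
      uvec P = passive_index(passive);
      vec z = solve_passive(Q, b, P);
      if (P.n_elem == 0) break;
      if (z.min() > 0.0) {
        x.zeros();
        x.elem(P) = z;
        break;
      }
      if (inner++ > maxit) {  // numerical stall: clamp and accept
        x.zeros();
        x.elem(P) = clamp(z, 0.0, datum::inf);
        break;
      }
      // step from x towards z until the first passive coordinate hits zero
      double alpha = datum::inf;
      for (uword k = 0; k < P.n_elem; ++k) {
        if (z(k) <= 0.0) {
          double xi = x(P(k));
          double denom = xi - z(k);
          double a = denom > 0.0 ? xi / denom : 0.0;
          if (a < alpha) alpha = a;
        }
      }
      if (!std::isfinite(alpha)) alpha = 0.0;
      for (uword k = 0; k < P.n_elem; ++k) {
        uword j = P(k);
        x(j) += alpha * (z(k) - x(j));
        if (z(k) <= 0.0 && x(j) <= tol) { x(j) = 0.0; passive[j] = false; }
      }
    }
    w = b - Q * x;
  }
  return Rcpp::NumericVector(x.begin(), x.end());
}
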