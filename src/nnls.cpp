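// Active-set (Lawson-Hanson) nonnegative least squares on the normal
// equations.  Working with G = X'X (+ lambda*I) and a = X'y lets one
// Gram matrix be shared across the many right-hand sides that arise when
// the same predictor matrix is fit to every time point of an RDM movie.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static vec nnls_gram_one(const mat& G, const vec& a, double tol, int maxit) {
  const uword p = G.n_cols;
  std::vector<bool> passive(p, false);
  vec x(p, fill::zeros);
  vec grad = a;  // gradient of 0.5*||y - Xw||^2 at w = 0 is -X'y; we track a - G x

  int outer = 0;
  while (outer++ < maxit) {
    // most positive gradient among the active (zero) set
    double wmax = -datum::inf;
    sword t = -1;
    for (uword j = 0; j < p; ++j) {
      if (!passive[j] && grad(j) > wmax) { wmax = grad(j); t = (sword)j; }
    }
    if (t < 0 || wmax <= tol) break;
    passive[(uword)t] = true;

    int inner = 0;
    while (inner++ < maxit) {
      uvec idx(p);
      uword np = 0;
      for (uword j = 0; j < p; ++j) if (passive[j]) idx(np++) = j;
      idx = idx.head(np);

      mat Gs = symmatu(G.submat(idx, idx));
      vec as = a.elem(idx);
      vec z;
      bool ok = solve(z, Gs, as, solve_opts::likely_sympd + solve_opts::no_approx);
      if (!ok) z = pinv(Gs) * as;

      if (z.min() > 0) {
        x.zeros();
        x.elem(idx) = z;
        break;
      }
      // step back toward feasibility along x -> z
      double alpha = datum::inf;
      for (uword k = 0; k < np; ++k) {
        if (z(k) <= 0) {
          double xk = x(idx(k));
          double denom = xk - z(k);
          double step = denom > 0 ? xk / denom : 0.0;
          if (step < alpha) alpha = step;
        }
      }
      vec xs = x.elem(idx);
      xs += alpha * (z - xs);
      x.zeros();
      x.elem(idx) = xs;
      for (uword k = 0; k < np; ++k) {
        if (xs(k) <= tol) { passive[idx(k)] = false; x(idx(k)) = 0.0; }
      }
    }
    grad = a - G * x;
  }
  return x;
}

//' @rdname nnls_gram
//' @keywords internal
// [[Rcpp::export(name = ".nnls_gram")]]
arma::mat nnls_gram_cpp(const arma::mat& G, const arma::mat& A,
                        double tol = 1e-10, int maxit = 1000) {
  if (G.n_rows != G.n_cols) Rcpp::stop("G must be square");
  if (A.n_rows != G.n_rows) Rcpp::stop("nrow(A) must equal nrow(G)");
  mat W(A.n_rows, A.n_cols);
  for (uword j = 0; j < A.n_cols; ++j) {
    double scale = norm(A.col(j), "inf");
    double tj = tol * std::max(1.0, scale);
    W.col(j) = nnls_gram_one(G, A.col(j), tj, maxit);
  }
  return W;
}
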