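// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

// Moving-least-squares projection. For each point a weighted PCA plane is
// fitted to its k-neighbourhood, a bivariate polynomial height field is fitted
// over that plane (Gaussian distance weights), and the point is moved to the
// fitted surface along the plane normal. The full bivariate quadratic basis is
// rotation-closed, so the projection does not depend on the in-plane frame.

// [[Rcpp::export]]
Rcpp::List mls_smooth_cpp(const arma::mat& P, const Rcpp::IntegerMatrix& nbr,
                          const Rcpp::NumericMatrix& nbd, int order,
                          double bandwidth) {
  const int n = P.n_rows;
  const int k = nbr.ncol();
  arma::mat out(n, 3);
  int fallback_plane = 0;

  const int m = (order >= 2) ? 6 : 3;  // 1,u,v[,u2,uv,v2]
  arma::mat B(k + 1, m);
  arma::vec hgt(k + 1), w(k + 1);
  arma::mat Q(k + 1, 3);

  for (int i = 0; i < n; ++i) {
    Q.row(0) = P.row(i);
    double dsum = 0.0;
    for (int j = 0; j < k; ++j) {
      Q.row(j + 1) = P.row(nbr(i, j) - 1);
      dsum += nbd(i, j);
    }
    double h = bandwidth * (dsum / k);
    if (h <= 0) h = 1.0;
    w[0] = 1.0;
    for (int j = 0; j < k; ++j) {
      double d = nbd(i, j);
      w[j + 1] = std::exp(-(d * d) / (h * h));
    }

    // Weighted PCA frame.
    arma::rowvec c = (w.t() * Q) / arma::accu(w);
    arma::mat D = Q.each_row() - c;
    arma::mat C = D.t() * (D.each_col() % w);
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, C);
    arma::vec nrm = evec.col(0);
    arma::vec e1 = evec.col(2);
    arma::vec e2 = evec.col(1);

    double maxd = nbd(i, k - 1);
    bool degenerate = !(eval[1] > 1e-12 * std::max(eval[2], 1e-300));

    arma::vec u = D * e1, v = D * e2;
    hgt = D * nrm;
    double u0 = arma::dot(P.row(i).t() - c.t(), e1);
    double v0 = arma::dot(P.row(i).t() - c.t(), e2);
    double h0 = arma::dot(P.row(i).t() - c.t(), nrm);

    double f0 = 0.0;
    bool ok = false;
    if (!degenerate) {
      B.col(0).ones();
      B.col(1) = u;
      B.col(2) = v;
      if (m == 6) {
        B.col(3) = u % u;
        B.col(4) = u % v;
        B.col(5) = v % v;
      }
      arma::mat Bw = B.each_col() % w;
      arma::mat A = B.t() * Bw;
      arma::vec rhs = Bw.t() * hgt;
      arma::vec coef;
      ok = arma::solve(coef, A, rhs, arma::solve_opts::no_approx);
      if (ok) {
        f0 = coef[0] + coef[1] * u0 + coef[2] * v0;
        if (m == 6) f0 += coef[3] * u0 * u0 + coef[4] * u0 * v0 + coef[5] * v0 * v0;
        // Guard: a wild extrapolation falls back to the plane.
        if (!std::isfinite(f0) || std::fabs(f0 - h0) > maxd) ok = false;
      }
    }
    if (!ok) {
      ++fallback_plane;
      f0 = 0.0;  // best-fit-plane projection
    }
    arma::vec np = c.t() + u0 * e1 + v0 * e2 + f0 * nrm;
    out.row(i) = np.t();
  }
  return Rcpp::List::create(Rcpp::_["points"] = out,
                            Rcpp::_["n_fallback"] = fallback_plane);
}

// PCA normal estimation: covariance about the query point itself
// (C = X'X/k with rows x_i - x0), smallest-eigenvalue eigenvector.
// [[Rcpp::export]]
arma::mat pca_normals_cpp(const arma::mat& P, const Rcpp::IntegerMatrix& nbr) {
  const int n = P.n_rows;
  const int k = nbr.ncol();
  arma::mat N(n, 3);
  arma::mat X(k, 3);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < k; ++j) {
      X.row(j) = P.row(nbr(i, j) - 1) - P.row(i);
    }
    arma::mat C = X.t() * X / k;
    double tr = arma::trace(C);
    if (!(tr > 1e-24)) {
      Rcpp::stop("coincident neighbourhood at point %d: zero covariance", i + 1);
    }
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, C);
    arma::vec v = evec.col(0);
    N.row(i) = (v / arma::norm(v)).t();
  }
  return N;
}
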