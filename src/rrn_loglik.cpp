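// Marginal Gaussian likelihood for the random-regression mixed model
//
//   y = X beta + Z_i b_i + a_{year} + c_{month} + e
//
// with b_i = (intercept, slope) ~ N(0, G), year effects AR1-correlated,
// month effects iid, and iid residuals.  The marginal covariance is
//
//   V = B + U D U'            B  = blockdiag_i( Z_i G Z_i' + Vresid I )
//                             U  = [year indicators | month indicators]
//                             D  = blockdiag( Vyear * R_ar1, Vmonth * I )
//
// so log|V| and quadratic forms are obtained from per-individual Cholesky
// factors plus a q x q Woodbury correction (q = n_years + n_months), never
// from an n x n factorization.  Rows MUST arrive sorted by individual.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// theta layout (natural scale):
//   0 Vint, 1 Vslope, 2 Cov, 3 Vyear, 4 rho_year, 5 Vmonth, 6 Vresid
// year_idx / month_idx are 0-based level indices, or all -1 when the
// component is absent; year_vals holds the numeric year of each year level
// so AR1 correlation decays with the true year gap rho^|t - s|.

// [[Rcpp::export]]
Rcpp::List rrn_objective_cpp(const arma::vec& y,
                             const arma::mat& X,
                             const arma::ivec& id,
                             const arma::vec& x,
                             const arma::ivec& year_idx,
                             const arma::ivec& month_idx,
                             const arma::vec& year_vals,
                             const arma::vec& theta,
                             const bool profile_beta,
                             const arma::vec& beta_in) {
  const uword n = y.n_elem;
  const uword p = X.n_cols;

  const double Vint = theta(0), Vslope = theta(1), Cov = theta(2);
  const double Vyear = theta(3), rho = theta(4);
  const double Vmonth = theta(5), Vresid = theta(6);

  Rcpp::List fail = Rcpp::List::create(Rcpp::Named("ok") = false,
                                       Rcpp::Named("nll") = 1e10);
  if (!(Vresid > 0.0) || !std::isfinite(Vresid)) return fail;

  const bool use_year = year_idx.n_elem == n && year_idx.max() >= 0;
  const bool use_month = month_idx.n_elem == n && month_idx.max() >= 0;
  const uword qy = use_year ? (uword)(year_idx.max() + 1) : 0;
  const uword qm = use_month ? (uword)(month_idx.max() + 1) : 0;
  const uword q = qy + qm;

  // Cholesky factor of D; the Woodbury step uses the stabilized form
  // M = I + Ld' (U'B^{-1}U) Ld  with  D = Ld Ld', which stays
  // well-conditioned as variance components shrink to the boundary.
  mat Ld;
  if (q > 0) {
    mat D(q, q, fill::zeros);
    if (use_year) {
      if (!(Vyear > 0.0) || std::abs(rho) >= 1.0) return fail;
      for (uword a = 0; a < qy; ++a)
        for (uword b = 0; b < qy; ++b)
          D(a, b) = Vyear * std::pow(rho, std::abs(year_vals(a) - year_vals(b)));
    }
    if (use_month) {
      if (!(Vmonth > 0.0)) return fail;
      for (uword a = 0; a < qm; ++a) D(qy + a, qy + a) = Vmonth;
    }
    if (!chol(Ld, D, "lower")) return fail;
  }

  const mat G = { { Vint, Cov }, { Cov, Vslope } };

  // accumulate crossproducts of A = [y, X, U] against B^{-1}
  const uword r = 1 + p + q;
  mat S(r, r, fill::zeros);
  double logdetB = 0.0;

  uword start = 0;
  while (start < n) {
    uword end = start;
    while (end + 1 < n && id(end + 1) == id(start)) ++end;
    const uword ni = end - start + 1;

    mat Zi(ni, 2);
    Zi.col(0).ones();
    Zi.col(1) = x.subvec(start, end);

    mat Bi = Zi * G * Zi.t();
    Bi.diag() += Vresid;

    mat Lb;
    if (!chol(Lb, Bi, "lower")) return fail;
    logdetB += 2.0 * accu(log(Lb.diag()));

    mat Ai(ni, r, fill::zeros);
    Ai.col(0) = y.subvec(start, end);
    if (p > 0) Ai.cols(1, p) = X.rows(start, end);
    for (uword k = 0; k < ni; ++k) {
      if (use_year) Ai(k, 1 + p + (uword)year_idx(start + k)) = 1.0;
      if (use_month) Ai(k, 1 + p + qy + (uword)month_idx(start + k)) = 1.0;
    }

    mat Ci = solve(trimatl(Lb), Ai, solve_opts::no_approx);  // L^{-1} A
    S += Ci.t() * Ci;                  // A' B^{-1} A
    start = end + 1;
  }

  double logdetV = logdetB;

  // Woodbury: a'V^{-1}b = a'B^{-1}b - (Ld'U'B^{-1}a)' M^{-1} (Ld'U'B^{-1}b)
  // and log|V| = log|B| + log|M|, with M = I + Ld'(U'B^{-1}U)Ld.
  mat S_yx = S.submat(0, 0, p, p);     // [y X]' B^{-1} [y X]
  if (q > 0) {
    mat M = eye(q, q) +
      Ld.t() * S.submat(1 + p, 1 + p, r - 1, r - 1) * Ld;
    M = 0.5 * (M + M.t());
    mat Lm;
    if (!chol(Lm, M, "lower")) return fail;
    logdetV += 2.0 * accu(log(Lm.diag()));
    mat Uyx = Ld.t() * S.submat(1 + p, 0, r - 1, p);  // Ld'U'B^{-1}[y X]
    mat W = solve(trimatl(Lm), Uyx, solve_opts::no_approx);
    S_yx -= W.t() * W;
  }

  const double yy = S_yx(0, 0);
  vec beta;
  double quad;
  mat XtViX;
  if (p > 0) {
    XtViX = S_yx.submat(1, 1, p, p);
    vec Xty = S_yx.submat(1, 0, p, 0);
    if (profile_beta) {
      if (!solve(beta, XtViX, Xty, solve_opts::no_approx)) return fail;
      quad = yy - dot(beta, Xty);
    } else {
      beta = beta_in;
      quad = yy - 2.0 * dot(beta, Xty) +
        as_scalar(beta.t() * XtViX * beta);
    }
  } else {
    beta = vec();
    XtViX = mat();
    quad = yy;
  }

  const double nll = 0.5 * (logdetV + quad + (double)n * std::log(2.0 * M_PI));
  if (!std::isfinite(nll)) return fail;

  return Rcpp::List::create(
    Rcpp::Named("ok") = true,
    Rcpp::Named("nll") = nll,
    Rcpp::Named("beta") = beta,
    Rcpp::Named("XtViX") = XtViX,
    Rcpp::Named("logdetV") = logdetV,
    Rcpp::Named("quad") = quad);
}
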