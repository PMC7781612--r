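// Penalized and support-constrained Gaussian graphical model solvers.
//
// agl_solve: block coordinate descent for
//   min_{Phi > 0} -log det Phi + tr(S Phi) + sum_{j<k} Lambda_jk |Phi_jk|
// with an arbitrary symmetric elementwise penalty matrix Lambda (diagonal
// unpenalized).  Each column update is a lasso solved by coordinate descent
// on the working covariance W; convergence is certified by the duality gap
//   gap = tr(S Phi) - p + sum_{j!=k} Lambda_jk |Phi_jk|
// which is zero at the optimum when W = Phi^{-1} is dual feasible.
//
// ggm_refit: unpenalized MLE of the precision constrained to a fixed support
// graph (regression/IPF algorithm of Hastie, Tibshirani & Friedman, Alg 17.1):
// at convergence Phi^{-1} matches the input covariance on support+diagonal and
// Phi is exactly zero off support.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// coordinate descent for min_b 0.5 b'Vb - s'b + sum_k lam_k |b_k|
static void lasso_cd(const mat &V, const vec &s, const vec &lam, vec &b,
                     const int max_iter, const double tol) {
  const uword p = b.n_elem;
  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword k = 0; k < p; ++k) {
      const double bk_old = b(k);
      // gradient excluding the k-th term
      const double g = s(k) - dot(V.col(k), b) + V(k, k) * bk_old;
      double bk = 0.0;
      if (g > lam(k)) bk = (g - lam(k)) / V(k, k);
      else if (g < -lam(k)) bk = (g + lam(k)) / V(k, k);
      b(k) = bk;
      const double d = std::fabs(bk - bk_old);
      if (d > delta) delta = d;
    }
    if (delta < tol) break;
  }
}

static mat precision_from_working(const mat &W, const mat &B) {
  const uword p = W.n_cols;
  mat Phi(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    uvec idx = find(regspace<uvec>(0, p - 1) != j);
    const vec bi = B.col(j);   // reduced (p-1)-vector ordered by idx
    const vec w12 = W.submat(idx, uvec{j});
    const double phi_jj = 1.0 / (W(j, j) - dot(w12, bi));
    Phi(j, j) = phi_jj;
    Phi.submat(idx, uvec{j}) = -bi * phi_jj;
  }
  return 0.5 * (Phi + Phi.t());
}

// [[Rcpp::export]]
Rcpp::List agl_solve(const arma::mat &S, const arma::mat &Lambda,
                     const double tol, const int max_iter) {
  const uword p = S.n_cols;
  mat W = S;                 // working covariance; diagonal unpenalized
  mat B(p - 1 > 0 ? p - 1 : 1, p, fill::zeros);
  std::vector<double> obj_trace;
  double gap = datum::inf;
  bool converged = false;
  int iter = 0;

  const uvec all = regspace<uvec>(0, p - 1);
  for (iter = 1; iter <= max_iter; ++iter) {
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      mat V = W.submat(idx, idx);
      vec s12 = S.submat(idx, uvec{j});
      vec lam = Lambda.submat(idx, uvec{j});
      vec b = B.col(j);
      lasso_cd(V, s12, lam, b, 200, 1e-10);
      B.col(j) = b;
      vec w12 = V * b;
      W.submat(idx, uvec{j}) = w12;
      W.submat(uvec{j}, idx) = w12.t();
    }
    mat Phi = precision_from_working(W, B);
    // objective (guard: Phi must be PD along the trajectory)
    double ld, sign;
    log_det(ld, sign, Phi);
    double pen = 0.0;
    for (uword a = 0; a < p; ++a)
      for (uword bcol = a + 1; bcol < p; ++bcol)
        pen += Lambda(a, bcol) * std::fabs(Phi(a, bcol));
    obj_trace.push_back(-ld + accu(S % Phi) + 2.0 * pen);
    gap = accu(S % Phi) - static_cast<double>(p) + 2.0 * pen;
    if (std::fabs(gap) < tol) { converged = true; break; }
  }

  mat Phi = precision_from_working(W, B);
  return Rcpp::List::create(
      Rcpp::Named("precision") = Phi, Rcpp::Named("working_cov") = W,
      Rcpp::Named("gap") = gap, Rcpp::Named("iterations") = iter,
      Rcpp::Named("converged") = converged,
      Rcpp::Named("objective_trace") = obj_trace);
}

// [[Rcpp::export]]
Rcpp::List ggm_refit_cpp(const arma::mat &Sd, const arma::umat &adj,
                         const double tol, const int max_iter) {
  const uword p = Sd.n_cols;
  mat W = Sd;
  mat B(p > 1 ? p - 1 : 1, p, fill::zeros);
  const uvec all = regspace<uvec>(0, p - 1);
  bool converged = false;

  for (int it = 0; it < max_iter; ++it) {
    double delta = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx = find(all != j);
      // neighbour positions within idx
      uvec nb_local = find(adj.submat(idx, uvec{j}) != 0);
      vec b(p - 1, fill::zeros);
      if (nb_local.n_elem > 0) {
        mat V = W.submat(idx, idx);
        mat Vnb = V.submat(nb_local, nb_local);
        vec snb = Sd.submat(idx, uvec{j});
        vec bnb;
        const bool ok = solve(bnb, Vnb, snb.elem(nb_local),
                              solve_opts::no_approx);
        if (!ok) Rcpp::stop("support-constrained refit: singular system");
        b.elem(nb_local) = bnb;
        vec w12 = V * b;
        delta = std::max(delta,
                         abs(w12 - W.submat(idx, uvec{j})).max());
        W.submat(idx, uvec{j}) = w12;
        W.submat(uvec{j}, idx) = w12.t();
      } else {
        delta = std::max(delta, abs(W.submat(idx, uvec{j})).max());
        W.submat(idx, uvec{j}).zeros();
        W.submat(uvec{j}, idx).zeros();
      }
      B.col(j) = b;
    }
    if (delta < tol) { converged = true; break; }
  }

  mat Phi = precision_from_working(W, B);
  // enforce exact zeros off support
  for (uword a = 0; a < p; ++a)
    for (uword b2 = 0; b2 < p; ++b2)
      if (a != b2 && adj(a, b2) == 0) Phi(a, b2) = 0.0;
  return Rcpp::List::create(Rcpp::Named("precision") = Phi,
                            Rcpp::Named("fitted_cov") = W,
                            Rcpp::Named("converged") = converged);
}
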