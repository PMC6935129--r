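// EM for Gaussian mixtures with constrained covariance structures.
// Models: EII (lambda I), VII (lambda_k I), EEE (shared Sigma),
// VEV (lambda_k D_k A D_k', det(A) = 1), VVV (free Sigma_k).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Cholesky (lower) with eigenvalue flooring on failure / tiny pivots
static bool safe_chol_lower(const mat& S, double floor_val, mat& L) {
  mat Ssym = 0.5 * (S + S.t());
  bool ok = chol(L, Ssym, "lower");
  if (ok) {
    vec dg = L.diag();
    if (dg.min() * dg.min() >= floor_val) return true;
  }
  vec eval;
  mat evec;
  if (!eig_sym(eval, evec, Ssym)) return false;
  eval = clamp(eval, floor_val, datum::inf);
  Ssym = evec * diagmat(eval) * evec.t();
  return chol(L, 0.5 * (Ssym + Ssym.t()), "lower");
}

// [[Rcpp::export(name = ".gmm_em_cpp")]]
Rcpp::List gmm_em_cpp(const arma::mat& x, arma::mat z,
                      const std::string& model, double tol, int max_iter,
                      double floor_val, double shape_tol, int shape_iter) {
  const uword n = x.n_rows, d = x.n_cols;
  const uword k = z.n_cols;
  const double cst = d * std::log(2.0 * datum::pi);

  vec lambda;          // EII (1), VII/VEV (k)
  vec shape;           // VEV (d)
  cube orient;         // VEV (d x d x k)
  cube Sigma;          // VVV (d x d x k), EEE in slice 0
  cube Lchol;          // cholesky factors matching Sigma
  vec logdet(k);
  rowvec w(k);
  mat means(k, d);

  std::vector<double> trace;
  trace.reserve(max_iter);
  double ll_old = -datum::inf;
  std::string fail;

  mat ld(n, k);
  for (int iter = 0; iter < max_iter; ++iter) {
    rowvec nk = sum(z, 0);
    if (nk.min() < 2.0) {
      fail = "degenerate component (mass < 2 cells)";
      break;
    }
    w = nk / double(n);
    means = z.t() * x;
    means.each_col() /= nk.t();

    // weighted scatter matrices
    cube W(d, d, k);
    for (uword j = 0; j < k; ++j) {
      mat xc = x.each_row() - means.row(j);
      W.slice(j) = xc.t() * (xc.each_col() % z.col(j));
    }

    // covariance M-step
    if (model == "EII") {
      double tr = 0.0;
      for (uword j = 0; j < k; ++j) tr += arma::trace(W.slice(j));
      lambda = vec(1);
      lambda(0) = std::max(tr / (double(n) * d), floor_val);
    } else if (model == "VII") {
      lambda.set_size(k);
      for (uword j = 0; j < k; ++j)
        lambda(j) = std::max(arma::trace(W.slice(j)) / (nk(j) * d),
                             floor_val);
    } else if (model == "EEE") {
      mat S(d, d, fill::zeros);
      for (uword j = 0; j < k; ++j) S += W.slice(j);
      S /= double(n);
      Sigma.set_size(d, d, 1);
      Lchol.set_size(d, d, 1);
      Sigma.slice(0) = S;
      if (!safe_chol_lower(S, floor_val, Lchol.slice(0))) {
        fail = "covariance factorization failed";
        break;
      }
      logdet.fill(2.0 * accu(log(Lchol.slice(0).diag())));
    } else if (model == "VEV") {
      mat omega(d, k);
      orient.set_size(d, d, k);
      bool eig_ok = true;
      for (uword j = 0; j < k; ++j) {
        vec eval;
        mat evec;
        if (!eig_sym(eval, evec, 0.5 * (W.slice(j) + W.slice(j).t()))) {
          eig_ok = false;
          break;
        }
        omega.col(j) = clamp(eval, floor_val * 1e-2, datum::inf);
        orient.slice(j) = evec;
      }
      if (!eig_ok) {
        fail = "covariance factorization failed";
        break;
      }
      shape = vec(d, fill::ones);
      lambda.set_size(k);
      for (uword j = 0; j < k; ++j)
        lambda(j) = std::max(accu(omega.col(j)) / (nk(j) * d), floor_val);
      // flip-flop between component volumes and the shared shape
      for (int it = 0; it < shape_iter; ++it) {
        vec b(d, fill::zeros);
        for (uword j = 0; j < k; ++j) b += omega.col(j) / lambda(j);
        vec shape_new = b / std::exp(accu(log(b)) / double(d));
        vec lam_new(k);
        for (uword j = 0; j < k; ++j)
          lam_new(j) = std::max(accu(omega.col(j) / shape_new) /
                                    (nk(j) * d),
                                floor_val);
        double delta = std::max(
            abs((shape_new - shape) / (abs(shape) + 1e-12)).max(),
            abs((lam_new - lambda) / (lambda + 1e-12)).max());
        shape = shape_new;
        lambda = lam_new;
        if (delta < shape_tol) break;
      }
    } else {  // VVV
      Sigma.set_size(d, d, k);
      Lchol.set_size(d, d, k);
      bool ok = true;
      for (uword j = 0; j < k; ++j) {
        Sigma.slice(j) = W.slice(j) / nk(j);
        if (!safe_chol_lower(Sigma.slice(j), floor_val, Lchol.slice(j))) {
          ok = false;
          break;
        }
        logdet(j) = 2.0 * accu(log(Lchol.slice(j).diag()));
      }
      if (!ok) {
        fail = "covariance factorization failed";
        break;
      }
    }

    // E-step log densities
    for (uword j = 0; j < k; ++j) {
      mat xc = x.each_row() - means.row(j);
      vec maha;
      double ldet;
      if (model == "EII" || model == "VII") {
        double lam = (model == "EII") ? lambda(0) : lambda(j);
        maha = sum(square(xc), 1) / lam;
        ldet = d * std::log(lam);
      } else if (model == "EEE") {
        mat y = solve(trimatl(Lchol.slice(0)), xc.t());
        maha = sum(square(y), 0).t();
        ldet = logdet(0);
      } else if (model == "VEV") {
        mat proj = square(xc * orient.slice(j));
        rowvec sc = (lambda(j) * shape).t();
        proj.each_row() /= sc;
        maha = sum(proj, 1);
        ldet = d * std::log(lambda(j)) + accu(log(shape));
      } else {
        mat y = solve(trimatl(Lchol.slice(j)), xc.t());
        maha = sum(square(y), 0).t();
        ldet = logdet(j);
      }
      ld.col(j) = -0.5 * (cst + ldet + maha);
    }
    ld.each_row() += log(w);
    vec mx = max(ld, 1);
    vec lse = mx + log(sum(exp(ld.each_col() - mx), 1));
    double ll = accu(lse);
    if (!std::isfinite(ll)) {
      fail = "non-finite log-likelihood";
      break;
    }
    if (ll < ll_old - 1e-6 * (1.0 + std::fabs(ll_old))) {
      fail = "loglik_decreased";
      break;
    }
    trace.push_back(ll);
    z = exp(ld.each_col() - lse);
    bool done = (ll - ll_old) < tol;
    ll_old = ll;
    if (done) break;
  }

  Rcpp::List covp;
  if (model == "EII") {
    covp = Rcpp::List::create(Rcpp::Named("lambda") = lambda(0));
  } else if (model == "VII") {
    covp = Rcpp::List::create(Rcpp::Named("lambda") = lambda);
  } else if (model == "EEE") {
    covp = Rcpp::List::create(Rcpp::Named("Sigma") = Sigma.slice(0),
                              Rcpp::Named("L") = Lchol.slice(0),
                              Rcpp::Named("logdet") = logdet(0));
  } else if (model == "VEV") {
    Rcpp::List D(k);
    for (uword j = 0; j < k; ++j) D[j] = orient.slice(j);
    covp = Rcpp::List::create(Rcpp::Named("lambda") = lambda,
                              Rcpp::Named("shape") = shape,
                              Rcpp::Named("orientation") = D);
  } else {
    Rcpp::List S(k), L(k);
    vec lds(k);
    for (uword j = 0; j < k; ++j) {
      S[j] = Sigma.slice(j);
      L[j] = Lchol.slice(j);
      lds(j) = logdet(j);
    }
    covp = Rcpp::List::create(Rcpp::Named("Sigma") = S,
                              Rcpp::Named("L") = L,
                              Rcpp::Named("logdet") = lds);
  }

  return Rcpp::List::create(
      Rcpp::Named("failed") = !fail.empty(),
      Rcpp::Named("reason") = fail,
      Rcpp::Named("loglik") = ll_old,
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("weights") = w.t(),
      Rcpp::Named("means") = means,
      Rcpp::Named("covp") = covp,
      Rcpp::Named("responsibilities") = z,
      Rcpp::Named("iterations") = int(trace.size()));
}
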