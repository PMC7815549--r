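// Per-family Gaussian likelihood accumulation for pedigree variance-
// component models.  Each family contributes an independent multivariate-
// normal block; the kernel accumulates the sufficient statistics for the
// profile likelihood of the fixed effects (GLS) across families.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// fams: list of family blocks, each a list with
//   K     list of individual-level relationship matrices, one per component
//         (unique-environment component = identity over individuals)
//   ind   1-based individual index of each observation
//   trait 1-based trait index of each observation (all 1 for univariate)
//   X     fixed-effect design (nobs x p)
//   y     observation vector (nobs)
// C: list of trait covariance matrices per component (t x t); for the
//    univariate model these are 1x1 variances.
// Covariance entry between observations o, q:
//   V(o,q) = sum_c C_c(trait_o, trait_q) * K_c(ind_o, ind_q)
// [[Rcpp::export(name = ".ll_terms_cpp")]]
List ll_terms_cpp(List fams, List C) {
  const int ncomp = C.size();
  std::vector<arma::mat> Cm(ncomp);
  for (int c = 0; c < ncomp; ++c) Cm[c] = as<arma::mat>(C[c]);

  int p = -1, ntot = 0;
  arma::mat XtX;
  arma::vec Xty;
  double yty = 0.0, logdet = 0.0;
  bool ok = true;

  const int nfam = fams.size();
  for (int f = 0; f < nfam && ok; ++f) {
    List fam = fams[f];
    List K = fam["K"];
    arma::uvec ind = as<arma::uvec>(fam["ind"]) - 1;
    arma::uvec trait = as<arma::uvec>(fam["trait"]) - 1;
    arma::mat X = as<arma::mat>(fam["X"]);
    arma::vec y = as<arma::vec>(fam["y"]);
    const int n = y.n_elem;
    if (p < 0) {
      p = X.n_cols;
      XtX.zeros(p, p);
      Xty.zeros(p);
    }
    arma::mat V(n, n, arma::fill::zeros);
    for (int c = 0; c < ncomp; ++c) {
      arma::mat Kc = as<arma::mat>(K[c]);
      for (int o = 0; o < n; ++o)
        for (int q = 0; q <= o; ++q) {
          double v = Cm[c](trait[o], trait[q]) * Kc(ind[o], ind[q]);
          V(o, q) += v;
          if (q < o) V(q, o) += v;
        }
    }
    arma::mat L;
    if (!arma::chol(L, V, "lower")) {
      V.diag() += 1e-10;                       // numerical jitter
      if (!arma::chol(L, V, "lower")) { ok = false; break; }
    }
    for (int o = 0; o < n; ++o) logdet += 2.0 * std::log(L(o, o));
    arma::mat Xs = arma::solve(arma::trimatl(L), X);
    arma::vec ys = arma::solve(arma::trimatl(L), y);
    XtX += Xs.t() * Xs;
    Xty += Xs.t() * ys;
    yty += arma::dot(ys, ys);
    ntot += n;
  }
  return List::create(_["ok"] = ok, _["n"] = ntot, _["logdet"] = logdet,
                      _["XtX"] = XtX, _["Xty"] = Xty, _["yty"] = yty);
}

// Gradient of the negative log-likelihood with respect to the symmetric
// entries of the per-component trait covariance matrices, at fixed beta
// (exact for the profiled objective at the GLS beta, by the envelope
// theorem).  Entry order: per component, lower triangle column-major
// ((1,1), (2,1), (2,2) for two traits; (1,1) for one).
// [[Rcpp::export(name = ".ll_grad_cpp")]]
arma::vec ll_grad_cpp(List fams, List C, arma::vec beta) {
  const int ncomp = C.size();
  const int t = as<arma::mat>(C[0]).n_rows;
  const int perC = t * (t + 1) / 2;
  std::vector<arma::mat> Cm(ncomp);
  for (int c = 0; c < ncomp; ++c) Cm[c] = as<arma::mat>(C[c]);
  arma::vec grad(ncomp * perC, arma::fill::zeros);

  const int nfam = fams.size();
  for (int f = 0; f < nfam; ++f) {
    List fam = fams[f];
    List K = fam["K"];
    arma::uvec ind = as<arma::uvec>(fam["ind"]) - 1;
    arma::uvec trait = as<arma::uvec>(fam["trait"]) - 1;
    arma::mat X = as<arma::mat>(fam["X"]);
    arma::vec y = as<arma::vec>(fam["y"]);
    const int n = y.n_elem;
    arma::mat V(n, n, arma::fill::zeros);
    std::vector<arma::mat> Ksub(ncomp);
    for (int c = 0; c < ncomp; ++c) {
      arma::mat Kc = as<arma::mat>(K[c]);
      Ksub[c].set_size(n, n);
      for (int o = 0; o < n; ++o)
        for (int q = 0; q < n; ++q)
          Ksub[c](o, q) = Kc(ind[o], ind[q]);
      for (int o = 0; o < n; ++o)
        for (int q = 0; q <= o; ++q) {
          double v = Cm[c](trait[o], trait[q]) * Ksub[c](o, q);
          V(o, q) += v;
          if (q < o) V(q, o) += v;
        }
    }
    arma::mat Vinv;
    if (!arma::inv_sympd(Vinv, V)) {
      V.diag() += 1e-10;
      Vinv = arma::inv_sympd(V);
    }
    arma::vec r = y - X * beta;
    arma::vec a = Vinv * r;
    int g = 0;
    for (int c = 0; c < ncomp; ++c) {
      for (int v = 0; v < t; ++v)
        for (int u = v; u < t; ++u) {
          double tr = 0.0, quad = 0.0;
          for (int o = 0; o < n; ++o)
            for (int q = 0; q < n; ++q) {
              double ok = ((int)trait[o] == u && (int)trait[q] == v) ? 1.0 : 0.0;
              if (u != v && (int)trait[o] == v && (int)trait[q] == u) ok += 1.0;
              if (ok == 0.0) continue;
              double dv = ok * Ksub[c](o, q);
              tr += Vinv(o, q) * dv;
              quad += a[o] * dv * a[q];
            }
          grad[g++] += 0.5 * (tr - quad);
        }
    }
  }
  return grad;
}
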