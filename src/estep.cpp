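// E-step routines for the switching accumulator models.
//
// Per trial: (1) forward-backward over the discrete chain, conditioning on
// the current continuous-latent mode (discrete "emissions" are the
// state-specific Gaussian dynamics densities; transitions out of the
// accumulation state follow the softmax boundary rule, movement states are
// absorbing); (2) Newton ascent to the mode of the continuous-latent
// posterior given the discrete marginals (the objective is concave:
// Gaussian dynamics + log-softplus Poisson emissions + log-softmax
// transition terms), with the Laplace covariance blocks extracted from the
// banded precision.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

static inline double softplus_c(double x) {
  if (x > 30.0) return x;
  if (x < -30.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double log_softplus_c(double x) {
  if (x > 30.0) return std::log(x);
  if (x < -30.0) return x;  // softplus ~ e^x
  return std::log(std::log1p(std::exp(x)));
}
static inline double sigmoid_c(double x) {
  if (x > 0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}
static inline double logsumexp2(double a, double b) {
  double m = std::max(a, b);
  if (m == -datum::inf) return m;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// emission log-likelihood for one time bin
static double emis_ll_row(const rowvec& yrow, const rowvec& eta, double dt) {
  double ll = 0.0;
  for (uword n = 0; n < yrow.n_elem; ++n) {
    double lam = softplus_c(eta[n]) * dt;
    double llam = log_softplus_c(eta[n]) + std::log(dt);
    ll += yrow[n] * llam - lam - std::lgamma(yrow[n] + 1.0);
  }
  return ll;
}

// gradient and curvature of the emission term w.r.t. eta (h <= 0: concave)
static void emis_grad_hess_row(const rowvec& yrow, const rowvec& eta,
                               double dt, rowvec& g, rowvec& h) {
  for (uword n = 0; n < yrow.n_elem; ++n) {
    double e = eta[n];
    double f = softplus_c(e);
    double s = sigmoid_c(e);
    double fp = s;
    double fpp = s * (1.0 - s);
    double ratio = (e < -30.0) ? 1.0 : fp / f;
    double ratio2 = (e < -30.0) ? 0.0 : (fpp * f - fp * fp) / (f * f);
    g[n] = yrow[n] * ratio - fp * dt;
    h[n] = yrow[n] * ratio2 - fpp * dt;
  }
}

struct TrialPack {
  mat y;         // T x N
  mat Vu;        // D x K
  cube A;        // D x D x K
  cube Qi;       // D x D x K
  vec ldQ;       // K
  mat G;         // K x D  (gamma * R)
  mat g0;        // T x K  (gamma * effective r for the transition into step t)
  mat C;         // N x D
  double d;
  double dt;
};

// out(t,k) = log N(x_t | A_k x_{t-1} + Vu_k, Q_k), x_{-1} = 0
static mat dyn_loglik(const TrialPack& P, const mat& X) {
  uword T = P.y.n_rows, K = P.ldQ.n_elem, D = X.n_cols;
  mat out(T, K);
  for (uword t = 0; t < T; ++t) {
    vec xt = X.row(t).t();
    vec xp = (t == 0) ? vec(D, fill::zeros) : vec(X.row(t - 1).t());
    for (uword k = 0; k < K; ++k) {
      vec r = xt - P.A.slice(k) * xp - P.Vu.col(k);
      out(t, k) = -0.5 * (dot(r, P.Qi.slice(k) * r) + P.ldQ[k] + D * LOG2PI);
    }
  }
  return out;
}

static rowvec log_softmax_row(const rowvec& v) {
  double m = v.max();
  rowvec e = exp(v - m);
  return v - m - std::log(accu(e));
}

// forward-backward; state 0 = accumulation, others absorbing movement
static void forward_backward(const TrialPack& P, const mat& X,
                             mat& q, mat& xi, double& logZ) {
  uword T = P.y.n_rows, K = P.ldQ.n_elem;
  mat dll = dyn_loglik(P, X);
  mat ltr(T, K);                       // log p(z_t = k | z_{t-1} = acc)
  ltr.row(0) = log_softmax_row(P.g0.row(0));       // prior from x_0 = 0
  for (uword t = 1; t < T; ++t)
    ltr.row(t) = log_softmax_row((P.G * X.row(t - 1).t()).t() + P.g0.row(t));

  mat la(T, K);
  la.row(0) = ltr.row(0) + dll.row(0);
  for (uword t = 1; t < T; ++t) {
    for (uword k = 0; k < K; ++k) {
      double from_acc = la(t - 1, 0) + ltr(t, k);
      double v = (k == 0) ? from_acc : logsumexp2(from_acc, la(t - 1, k));
      la(t, k) = v + dll(t, k);
    }
  }
  rowvec last = la.row(T - 1);
  double m = last.max();
  logZ = m + std::log(accu(exp(last - m)));

  mat lb(T, K, fill::zeros);
  for (uword t = T - 1; t > 0; --t) {
    rowvec v = ltr.row(t) + dll.row(t) + lb.row(t);
    double mm = v.max();
    lb(t - 1, 0) = mm + std::log(accu(exp(v - mm)));
    for (uword j = 1; j < K; ++j)
      lb(t - 1, j) = dll(t, j) + lb(t, j);
  }
  q = exp(la + lb - logZ);
  q.each_col() /= sum(q, 1);           // guard numeric drift
  xi.zeros(T, K);
  for (uword t = 1; t < T; ++t)
    for (uword k = 0; k < K; ++k)
      xi(t, k) = std::exp(la(t - 1, 0) + ltr(t, k) + dll(t, k) +
                          lb(t, k) - logZ);
}

// objective of the continuous E-step at X given q, xi
static double cont_objective(const TrialPack& P, const mat& X,
                             const mat& q, const mat& xi) {
  uword T = P.y.n_rows;
  mat dll = dyn_loglik(P, X);
  double J = accu(q % dll);
  for (uword t = 0; t < T; ++t) {
    rowvec eta = X.row(t) * P.C.t() + P.d;
    J += emis_ll_row(P.y.row(t), eta, P.dt);
  }
  for (uword t = 1; t < T; ++t) {
    if (accu(xi.row(t)) < 1e-12) continue;
    rowvec ls = log_softmax_row((P.G * X.row(t - 1).t()).t() + P.g0.row(t));
    J += dot(xi.row(t), ls);
  }
  return J;
}

// gradient and precision (negative Hessian) of the objective at X
static void build_grad_prec(const TrialPack& P, const mat& q, const mat& xi,
                            const mat& X, vec& grad, mat& H) {
  uword T = P.y.n_rows, K = P.ldQ.n_elem, D = X.n_cols;
  uword dim = T * D;
  grad.zeros(dim);
  H.zeros(dim, dim);
  for (uword t = 0; t < T; ++t) {
    vec xt = X.row(t).t();
    vec xp = (t == 0) ? vec(D, fill::zeros) : vec(X.row(t - 1).t());
    for (uword k = 0; k < K; ++k) {
      double w = q(t, k);
      if (w < 1e-12) continue;
      const mat& Ak = P.A.slice(k);
      const mat& Qik = P.Qi.slice(k);
      vec r = xt - Ak * xp - P.Vu.col(k);
      grad.subvec(t * D, t * D + D - 1) -= w * (Qik * r);
      H.submat(t * D, t * D, t * D + D - 1, t * D + D - 1) += w * Qik;
      if (t > 0) {
        mat AQ = Ak.t() * Qik;
        grad.subvec((t - 1) * D, (t - 1) * D + D - 1) += w * (AQ * r);
        H.submat((t - 1) * D, (t - 1) * D, (t - 1) * D + D - 1,
                 (t - 1) * D + D - 1) += w * (AQ * Ak);
        H.submat(t * D, (t - 1) * D, t * D + D - 1,
                 (t - 1) * D + D - 1) -= w * (Qik * Ak);
        H.submat((t - 1) * D, t * D, (t - 1) * D + D - 1,
                 t * D + D - 1) -= w * AQ;
      }
    }
  }
  rowvec ge(P.y.n_cols), he(P.y.n_cols);
  for (uword t = 0; t < T; ++t) {
    rowvec eta = X.row(t) * P.C.t() + P.d;
    emis_grad_hess_row(P.y.row(t), eta, P.dt, ge, he);
    grad.subvec(t * D, t * D + D - 1) += P.C.t() * ge.t();
    mat CH = P.C;
    CH.each_col() %= (-he.t());
    H.submat(t * D, t * D, t * D + D - 1, t * D + D - 1) += P.C.t() * CH;
  }
  for (uword t = 1; t < T; ++t) {
    double w = accu(xi.row(t));
    if (w < 1e-12) continue;
    rowvec s = exp(log_softmax_row((P.G * X.row(t - 1).t()).t() +
                                   P.g0.row(t)));
    grad.subvec((t - 1) * D, (t - 1) * D + D - 1) +=
      P.G.t() * (xi.row(t).t() - w * s.t());
    mat S = diagmat(s) - s.t() * s;
    H.submat((t - 1) * D, (t - 1) * D, (t - 1) * D + D - 1,
             (t - 1) * D + D - 1) += w * (P.G.t() * S * P.G);
  }
  H.diag() += 1e-9;
}

// damped Newton ascent; X updated in place, H left at the final mode
static mat laplace_mode(const TrialPack& P, const mat& q, const mat& xi,
                        mat X, mat& H, int max_iter, double tol) {
  uword T = P.y.n_rows, D = X.n_cols;
  vec grad;
  double J = cont_objective(P, X, q, xi);
  for (int it = 0; it < max_iter; ++it) {
    build_grad_prec(P, q, xi, X, grad, H);
    vec step;
    bool ok = solve(step, H, grad, solve_opts::likely_sympd);
    if (!ok || !step.is_finite()) {
      H.diag() += 1e-4;
      if (!solve(step, H, grad) || !step.is_finite()) break;
    }
    double alpha = 1.0, Jn = -datum::inf;
    mat Xn;
    for (int ls_it = 0; ls_it < 15; ++ls_it) {
      Xn = X + alpha * reshape(step, D, T).t();
      Jn = cont_objective(P, Xn, q, xi);
      if (std::isfinite(Jn) && Jn >= J - 1e-12) break;
      alpha *= 0.5;
    }
    if (!std::isfinite(Jn) || Jn < J - 1e-12) break;
    X = Xn;
    double impr = Jn - J;
    J = Jn;
    if (impr < tol && abs(step).max() * alpha < 1e-5) break;
  }
  build_grad_prec(P, q, xi, X, grad, H);   // precision at the final mode
  return X;
}

static TrialPack make_pack(const arma::mat& y, const arma::mat& Vu,
                           const arma::cube& A, const arma::cube& Qi,
                           const arma::vec& ldQ, const arma::mat& G,
                           const arma::mat& g0, const arma::mat& C,
                           double d, double dt) {
  TrialPack P;
  P.y = y; P.Vu = Vu; P.A = A; P.Qi = Qi; P.ldQ = ldQ;
  P.G = G; P.g0 = g0; P.C = C; P.d = d; P.dt = dt;
  return P;
}

// [[Rcpp::export]]
Rcpp::List cpp_trial_estep(const arma::mat& y, const arma::mat& Vu,
                           const arma::cube& A, const arma::cube& Qi,
                           const arma::vec& ldQ, const arma::mat& G,
                           const arma::mat& g0, const arma::mat& C,
                           double d, double dt, const arma::mat& x_init,
                           int max_newton = 30, double tol = 1e-8) {
  TrialPack P = make_pack(y, Vu, A, Qi, ldQ, G, g0, C, d, dt);
  uword T = y.n_rows, D = x_init.n_cols;

  mat q, xi;
  double logZ;
  forward_backward(P, x_init, q, xi, logZ);

  mat H;
  mat X = laplace_mode(P, q, xi, x_init, H, max_newton, tol);

  mat Sigma;
  if (!inv_sympd(Sigma, H)) { H.diag() += 1e-5; Sigma = inv(H); }
  cube Stt(D, D, T), Soff(D, D, T, fill::zeros);
  for (uword t = 0; t < T; ++t) {
    Stt.slice(t) = Sigma.submat(t * D, t * D, t * D + D - 1, t * D + D - 1);
    if (t > 0)
      Soff.slice(t) = Sigma.submat(t * D, (t - 1) * D, t * D + D - 1,
                                   (t - 1) * D + D - 1);
  }
  double ld, sign;
  log_det(ld, sign, Sigma);

  double ell = 0.0;
  for (uword t = 0; t < T; ++t) {
    rowvec eta = X.row(t) * C.t() + d;
    ell += emis_ll_row(y.row(t), eta, dt);
  }
  // discrete posterior and chain normalizer at the final mode
  mat q2, xi2;
  double logZ2;
  forward_backward(P, X, q2, xi2, logZ2);

  return Rcpp::List::create(
    Rcpp::Named("x") = X, Rcpp::Named("q") = q2, Rcpp::Named("xi") = xi2,
    Rcpp::Named("Stt") = Stt, Rcpp::Named("Soff") = Soff,
    Rcpp::Named("logZ") = logZ2, Rcpp::Named("emis_ll") = ell,
    Rcpp::Named("logdetSigma") = ld);
}

// Emission log-likelihood under samples from the Laplace posterior of the
// continuous path: x^(s) = mode + L^{-T} eps^(s) with H = L L'. `eps` is a
// (T*D) x S standard-normal matrix supplied by the caller so that the R RNG
// governs determinism.
// [[Rcpp::export]]
arma::vec cpp_trial_sample_ll(const arma::mat& y, const arma::mat& Vu,
                              const arma::cube& A, const arma::cube& Qi,
                              const arma::vec& ldQ, const arma::mat& G,
                              const arma::mat& g0, const arma::mat& C,
                              double d, double dt, const arma::mat& x_mode,
                              const arma::mat& q, const arma::mat& xi,
                              const arma::mat& eps) {
  TrialPack P = make_pack(y, Vu, A, Qi, ldQ, G, g0, C, d, dt);
  uword T = y.n_rows, D = x_mode.n_cols;
  vec grad;
  mat H;
  build_grad_prec(P, q, xi, x_mode, grad, H);
  mat L;
  if (!chol(L, H, "lower")) { H.diag() += 1e-5; L = chol(H, "lower"); }
  uword S = eps.n_cols;
  vec out(S);
  for (uword s = 0; s < S; ++s) {
    vec z = solve(trimatu(L.t()), eps.col(s));
    mat X = x_mode + reshape(z, D, T).t();
    double ell = 0.0;
    for (uword t = 0; t < T; ++t) {
      rowvec eta = X.row(t) * C.t() + d;
      ell += emis_ll_row(y.row(t), eta, dt);
    }
    out[s] = ell;
  }
  return out;
}

// ---- fast combined-condition auROC ---------------------------------------
// Per-column sort order and tie-group ids are precomputed once per neuron;
// each relabeling then costs one O(n) counting pass per column, with exact
// half-credit for tied pairs.

// [[Rcpp::export]]
Rcpp::List cpp_order_groups(const arma::mat& M) {
  uword n = M.n_rows, T = M.n_cols;
  arma::umat ord(n, T);
  arma::umat grp(n, T);
  std::vector<uword> idx(n);
  for (uword t = 0; t < T; ++t) {
    for (uword i = 0; i < n; ++i) idx[i] = i;
    const double* col = M.colptr(t);
    std::stable_sort(idx.begin(), idx.end(),
                     [col](uword a, uword b) { return col[a] < col[b]; });
    uword g = 0;
    for (uword p = 0; p < n; ++p) {
      if (p > 0 && col[idx[p]] != col[idx[p - 1]]) ++g;
      ord(p, t) = idx[p];
      grp(p, t) = g;
    }
  }
  return Rcpp::List::create(Rcpp::Named("ord") = ord,
                            Rcpp::Named("grp") = grp);
}

// labels: 0 = excluded, 1 = sample a, 2 = sample b; returns P(b > a) with
// 0.5 per tie, per column
// [[Rcpp::export]]
arma::rowvec cpp_auroc_subsets(const arma::umat& ord, const arma::umat& grp,
                               const arma::ivec& labels) {
  uword n = ord.n_rows, T = ord.n_cols;
  double na = 0, nb = 0;
  for (uword i = 0; i < n; ++i) {
    if (labels[i] == 1) ++na;
    else if (labels[i] == 2) ++nb;
  }
  arma::rowvec out(T, fill::value(datum::nan));
  if (na == 0 || nb == 0) return out;
  for (uword t = 0; t < T; ++t) {
    double U = 0, preA = 0, cntA = 0, cntB = 0;
    uword cur = 0;
    bool started = false;
    for (uword p = 0; p < n; ++p) {
      int lab = labels[ord(p, t)];
      if (lab == 0) continue;
      uword g = grp(p, t);
      if (started && g != cur) {
        U += cntB * preA + 0.5 * cntA * cntB;
        preA += cntA;
        cntA = 0; cntB = 0;
      }
      cur = g; started = true;
      if (lab == 1) ++cntA; else ++cntB;
    }
    U += cntB * preA + 0.5 * cntA * cntB;
    out[t] = U / (na * nb);
  }
  return out;
}
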