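// Marginal log-likelihood for two-level cumulative-logit growth models.
//
// Level 1: visits t within subject i, ordinal outcome y in 1..K,
//   logit P(Y <= k) = delta_k + xnpo' beta_c(k) + xsh' beta + u0 + u1 * time.
// Level 2: (u0, u1) ~ N(0, D), D = L L'.
// The subject-level integral over (u0, u1) is evaluated by adaptive
// Gauss-Hermite quadrature: per-subject posterior mode and Laplace curvature
// re-centre and re-scale a tensor product grid in the standardized effect v,
// where u = L v. Degenerate D collapses to 1-D quadrature (slope variance 0)
// or to a point mass at u = 0 (D = 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double plogis_d(double x) {
  if (x > 0) {
    double e = std::exp(-x);
    return 1.0 / (1.0 + e);
  }
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double dlogis_d(double x) {
  double p = plogis_d(x);
  return p * (1.0 - p);
}

// Conditional log-likelihood of one subject's visits given u = (u0, u1),
// with optional gradient and Hessian in u. B holds the u-free part of the
// K-1 cumulative logits per row. Returns -Inf when a needed category
// probability is non-positive.
static double cond_ll(const mat& B, const ivec& y, const vec& tim,
                      int from, int to, int K,
                      double u0, double u1,
                      bool want_deriv, vec& grad, mat& hess) {
  double ll = 0.0;
  if (want_deriv) { grad.zeros(2); hess.zeros(2, 2); }
  for (int r = from; r <= to; ++r) {
    int k = y(r);                     // 1..K
    double t = tim(r);
    double shift = u0 + u1 * t;
    double Fk = 1.0, fk = 0.0, Fk1 = 0.0, fk1 = 0.0;
    double dk = 0.0, dk1 = 0.0;       // f' = f (1 - 2F)
    if (k < K) {
      double e = B(r, k - 1) + shift;
      Fk = plogis_d(e);
      fk = Fk * (1.0 - Fk);
      dk = fk * (1.0 - 2.0 * Fk);
    }
    if (k > 1) {
      double e = B(r, k - 2) + shift;
      Fk1 = plogis_d(e);
      fk1 = Fk1 * (1.0 - Fk1);
      dk1 = fk1 * (1.0 - 2.0 * Fk1);
    }
    double p = Fk - Fk1;
    if (!(p > 0.0)) return -datum::inf;
    ll += std::log(p);
    if (want_deriv) {
      double g0 = (fk - fk1) / p;          // d ll / d u0 for this row
      double q = (dk - dk1) / p;
      double h00 = q - g0 * g0;
      grad(0) += g0;
      grad(1) += g0 * t;
      hess(0, 0) += h00;
      hess(0, 1) += h00 * t;
      hess(1, 1) += h00 * t * t;
    }
  }
  if (want_deriv) hess(1, 0) = hess(0, 1);
  return ll;
}

// [[Rcpp::export]]
Rcpp::List ogm_marginal_ll_cpp(const arma::vec& delta,
                               const arma::vec& beta_s,
                               const arma::mat& beta_n,
                               const arma::mat& Xs,
                               const arma::mat& Xn,
                               const arma::ivec& y,
                               const arma::vec& tim,
                               const arma::ivec& first,
                               const arma::ivec& last,
                               const arma::mat& L,
                               int re_mode,
                               const arma::vec& ghx,
                               const arma::vec& ghw,
                               bool per_subject) {
  const int n = y.n_elem;
  const int K = delta.n_elem + 1;
  const int nsub = first.n_elem;
  const int Q = ghx.n_elem;

  // u-free part of the cumulative logits, one column per logit
  mat B(n, K - 1);
  vec base = (Xs.n_cols > 0) ? vec(Xs * beta_s) : zeros<vec>(n);
  for (int k = 0; k < K - 1; ++k) {
    B.col(k) = delta(k) + base;
    if (Xn.n_cols > 0) B.col(k) += Xn * beta_n.row(k).t();
  }

  // category probabilities must be non-negative at every observed pattern:
  // u shifts all logits of a row equally, so validity depends on B only
  int bad_row = 0;
  for (int r = 0; r < n && bad_row == 0; ++r)
    for (int k = 1; k < K - 1; ++k)
      if (B(r, k) < B(r, k - 1)) { bad_row = r + 1; break; }
  if (bad_row > 0) {
    return Rcpp::List::create(
      Rcpp::Named("loglik") = R_NegInf,
      Rcpp::Named("per_subject") = Rcpp::NumericVector(0),
      Rcpp::Named("valid") = false,
      Rcpp::Named("bad_row") = bad_row);
  }

  vec lls(nsub);
  vec grad(2), gnew(2);
  mat hess(2, 2), hnew(2, 2);

  const double l2pi = std::log(2.0 * M_PI);

  for (int i = 0; i < nsub; ++i) {
    int from = first(i), to = last(i);

    if (re_mode == 0) {
      lls(i) = cond_ll(B, y, tim, from, to, K, 0.0, 0.0, false, grad, hess);
      continue;
    }

    int d = (re_mode == 2) ? 2 : 1;
    // mode of h(v) = cond_ll(Lv) - |v|^2/2 - (d/2) log(2pi), Newton with halving
    vec v = zeros<vec>(2);
    double h = cond_ll(B, y, tim, from, to, K, 0.0, 0.0, true, grad, hess);
    if (!std::isfinite(h)) { lls(i) = -datum::inf; continue; }
    h -= 0.5 * d * l2pi;

    vec gv(2);
    mat Hv(2, 2);
    bool ok = true;
    for (int it = 0; it < 60; ++it) {
      // gradient/Hessian in v-space (active dims only)
      if (d == 2) {
        gv = L.t() * grad - v;
        Hv = L.t() * hess * L;
        Hv(0, 0) -= 1.0; Hv(1, 1) -= 1.0;
      } else {
        gv(0) = L(0, 0) * grad(0) - v(0); gv(1) = 0.0;
        Hv.zeros();
        Hv(0, 0) = L(0, 0) * L(0, 0) * hess(0, 0) - 1.0;
        Hv(1, 1) = -1.0;
      }
      double gn = (d == 2) ? norm(gv.head(2)) : std::fabs(gv(0));
      if (gn < 1e-10) break;
      vec step(2, fill::zeros);
      if (d == 2) {
        mat A = -Hv;
        if (!solve(step, A, gv, solve_opts::no_approx)) { ok = false; break; }
      } else {
        step(0) = gv(0) / (-Hv(0, 0));
      }
      double sc = 1.0;
      double hn = -datum::inf;
      vec vn(2);
      for (int half = 0; half < 30; ++half) {
        vn = v + sc * step;
        double u0 = 0.0, u1 = 0.0;
        if (d == 2) { u0 = L(0,0) * vn(0); u1 = L(1,0) * vn(0) + L(1,1) * vn(1); }
        else u0 = L(0, 0) * vn(0);
        hn = cond_ll(B, y, tim, from, to, K, u0, u1, true, gnew, hnew);
        if (std::isfinite(hn)) {
          hn -= 0.5 * dot(vn, vn) + 0.5 * d * l2pi;
          if (hn >= h - 1e-12) break;
        }
        sc *= 0.5;
      }
      if (!std::isfinite(hn) || hn < h - 1e-8) break;  // no further progress
      double mv = std::max(std::fabs(sc * step(0)), std::fabs(sc * step(1)));
      v = vn; h = hn; grad = gnew; hess = hnew;
      if (mv < 1e-9) break;
    }
    if (!ok) { lls(i) = -datum::inf; continue; }

    // Laplace curvature A = -(d2 h / dv2) at the mode, then AGQ
    if (d == 2) {
      mat A = -(L.t() * hess * L);
      A(0, 0) += 1.0; A(1, 1) += 1.0;
      mat Lc;
      if (!chol(Lc, A, "lower")) { lls(i) = -datum::inf; continue; }
      mat C = solve(trimatl(Lc), eye<mat>(2, 2)).t();   // C C' = A^{-1}
      double ldC = -std::log(Lc(0, 0)) - std::log(Lc(1, 1));
      double m = -datum::inf;
      mat hq(Q, Q);
      for (int a = 0; a < Q; ++a) {
        for (int b = 0; b < Q; ++b) {
          vec z = {ghx(a), ghx(b)};
          vec vq = v + std::sqrt(2.0) * (C * z);
          double u0 = L(0,0) * vq(0);
          double u1 = L(1,0) * vq(0) + L(1,1) * vq(1);
          double hv = cond_ll(B, y, tim, from, to, K, u0, u1, false, gnew, hnew);
          if (std::isfinite(hv))
            hv += -0.5 * dot(vq, vq) - l2pi + dot(z, z);
          hq(a, b) = hv;
          if (hv > m) m = hv;
        }
      }
      if (!std::isfinite(m)) { lls(i) = -datum::inf; continue; }
      double s = 0.0;
      for (int a = 0; a < Q; ++a)
        for (int b = 0; b < Q; ++b)
          if (std::isfinite(hq(a, b)))
            s += ghw(a) * ghw(b) * std::exp(hq(a, b) - m);
      lls(i) = std::log(2.0) + ldC + m + std::log(s);
    } else {
      double A = 1.0 - L(0, 0) * L(0, 0) * hess(0, 0);
      if (!(A > 0.0)) { lls(i) = -datum::inf; continue; }
      double c = 1.0 / std::sqrt(A);
      double m = -datum::inf;
      vec hq(Q);
      for (int a = 0; a < Q; ++a) {
        double vq = v(0) + std::sqrt(2.0) * c * ghx(a);
        double u0 = L(0, 0) * vq;
        double hv = cond_ll(B, y, tim, from, to, K, u0, 0.0, false, gnew, hnew);
        if (std::isfinite(hv))
          hv += -0.5 * vq * vq - 0.5 * l2pi + ghx(a) * ghx(a);
        hq(a) = hv;
        if (hv > m) m = hv;
      }
      if (!std::isfinite(m)) { lls(i) = -datum::inf; continue; }
      double s = 0.0;
      for (int a = 0; a < Q; ++a)
        if (std::isfinite(hq(a))) s += ghw(a) * std::exp(hq(a) - m);
      lls(i) = 0.5 * std::log(2.0) + std::log(c) + m + std::log(s);
    }
  }

  double tot = accu(lls);
  return Rcpp::List::create(
    Rcpp::Named("loglik") = tot,
    Rcpp::Named("per_subject") = per_subject ? Rcpp::wrap(lls) : Rcpp::wrap(Rcpp::NumericVector(0)),
    Rcpp::Named("valid") = true,
    Rcpp::Named("bad_row") = 0);
}
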