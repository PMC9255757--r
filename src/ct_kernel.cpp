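// Forward filtering of a discrete HMM over ASRT stimuli, the LATER
// response-time likelihood evaluated at the filtered per-trial predictive
// probabilities, and the analytic gradient of that likelihood with respect
// to the transition matrix, emission matrix and LATER parameters
// (reverse-mode through the filtering recursion).
//
// Conventions: stimuli are 1..4; beliefs are row vectors over K states;
// the slice truncation keeps the smallest set of highest-mass states
// covering at least 1 - eps of the belief and renormalizes. Gradients are
// not propagated through the initial belief (treated as a constant), which
// only affects sampler efficiency, never the Metropolis acceptance.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG_2PI = std::log(2.0 * M_PI);

// standard normal pdf/cdf
static inline double phi_pdf(double x) {
  return std::exp(-0.5 * x * x) / std::sqrt(2.0 * M_PI);
}
static inline double phi_cdf(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }

// truncate belief to its (1 - eps) support, in place; returns kept mask
static uvec slice_truncate(vec &s, double eps) {
  const int K = s.n_elem;
  uvec keep(K, fill::ones);
  if (eps <= 0.0) return keep;
  uvec ord = sort_index(s, "descend");
  double cum = 0.0;
  int n_keep = K;
  for (int i = 0; i < K; ++i) {
    cum += s(ord(i));
    if (cum >= 1.0 - eps) { n_keep = i + 1; break; }
  }
  if (n_keep == K) return keep;
  keep.zeros();
  double z = 0.0;
  for (int i = 0; i < n_keep; ++i) { keep(ord(i)) = 1; z += s(ord(i)); }
  for (int k = 0; k < K; ++k) s(k) = keep(k) ? s(k) / z : 0.0;
  return keep;
}

// log density of the LATER model at rt (seconds) given subjective
// probability p (already clamped), plus partials. Returns false if rt is
// outside the support (rt <= theta0).
struct LaterGrad { double lp, d_p, d_theta0, d_mu, d_sigma; };

static bool later_logpdf(double rt, double p, double theta0, double mu,
                         double sigma, LaterGrad &g) {
  const double d = rt - theta0;
  if (d <= 0.0) return false;
  const double x = -std::log(p);
  const double m = mu / sigma;
  const double z = (x / d - mu) / sigma;
  const double logZ = std::log(phi_cdf(m));
  g.lp = -std::log(sigma) - logZ - 0.5 * z * z - 0.5 * LOG_2PI +
         std::log(x) - 2.0 * std::log(d);
  const double lam = phi_pdf(m) / phi_cdf(m);
  g.d_p = (z / (sigma * d) - 1.0 / x) / p;
  g.d_theta0 = 2.0 / d - z * x / (sigma * d * d);
  g.d_mu = z / sigma - lam / sigma;
  g.d_sigma = (z * z - 1.0) / sigma + lam * mu / (sigma * sigma);
  return true;
}

// [[Rcpp::export]]
Rcpp::List filter_hmm_cpp(const arma::mat &transition, const arma::mat &emission,
                          const arma::ivec &y, const arma::vec &init,
                          double eps) {
  const int T = y.n_elem, K = transition.n_rows;
  mat predictions(T, 4), beliefs(T, K);
  vec s = init;
  slice_truncate(s, eps);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    vec pred = transition.t() * s;            // prior over S_t
    rowvec obs = pred.t() * emission;         // predictive over Y_t
    predictions.row(t) = obs;
    const int yt = y(t) - 1;
    vec u = pred % emission.col(yt);
    const double p = accu(u);
    if (p <= 0.0) {
      Rcpp::stop("observation %d at trial %d has zero probability under every reachable state",
                 y(t), t + 1);
    }
    ll += std::log(p);
    s = u / p;
    slice_truncate(s, eps);
    beliefs.row(t) = s.t();
  }
  return Rcpp::List::create(Rcpp::Named("predictions") = predictions,
                            Rcpp::Named("beliefs") = beliefs,
                            Rcpp::Named("loglik_stim") = ll);
}

// Joint filtered likelihood and gradient.
// mode 0: response-time likelihood over valid trials (LATER model at the
//         filtered predictive probability of the realized stimulus)
// mode 1: stimulus predictive likelihood, sum_t log p(y_t | y_<t)
// [[Rcpp::export]]
Rcpp::List ct_loglik_cpp(const arma::mat &transition, const arma::mat &emission,
                         const arma::ivec &y, const arma::vec &init,
                         double eps, const arma::ivec &valid,
                         const arma::vec &rt, double theta0, double mu,
                         double sigma, double p_floor, int mode,
                         bool want_grad) {
  const int T = y.n_elem, K = transition.n_rows;
  const double p_ceil = 1.0 - 1e-9;

  // forward pass storage
  mat S_in(K, T), PRED(K, T), U(K, T), S_norm(K, T);
  umat KEEP(K, T);
  vec pvec(T), csum(T);
  vec g_p(T, fill::zeros);
  vec p_subj(T);

  vec s = init;
  slice_truncate(s, eps);
  double ll = 0.0;
  double d_theta0 = 0.0, d_mu = 0.0, d_sigma = 0.0;
  bool ok = true;

  for (int t = 0; t < T; ++t) {
    S_in.col(t) = s;
    vec pred = transition.t() * s;
    PRED.col(t) = pred;
    const int yt = y(t) - 1;
    vec u = pred % emission.col(yt);
    const double c = accu(u);
    if (c <= 0.0) { ok = false; break; }
    csum(t) = c;
    U.col(t) = u;
    p_subj(t) = c;  // predictive probability of the realized stimulus

    if (mode == 1) {
      ll += std::log(c);
      g_p(t) = 1.0 / c;
    } else if (valid(t)) {
      double p = std::min(std::max(c, p_floor), p_ceil);
      LaterGrad g;
      if (!later_logpdf(rt(t), p, theta0, mu, sigma, g)) { ok = false; break; }
      ll += g.lp;
      d_theta0 += g.d_theta0;
      d_mu += g.d_mu;
      d_sigma += g.d_sigma;
      if (c > p_floor && c < p_ceil) g_p(t) = g.d_p;
    }

    s = u / c;
    S_norm.col(t) = s;
    KEEP.col(t) = slice_truncate(s, eps);
  }

  if (!ok) {
    return Rcpp::List::create(
        Rcpp::Named("loglik") = R_NegInf,
        Rcpp::Named("grad_transition") = mat(K, K, fill::zeros),
        Rcpp::Named("grad_emission") = mat(K, 4, fill::zeros),
        Rcpp::Named("grad_later") = vec(3, fill::zeros),
        Rcpp::Named("p_subjective") = pvec.zeros());
  }

  mat g_tr(K, K, fill::zeros), g_em(K, 4, fill::zeros);
  if (want_grad) {
    vec adj_next(K, fill::zeros);  // adjoint of the truncated belief at t
    for (int t = T - 1; t >= 0; --t) {
      // through slice truncation: s_out = (s .* m) / Z
      vec s_pre = S_norm.col(t);
      vec adj_s(K, fill::zeros);
      if (any(KEEP.col(t) == 0)) {
        vec m = conv_to<vec>::from(KEEP.col(t));
        double Z = accu(s_pre % m);
        vec s_out = (s_pre % m) / Z;
        double dot = accu(adj_next % s_out);
        adj_s = m % (adj_next - dot) / Z;
      } else {
        adj_s = adj_next;
      }
      // through normalization: s = u / c, plus direct g_p on c
      const double c = csum(t);
      double adj_c = g_p(t) - accu(adj_s % U.col(t)) / (c * c);
      vec adj_u = adj_s / c + adj_c;
      // u = pred .* phi[, y_t]
      const int yt = y(t) - 1;
      vec adj_pred = adj_u % emission.col(yt);
      g_em.col(yt) += adj_u % PRED.col(t);
      // pred = t(transition) %*% s_in
      g_tr += S_in.col(t) * adj_pred.t();
      adj_next = transition * adj_pred;
    }
  }

  vec g_later = {d_theta0, d_mu, d_sigma};
  return Rcpp::List::create(
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("grad_transition") = g_tr,
      Rcpp::Named("grad_emission") = g_em,
      Rcpp::Named("grad_later") = g_later,
      Rcpp::Named("p_subjective") = p_subj);
}

// ---------------------------------------------------------------------------
// Full unconstrained log posterior and gradient, for the samplers.
// theta layout:
//   model 0 ("ct"):       K*(K-1) transition coords, K*3 emission coords,
//                         3 log LATER params
//   model 1 ("markov"):   4*3 transition coords, 3 log LATER params
//                         (identity emissions, no emission prior)
//   model 2 ("stimulus"): K*(K-1) + K*3 coords, no LATER block; the
//                         likelihood is the stimulus predictive likelihood
// Transition/emission rows are anchored softmaxes (last coordinate fixed at
// 0); with a Dirichlet(a) prior the density plus transform Jacobian is
// sum(a * log x) + const, with gradient a_j - sum(a) x_j. The initial
// belief is the stationary distribution of the transition matrix (power
// iteration; sampled matrices are strictly positive, hence ergodic),
// treated as a constant in the gradient.

// u holds the free coordinates of row i of a K-row matrix stored
// column-major in theta: coordinate j lives at offset + j * K + i
static void softmax_fill(const double *theta, int offset, int i, int K,
                         int n_free, vec &x) {
  double mx = 0.0;
  for (int j = 0; j < n_free; ++j)
    mx = std::max(mx, theta[offset + j * K + i]);
  double s = std::exp(-mx);
  for (int j = 0; j < n_free; ++j) {
    x(j) = std::exp(theta[offset + j * K + i] - mx);
    s += x(j);
  }
  x(n_free) = std::exp(-mx);
  x /= s;
}

static vec stationary_power(const mat &tr) {
  const int K = tr.n_rows;
  vec v(K, fill::value(1.0 / K)), w(K);
  for (int it = 0; it < 500; ++it) {
    w = tr.t() * v;
    w /= accu(w);
    if (accu(abs(w - v)) < 1e-14) return w;
    v = w;
  }
  return w;
}

// [[Rcpp::export]]
Rcpp::List lp_grad_cpp(const arma::vec &theta, int model, int K,
                       const arma::ivec &y, const arma::vec &rt,
                       const arma::ivec &valid, double eps_slice,
                       const arma::vec &a_pi, const arma::vec &a_phi,
                       const arma::vec &prior_shapes,
                       const arma::vec &prior_rates, double p_floor) {
  const int T = y.n_elem;
  const double p_ceil = 1.0 - 1e-9;
  const int n_pi = K * (K - 1);
  const int n_phi = (model == 1) ? 0 : K * 3;
  const bool has_later = (model != 2);
  const int n_theta = n_pi + n_phi + (has_later ? 3 : 0);
  if ((int)theta.n_elem != n_theta) Rcpp::stop("theta has wrong length");

  vec grad(n_theta, fill::zeros);
  auto bad = [&]() {
    return Rcpp::List::create(Rcpp::Named("lp") = R_NegInf,
                              Rcpp::Named("grad") = grad);
  };

  // unpack parameters
  mat pi_m(K, K), phi_m(K, 4);
  vec xrow(K), erow(4);
  for (int i = 0; i < K; ++i) {
    softmax_fill(theta.memptr(), 0, i, K, K - 1, xrow);
    pi_m.row(i) = xrow.t();
  }
  if (model == 1) {
    phi_m.zeros();
    for (int i = 0; i < 4; ++i) phi_m(i, i) = 1.0;
  } else {
    for (int i = 0; i < K; ++i) {
      softmax_fill(theta.memptr(), n_pi, i, K, 3, erow);
      phi_m.row(i) = erow.t();
    }
  }
  double theta0 = 0.18, mu = 8.0, sigma = 2.0;
  if (has_later) {
    theta0 = std::exp(theta(n_pi + n_phi));
    mu = std::exp(theta(n_pi + n_phi + 1));
    sigma = std::exp(theta(n_pi + n_phi + 2));
    if (!std::isfinite(theta0) || !std::isfinite(mu) || !std::isfinite(sigma))
      return bad();
  }

  // ---- forward filtering ----
  const double eps = (model == 1) ? 0.0 : eps_slice;
  mat S_in(K, T), PRED(K, T), U(K, T), S_norm(K, T);
  umat KEEP(K, T, fill::ones);
  vec csum(T), g_p(T, fill::zeros);
  vec s = stationary_power(pi_m);
  slice_truncate(s, eps);
  double ll = 0.0, d_theta0 = 0.0, d_mu = 0.0, d_sigma = 0.0;
  vec pred(K), u(K);
  for (int t = 0; t < T; ++t) {
    S_in.col(t) = s;
    pred = pi_m.t() * s;
    PRED.col(t) = pred;
    const int yt = y(t) - 1;
    u = pred % phi_m.col(yt);
    const double c = accu(u);
    if (c <= 0.0 || !std::isfinite(c)) return bad();
    csum(t) = c;
    U.col(t) = u;
    if (model == 2) {
      ll += std::log(c);
      g_p(t) = 1.0 / c;
    } else if (valid(t)) {
      double p = std::min(std::max(c, p_floor), p_ceil);
      LaterGrad g;
      if (!later_logpdf(rt(t), p, theta0, mu, sigma, g)) return bad();
      ll += g.lp;
      d_theta0 += g.d_theta0; d_mu += g.d_mu; d_sigma += g.d_sigma;
      if (c > p_floor && c < p_ceil) g_p(t) = g.d_p;
    }
    s = u / c;
    S_norm.col(t) = s;
    KEEP.col(t) = slice_truncate(s, eps);
  }
  if (!std::isfinite(ll)) return bad();

  // ---- backward pass: gradients w.r.t. pi, phi ----
  mat g_tr(K, K, fill::zeros), g_em(K, 4, fill::zeros);
  vec adj_next(K, fill::zeros), adj_s(K), adj_u(K), adj_pred(K), s_pre(K);
  for (int t = T - 1; t >= 0; --t) {
    s_pre = S_norm.col(t);
    if (any(KEEP.col(t) == 0)) {
      vec m = conv_to<vec>::from(KEEP.col(t));
      double Z = accu(s_pre % m);
      vec s_out = (s_pre % m) / Z;
      double dot = accu(adj_next % s_out);
      adj_s = m % (adj_next - dot) / Z;
    } else {
      adj_s = adj_next;
    }
    const double c = csum(t);
    double adj_c = g_p(t) - accu(adj_s % U.col(t)) / (c * c);
    adj_u = adj_s / c + adj_c;
    const int yt = y(t) - 1;
    adj_pred = adj_u % phi_m.col(yt);
    g_em.col(yt) += adj_u % PRED.col(t);
    g_tr += S_in.col(t) * adj_pred.t();
    adj_next = pi_m * adj_pred;
  }

  // ---- priors and chain rule onto the unconstrained scale ----
  double lp = ll;
  const double A_pi = accu(a_pi);
  double const_pi = std::lgamma(A_pi);
  for (int k = 0; k < K; ++k) const_pi -= std::lgamma(a_pi(k));
  for (int i = 0; i < K; ++i) {
    double dot = 0.0;
    for (int k = 0; k < K; ++k) {
      lp += a_pi(k) * std::log(std::max(pi_m(i, k), 1e-300));
      dot += g_tr(i, k) * pi_m(i, k);
    }
    lp += const_pi;
    for (int j = 0; j < K - 1; ++j) {
      grad(j * K + i) = a_pi(j) - A_pi * pi_m(i, j) +
        pi_m(i, j) * (g_tr(i, j) - dot);
    }
  }
  if (model != 1) {
    const double A_phi = accu(a_phi);
    double const_phi = std::lgamma(A_phi);
    for (int k = 0; k < 4; ++k) const_phi -= std::lgamma(a_phi(k));
    for (int i = 0; i < K; ++i) {
      double dot = 0.0;
      for (int k = 0; k < 4; ++k) {
        lp += a_phi(k) * std::log(std::max(phi_m(i, k), 1e-300));
        dot += g_em(i, k) * phi_m(i, k);
      }
      lp += const_phi;
      for (int j = 0; j < 3; ++j) {
        grad(n_pi + j * K + i) = a_phi(j) - A_phi * phi_m(i, j) +
          phi_m(i, j) * (g_em(i, j) - dot);
      }
    }
  }
  if (has_later) {
    const double lat[3] = {theta0, mu, sigma};
    const double d_lat[3] = {d_theta0, d_mu, d_sigma};
    for (int j = 0; j < 3; ++j) {
      const double v = theta(n_pi + n_phi + j);
      lp += prior_shapes(j) * std::log(prior_rates(j)) -
            std::lgamma(prior_shapes(j)) + prior_shapes(j) * v -
            prior_rates(j) * lat[j];
      grad(n_pi + n_phi + j) =
          prior_shapes(j) - prior_rates(j) * lat[j] + d_lat[j] * lat[j];
    }
  }
  if (!std::isfinite(lp)) return bad();
  return Rcpp::List::create(Rcpp::Named("lp") = lp,
                            Rcpp::Named("grad") = grad);
}
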