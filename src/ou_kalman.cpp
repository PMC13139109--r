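// Exact discrete-time Gaussian state-space machinery for the multivariate
// Ornstein-Uhlenbeck (continuous-time VAR(1)) model:
//   dx = A (x - mu) dt + G dW,  Q = G G',  y_t = x_t + e_t, e_t ~ N(0, diag(R))
// Irregular spacing: each step uses Phi(dt) = expm(A dt) and
// Q(dt) = S - Phi S Phi' with S the stationary covariance (Lyapunov solution).
//
// Performance notes: Phi(dt) is computed through the eigendecomposition of A
// (one eig_gen per likelihood call, then two small complex products per
// distinct gap), falling back to the scaling-and-squaring expmat when the
// eigenvector basis is ill-conditioned; gaps are cached, and for runs of
// equal gaps with full observation the filter switches to the steady-state
// gain once the state covariance has converged.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
arma::mat cpp_expm(const arma::mat& M) {
  return expmat(M);
}

// Stationary covariance: solves A S + S A' + Q = 0.
// [[Rcpp::export]]
arma::mat cpp_lyapunov(const arma::mat& A, const arma::mat& Q) {
  mat S = syl(A, A.t(), Q); // solves A X + X A' + Q = 0
  return 0.5 * (S + S.t());
}

namespace {

// Propagator Phi(dt) = expm(A dt), by eigen decomposition when safe.
struct Propagator {
  mat A;
  bool use_eig = false;
  cx_vec lam;
  cx_mat V, Vi;

  explicit Propagator(const mat& A_) : A(A_) {
    cx_vec l;
    cx_mat v;
    if (eig_gen(l, v, A)) {
      cx_mat vi;
      if (inv(vi, v) && norm(v, 2) * norm(vi, 2) < 1e8) {
        lam = l;
        V = v;
        Vi = vi;
        use_eig = true;
      }
    }
  }

  mat operator()(double dt) const {
    if (use_eig) {
      cx_mat W = V;
      for (uword j = 0; j < W.n_cols; ++j) {
        W.col(j) *= std::exp(lam(j) * dt);
      }
      return real(W * Vi);
    }
    return expmat(A * dt);
  }
};

} // namespace

// Log-likelihood of an irregularly spaced, partially observed multivariate
// series under the OU model. Y is n x p with NaN for missing; times in
// hours. Returns -Inf (never throws) on numerical degeneracy so optimizers
// can treat failed iterates as infeasible.
// [[Rcpp::export]]
double cpp_ou_loglik(const arma::vec& times, const arma::mat& Y,
                     const arma::mat& A, const arma::vec& mu,
                     const arma::mat& Q, const arma::vec& Rdiag) {
  const uword n = Y.n_rows, p = Y.n_cols;
  const double log2pi = std::log(2.0 * M_PI);

  mat Sinf;
  try {
    Sinf = syl(A, A.t(), Q);
  } catch (...) {
    return R_NegInf;
  }
  Sinf = 0.5 * (Sinf + Sinf.t());
  if (!Sinf.is_finite()) return R_NegInf;

  Propagator prop(A);
  std::map<double, std::pair<mat, mat>> cache; // dt -> (Phi, Qdt)

  vec z(p, fill::zeros); // filtered mean of (x - mu)
  mat P = Sinf;          // filtered covariance
  double ll = 0.0;
  bool first = true;

  // steady-state machinery for runs of equal, fully observed gaps
  double prev_dt = -1.0;
  bool prev_full = false;
  bool steady = false;
  mat ss_K, ss_Sichol, ss_P, ss_Phi;
  double ss_logdet = 0.0;

  vec yrow(p);
  for (uword t = 0; t < n; ++t) {
    yrow = Y.row(t).t();
    uvec obs = find_finite(yrow);
    bool full = (obs.n_elem == p);

    double dt = first ? 0.0 : times(t) - times(t - 1);
    if (!first && dt <= 0) return R_NegInf;

    if (!first && steady && full && dt == prev_dt) {
      // steady-state step: covariance, gain and innovation factor frozen
      vec zpred = ss_Phi * z;
      vec v = yrow - mu - zpred;
      vec w = solve(trimatl(ss_Sichol), v);
      ll += -0.5 * (p * log2pi + ss_logdet + dot(w, w));
      z = zpred + ss_K * v;
      prev_full = true;
      continue;
    }
    steady = false;

    vec zpred;
    mat Ppred;
    const mat* Phi_cur = nullptr;
    if (first) {
      zpred = z;
      Ppred = P;
    } else {
      auto it = cache.find(dt);
      if (it == cache.end()) {
        mat Phi = prop(dt);
        mat Qdt = Sinf - Phi * Sinf * Phi.t();
        Qdt = 0.5 * (Qdt + Qdt.t());
        it = cache.emplace(dt, std::make_pair(std::move(Phi),
                                              std::move(Qdt))).first;
      }
      Phi_cur = &it->second.first;
      zpred = *Phi_cur * z;
      Ppred = *Phi_cur * P * Phi_cur->t() + it->second.second;
      Ppred = 0.5 * (Ppred + Ppred.t());
    }

    if (obs.n_elem == 0) {
      z = zpred;
      P = Ppred;
      first = false;
      prev_full = false;
      prev_dt = dt;
      continue;
    }

    mat S, L, K;
    if (full) {
      S = Ppred + diagmat(Rdiag);
    } else {
      S = Ppred(obs, obs) + diagmat(Rdiag(obs));
    }
    S = 0.5 * (S + S.t());
    if (!chol(L, S, "lower")) return R_NegInf;
    double logdet = 2.0 * sum(log(L.diag()));

    vec v = full ? vec(yrow - mu - zpred)
                 : vec(yrow(obs) - mu(obs) - zpred(obs));
    vec w = solve(trimatl(L), v);
    ll += -0.5 * (obs.n_elem * log2pi + logdet + dot(w, w));

    mat PHt = full ? Ppred : mat(Ppred.cols(obs));
    K = solve(trimatl(L), PHt.t());
    K = solve(trimatu(L.t()), K).t();

    z = zpred + K * v;
    mat Pnew = Ppred - K * PHt.t();
    Pnew = 0.5 * (Pnew + Pnew.t());

    // detect covariance convergence across equal fully observed gaps
    if (!first && full && prev_full && dt == prev_dt && Phi_cur != nullptr) {
      if (norm(Pnew - P, "inf") < 1e-12 * (1.0 + norm(Pnew, "inf"))) {
        steady = true;
        ss_K = K;
        ss_Sichol = L;
        ss_logdet = logdet;
        ss_Phi = *Phi_cur;
      }
    }
    P = Pnew;
    prev_full = full;
    prev_dt = dt;
    first = false;
  }
  if (!std::isfinite(ll)) return R_NegInf;
  return ll;
}

// Exact OU path sampling at given timestamps, starting from the stationary
// distribution; innovations are passed in (n x p standard normals) so that
// all randomness is controlled from R's RNG.
// [[Rcpp::export]]
arma::mat cpp_ou_simulate(const arma::vec& times, const arma::mat& A,
                          const arma::vec& mu, const arma::mat& Q,
                          const arma::mat& Zinnov) {
  const uword n = times.n_elem, p = mu.n_elem;
  mat Sinf = syl(A, A.t(), Q);
  Sinf = 0.5 * (Sinf + Sinf.t());

  // PSD-safe factor via eigendecomposition (Q may be singular)
  auto psd_factor = [](const mat& M) {
    vec ev;
    mat V;
    eig_sym(ev, V, 0.5 * (M + M.t()));
    ev.transform([](double x) { return x > 0 ? std::sqrt(x) : 0.0; });
    return mat(V * diagmat(ev));
  };

  Propagator prop(A);
  mat X(n, p);
  vec z = psd_factor(Sinf) * Zinnov.row(0).t(); // deviation from mu
  X.row(0) = (mu + z).t();

  std::map<double, std::pair<mat, mat>> cache;
  for (uword t = 1; t < n; ++t) {
    double dt = times(t) - times(t - 1);
    auto it = cache.find(dt);
    if (it == cache.end()) {
      mat Phi = prop(dt);
      mat Qdt = Sinf - Phi * Sinf * Phi.t();
      it = cache.emplace(dt, std::make_pair(std::move(Phi),
                                            psd_factor(Qdt))).first;
    }
    z = it->second.first * z + it->second.second * Zinnov.row(t).t();
    X.row(t) = (mu + z).t();
  }
  return X;
}
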