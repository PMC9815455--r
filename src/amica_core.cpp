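// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// |u|^rho with fast paths for the common shapes.
static inline double pow_rho(double au, double rho) {
  if (rho == 2.0) return au * au;
  if (rho == 1.0) return au;
  return std::exp(rho * std::log(au + 1e-300));
}

// Core of the simplified adaptive-mixture ICA.  Each source density is a
// mixture of n_mix generalized Gaussians
//   q_i(s) = sum_j pi_ij * rho_ij / (2 beta_ij Gamma(1/rho_ij))
//                 * exp(-|(s - mu_ij)/beta_ij|^rho_ij),
// optionally with several concurrent models carrying per-sample
// responsibilities.  Updates per iteration: natural-gradient step on each
// W_h using the mixture score function, EM moment updates for
// weights/locations/scales, a clipped 1-D gradient step on the shapes, and
// per-sample model responsibilities when n_models > 1.  The learning rate
// is halved (and the step reverted) whenever the data log-likelihood
// decreases, so the recorded likelihood trace is non-decreasing; it grows
// by 5% on accepted steps.  Stops at max_iter or when lrate < min_lrate.
//
// Per-mixture log-probabilities are cached between the E and M passes
// (field `lp`); |u|^rho is recovered from the cache by subtraction
// instead of a second pow evaluation.
// [[Rcpp::export]]
List amica_core_cpp(const arma::mat& X, arma::cube W, arma::cube pi_,
                    arma::cube mu, arma::cube beta, arma::cube rho,
                    arma::vec alpha, int max_iter = 2000, double lrate = 0.05,
                    double min_lrate = 1e-8, double lrate_max = 1.0,
                    bool update_rho = true,
                    double rho_min = 1.0, double rho_max = 4.0) {
  const arma::uword n = X.n_rows, T = X.n_cols;
  const arma::uword M = W.n_slices, K = pi_.n_cols;

  std::vector<double> ll_trace;
  double ll_prev = -arma::datum::inf;

  arma::cube W_acc = W, pi_acc = pi_, mu_acc = mu, beta_acc = beta,
             rho_acc = rho;
  arma::vec alpha_acc = alpha;

  arma::cube S(n, T, M);
  arma::mat logLh(M, T);
  arma::cube Lsrc(n, T, M);
  arma::field<arma::mat> lp(M, n);  // cached K x T per-mixture log-probs
  for (arma::uword h = 0; h < M; ++h)
    for (arma::uword i = 0; i < n; ++i) lp(h, i).set_size(K, T);
  arma::vec rbar(M, arma::fill::zeros);
  int iter_done = 0;

  for (int iter = 0; iter < max_iter; ++iter) {
    // ---- E: per-sample log-likelihood under every model ----------------
    arma::cube logc(n, K, M);
    for (arma::uword h = 0; h < M; ++h) {
      S.slice(h) = W.slice(h) * X;
      double ldet, sign;
      arma::log_det(ldet, sign, W.slice(h));
      logLh.row(h).fill(ldet + std::log(alpha(h) + 1e-300));
      for (arma::uword i = 0; i < n; ++i) {
        arma::mat& lpi = lp(h, i);
        const double* s = S.slice(h).colptr(0) + i; // row i, stride n
        for (arma::uword j = 0; j < K; ++j) {
          const double r = rho(i, j, h);
          const double b = beta(i, j, h), m0 = mu(i, j, h);
          const double lc = std::log(pi_(i, j, h) + 1e-300) + std::log(r) -
                            std::log(2.0 * b) - std::lgamma(1.0 / r);
          logc(i, j, h) = lc;
          double* lpr = lpi.colptr(0) + j; // row j, stride K
          for (arma::uword t = 0; t < T; ++t)
            lpr[t * K] = lc - pow_rho(std::fabs(s[t * n] - m0) / b, r);
        }
        // logsumexp over mixtures
        double* Ls = Lsrc.slice(h).colptr(0) + i;
        for (arma::uword t = 0; t < T; ++t) {
          const double* c = lpi.colptr(t);
          double mx = c[0];
          for (arma::uword j = 1; j < K; ++j) if (c[j] > mx) mx = c[j];
          double se = 0.0;
          for (arma::uword j = 0; j < K; ++j) se += std::exp(c[j] - mx);
          Ls[t * n] = mx + std::log(se);
        }
      }
      logLh.row(h) += arma::sum(Lsrc.slice(h), 0);
    }

    arma::rowvec mxh = arma::max(logLh, 0);
    arma::rowvec lse =
        mxh + arma::log(arma::sum(arma::exp(logLh.each_row() - mxh), 0));
    const double ll = arma::mean(lse);

    if (!std::isfinite(ll))
      stop("AMICA diverged (non-finite likelihood); consider rescaling the data");
    if (ll + 1e-12 < ll_prev) {
      // revert the previous step and anneal the learning rate
      W = W_acc; pi_ = pi_acc; mu = mu_acc; beta = beta_acc; rho = rho_acc;
      alpha = alpha_acc;
      lrate *= 0.5;
      iter_done = iter + 1;
      if (lrate < min_lrate) break;
      continue;
    }
    ll_prev = ll;
    ll_trace.push_back(ll);
    W_acc = W; pi_acc = pi_; mu_acc = mu; beta_acc = beta; rho_acc = rho;
    alpha_acc = alpha;
    lrate = std::min(lrate * 1.05, lrate_max);
    iter_done = iter + 1;
    if (iter == max_iter - 1) break;

    arma::mat R(M, T);
    if (M > 1) R = arma::exp(logLh.each_row() - lse); else R.ones();
    rbar = arma::mean(R, 1);

    // ---- M: per-model updates ------------------------------------------
    for (arma::uword h = 0; h < M; ++h) {
      const arma::mat& Sh = S.slice(h);
      const double Nh = arma::accu(R.row(h)) + 1e-300;
      arma::mat Phi(n, T);
      arma::mat pi_new(n, K), mu_new(n, K), beta_new(n, K), rho_new(n, K);
      arma::rowvec z(T);

      arma::vec eta(n, arma::fill::zeros);   // E[phi'] per source
      arma::vec msq(n, arma::fill::zeros);   // E[s^2] per source
      for (arma::uword i = 0; i < n; ++i) {
        const arma::mat& lpi = lp(h, i);
        const double* Ls = Lsrc.slice(h).colptr(0) + i;
        const double* s = Sh.colptr(0) + i;
        double* ph = Phi.colptr(0) + i;
        for (arma::uword t = 0; t < T; ++t) {
          ph[t * n] = 0.0;
          msq(i) += R(h, t) * s[t * n] * s[t * n];
        }
        msq(i) /= Nh;

        for (arma::uword j = 0; j < K; ++j) {
          const double b = beta(i, j, h), r = rho(i, j, h),
                       m0 = mu(i, j, h), lc = logc(i, j, h);
          const double* lpr = lpi.colptr(0) + j;
          double wj = 0.0, sw = 0.0, mr = 0.0, dg = 0.0;
          // first pass: responsibilities z and location stats
          for (arma::uword t = 0; t < T; ++t) {
            const double zt =
                std::exp(lpr[t * K] - Ls[t * n]) * R(h, t);
            z[t] = zt;
            wj += zt;
            sw += zt * s[t * n];
            // score: (r/b) |u|^(r-1) sign(u) = r * prho / (s - mu),
            // recovering prho = |u|^r from the cached lp = lc - prho
            const double d = s[t * n] - m0;
            const double prho = lc - lpr[t * K];
            if (std::fabs(d) > 1e-300) ph[t * n] += zt * r * prho / d;
          }
          wj += 1e-300;
          const double mu_j = sw / wj;
          // second pass: scale moment, shape gradient, and score-slope
          // E[phi'] (pairwise-Newton curvature; |u|^(r-2) clamped)
          double et = 0.0;
          for (arma::uword t = 0; t < T; ++t) {
            const double au = std::fabs(s[t * n] - mu_j) / b;
            const double prho = pow_rho(au, r);
            mr += z[t] * prho;
            if (update_rho && au > 1e-12)
              dg += z[t] * prho * std::log(au);
            const double aup = std::min(pow_rho(std::max(au, 1e-6), r - 2.0),
                                        1e4);
            et += z[t] * (r * (std::max(r, 1.01) - 1.0) / (b * b)) * aup;
          }
          eta(i) += et / Nh;
          mr /= wj;
          pi_new(i, j) = wj / Nh;
          mu_new(i, j) = mu_j;
          beta_new(i, j) = b * std::pow(r * mr + 1e-300, 1.0 / r);
          if (update_rho) {
            const double g = 1.0 / r + R::digamma(1.0 / r) / (r * r) -
                             dg / wj;
            double step = 0.5 * lrate * g;
            step = std::max(-0.1, std::min(0.1, step));
            rho_new(i, j) = std::max(rho_min, std::min(rho_max, r + step));
          } else {
            rho_new(i, j) = r;
          }
        }
      }

      // pairwise-Newton preconditioned relative update: for each pair
      // (i,j) solve  [eta_i m_j, 1; 1, eta_j m_i] [B_ij; B_ji] =
      // [G_ij; G_ji]; diagonal keeps the natural-gradient scale step.
      arma::mat G = Phi * Sh.t() / Nh;
      arma::mat B(n, n, arma::fill::zeros);
      for (arma::uword i = 0; i < n; ++i) B(i, i) = G(i, i) - 1.0;
      for (arma::uword i = 0; i + 1 < n; ++i)
        for (arma::uword j = i + 1; j < n; ++j) {
          const double hii = eta(i) * msq(j), hjj = eta(j) * msq(i);
          const double dd = hii * hjj - 1.0;
          if (dd > 1e-6) {
            B(i, j) = (hjj * G(i, j) - G(j, i)) / dd;
            B(j, i) = (hii * G(j, i) - G(i, j)) / dd;
          } else {
            B(i, j) = G(i, j);
            B(j, i) = G(j, i);
          }
        }
      W.slice(h) -= lrate * B * W.slice(h);

      pi_.slice(h) = pi_new;
      mu.slice(h) = mu_new;
      beta.slice(h) = arma::clamp(beta_new, 1e-6, arma::datum::inf);
      rho.slice(h) = rho_new;
      alpha(h) = Nh / (double)T;

      // keep sources near unit scale
      arma::mat Sh2 = W.slice(h) * X;
      for (arma::uword i = 0; i < n; ++i) {
        const double sd = arma::stddev(Sh2.row(i));
        if (sd > 1e-12 && std::isfinite(sd)) {
          W.slice(h).row(i) /= sd;
          mu.slice(h).row(i) /= sd;
          beta.slice(h).row(i) /= sd;
        }
      }
    }
    alpha /= arma::accu(alpha);

    if (!W.is_finite())
      stop("AMICA diverged (non-finite demixing matrix); consider rescaling the data");
    if (lrate < min_lrate) break;
  }

  return List::create(_["W"] = W, _["pi"] = pi_, _["mu"] = mu,
                      _["beta"] = beta, _["rho"] = rho, _["alpha"] = alpha,
                      _["loglik"] =
                          NumericVector(ll_trace.begin(), ll_trace.end()),
                      _["n_iter"] = iter_done, _["lrate"] = lrate,
                      _["model_weight"] = rbar);
}
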