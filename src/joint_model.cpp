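#include <Rcpp.h>
using namespace Rcpp;

// Joint hierarchical model: 1-parameter IRT latent state (theta) coupled to a
// state-modulated linear effort-discounting choice model.
//
// Unconstrained parameter vector layout (in order):
//   theta_mu           [T]       group-mean latent state per occasion
//   theta_off_raw      [n_off]   non-centered person offsets (valid cells only)
//   log_sigma_theta    [1]
//   u_delta            [M]       delta = exp(u), truncated-normal(0,1) prior
//   beta               [nb]      trait/state modulation weights
//   mu_R, mu_E         [2]       population mean sensitivities
//   log_sigma_R/E      [2]
//   rew_raw            [n_cell]  non-centered per-participant-per-game offsets
//   eff_raw            [n_cell]
//
// beta slots by lag mode:
//   0 (current):         traitR, traitE, stateR,    stateE
//   1 (past_and_future): traitR, traitE, stateR_m1, stateR_p1, stateE
//   2 (past_two):        traitR, traitE, stateR_m1, stateR_m2, stateE
// The effort side always uses the current-occasion state.

struct ModelData {
  int N, T, M, nb, lag_mode, n_off, n_cell;
  IntegerMatrix valid;    // N x T
  IntegerMatrix off_idx;  // N x T -> index into theta_off_raw, -1 if fixed 0
  IntegerVector item_i, item_t, item_m, item_y;
  NumericVector ap;
  IntegerVector cell_i, cell_tc, cell_tp, cell_tf, cell_tp2;
  IntegerVector ch_cell, ch_y;
  NumericVector ch_dr, ch_de;
  NumericVector pb_mean, pb_sd;
  double theta_mu_sd, mu_sd;
};

static ModelData unpack(const List& data) {
  ModelData d;
  d.N = as<int>(data["N"]); d.T = as<int>(data["T"]); d.M = as<int>(data["M"]);
  d.nb = as<int>(data["nb"]); d.lag_mode = as<int>(data["lag_mode"]);
  d.n_off = as<int>(data["n_off"]); d.n_cell = as<int>(data["n_cell"]);
  d.valid = as<IntegerMatrix>(data["valid"]);
  d.off_idx = as<IntegerMatrix>(data["off_idx"]);
  d.item_i = as<IntegerVector>(data["item_i"]);
  d.item_t = as<IntegerVector>(data["item_t"]);
  d.item_m = as<IntegerVector>(data["item_m"]);
  d.item_y = as<IntegerVector>(data["item_y"]);
  d.ap = as<NumericVector>(data["ap"]);
  d.cell_i = as<IntegerVector>(data["cell_i"]);
  d.cell_tc = as<IntegerVector>(data["cell_tc"]);
  d.cell_tp = as<IntegerVector>(data["cell_tp"]);
  d.cell_tf = as<IntegerVector>(data["cell_tf"]);
  d.cell_tp2 = as<IntegerVector>(data["cell_tp2"]);
  d.ch_cell = as<IntegerVector>(data["ch_cell"]);
  d.ch_y = as<IntegerVector>(data["ch_y"]);
  d.ch_dr = as<NumericVector>(data["ch_dr"]);
  d.ch_de = as<NumericVector>(data["ch_de"]);
  d.pb_mean = as<NumericVector>(data["prior_beta_mean"]);
  d.pb_sd = as<NumericVector>(data["prior_beta_sd"]);
  d.theta_mu_sd = as<double>(data["prior_theta_mu_sd"]);
  d.mu_sd = as<double>(data["prior_mu_sd"]);
  return d;
}

static inline double soft_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double ilogit(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

// Core evaluation. If grad is non-null it must have length = dim and be zeroed.
// With jac = true the density is over the unconstrained vector (log-scale
// variance parameters, non-centered offsets) including Jacobian terms - the
// target the sampler explores. With jac = false it is the fully normalized
// joint density over the constrained parameters (offsets measured on their
// natural scale), which is what joint_log_density() reports; gradients are
// only supported for jac = true.
static const double HALF_LN2PI = 0.9189385332046727;

static double lp_eval(const ModelData& d, const double* par, double* grad,
                      bool jac = true) {
  const int T = d.T, N = d.N, M = d.M, nb = d.nb;
  // offsets into par
  const int o_tm = 0;
  const int o_off = o_tm + T;
  const int o_lst = o_off + d.n_off;
  const int o_del = o_lst + 1;
  const int o_beta = o_del + M;
  const int o_mu = o_beta + nb;
  const int o_lsre = o_mu + 2;
  const int o_rraw = o_lsre + 2;
  const int o_eraw = o_rraw + d.n_cell;

  const double sig_t = std::exp(par[o_lst]);
  const double sig_R = std::exp(par[o_lsre]);
  const double sig_E = std::exp(par[o_lsre + 1]);
  const double mu_R = par[o_mu], mu_E = par[o_mu + 1];

  double lp = 0.0;

  // ---- priors ----
  const double LOG2 = 0.6931471805599453;
  for (int t = 0; t < T; ++t) {
    double x = par[o_tm + t] / d.theta_mu_sd;
    lp += -0.5 * x * x - HALF_LN2PI - std::log(d.theta_mu_sd);
    if (grad) grad[o_tm + t] += -x / d.theta_mu_sd;
  }
  for (int k = 0; k < d.n_off; ++k) {
    lp += -0.5 * par[o_off + k] * par[o_off + k] - HALF_LN2PI;
    if (grad) grad[o_off + k] += -par[o_off + k];
  }
  if (!jac) lp += -d.n_off * par[o_lst];  // offsets ~ N(0, sigma_theta)
  // half-normal(0,1) on sigma_theta, log parameterization (+ Jacobian)
  lp += LOG2 - HALF_LN2PI - 0.5 * sig_t * sig_t + (jac ? par[o_lst] : 0.0);
  if (grad) grad[o_lst] += -sig_t * sig_t + 1.0;
  // delta = exp(u); truncated normal(0,1) on [0, Inf) + Jacobian
  std::vector<double> delta(M);
  for (int m = 0; m < M; ++m) {
    delta[m] = std::exp(par[o_del + m]);
    lp += LOG2 - HALF_LN2PI - 0.5 * delta[m] * delta[m] +
      (jac ? par[o_del + m] : 0.0);
    if (grad) grad[o_del + m] += -delta[m] * delta[m] + 1.0;
  }
  for (int b = 0; b < nb; ++b) {
    double x = (par[o_beta + b] - d.pb_mean[b]) / d.pb_sd[b];
    lp += -0.5 * x * x - HALF_LN2PI - std::log(d.pb_sd[b]);
    if (grad) grad[o_beta + b] += -x / d.pb_sd[b];
  }
  {
    double xr = mu_R / d.mu_sd, xe = mu_E / d.mu_sd;
    lp += -0.5 * xr * xr - 0.5 * xe * xe - 2.0 * (HALF_LN2PI + std::log(d.mu_sd));
    if (grad) { grad[o_mu] += -xr / d.mu_sd; grad[o_mu + 1] += -xe / d.mu_sd; }
  }
  lp += LOG2 - HALF_LN2PI - 0.5 * sig_R * sig_R + (jac ? par[o_lsre] : 0.0);
  lp += LOG2 - HALF_LN2PI - 0.5 * sig_E * sig_E + (jac ? par[o_lsre + 1] : 0.0);
  if (grad) {
    grad[o_lsre] += -sig_R * sig_R + 1.0;
    grad[o_lsre + 1] += -sig_E * sig_E + 1.0;
  }
  for (int k = 0; k < d.n_cell; ++k) {
    lp += -0.5 * par[o_rraw + k] * par[o_rraw + k] - HALF_LN2PI;
    lp += -0.5 * par[o_eraw + k] * par[o_eraw + k] - HALF_LN2PI;
    if (grad) {
      grad[o_rraw + k] += -par[o_rraw + k];
      grad[o_eraw + k] += -par[o_eraw + k];
    }
  }
  if (!jac) lp += -(double)d.n_cell * (par[o_lsre] + par[o_lsre + 1]);

  // ---- latent state matrix, person moments over valid occasions ----
  std::vector<double> theta(N * T);
  std::vector<double> pm(N), ps(N);
  std::vector<int> pn(N);
  for (int i = 0; i < N; ++i) {
    double s = 0.0; int n = 0;
    for (int t = 0; t < T; ++t) {
      double th = par[o_tm + t];
      int k = d.off_idx(i, t);
      if (k >= 0) th += sig_t * par[o_off + k];
      theta[i * T + t] = th;
      if (d.valid(i, t)) { s += th; ++n; }
    }
    pn[i] = n;
    pm[i] = (n > 0) ? s / n : 0.0;
    double ss = 0.0;
    if (n > 1) {
      for (int t = 0; t < T; ++t)
        if (d.valid(i, t)) {
          double e = theta[i * T + t] - pm[i];
          ss += e * e;
        }
      ps[i] = std::sqrt(ss / (n - 1));
    } else ps[i] = 0.0;
  }
  auto zok = [&](int i) { return pn[i] > 1 && ps[i] > 1e-10; };
  auto zval = [&](int i, int t) {
    return zok(i) ? (theta[i * T + t] - pm[i]) / ps[i] : 0.0;
  };

  std::vector<double> dtheta;          // accumulate d lp / d theta(i,t)
  std::vector<double> Gz;              // accumulate d lp / d z(i,t)
  if (grad) { dtheta.assign(N * T, 0.0); Gz.assign(N * T, 0.0); }

  // ---- IRT likelihood ----
  const int n_item = d.item_i.size();
  for (int r = 0; r < n_item; ++r) {
    int i = d.item_i[r], t = d.item_t[r], m = d.item_m[r], y = d.item_y[r];
    double lg = theta[i * T + t] - delta[m];
    lp += y * lg - soft_log1pexp(lg);
    if (grad) {
      double e = y - ilogit(lg);
      dtheta[i * T + t] += e;
      grad[o_del + m] += -e * delta[m];  // chain through delta = exp(u)
    }
  }

  // ---- choice likelihood ----
  const int b_tR = 0, b_tE = 1;
  std::vector<double> rs(d.n_cell), es(d.n_cell);
  for (int c = 0; c < d.n_cell; ++c) {
    int i = d.cell_i[c], tc = d.cell_tc[c];
    double zc = zval(i, tc);
    double br;
    if (d.lag_mode == 0) {
      br = par[o_beta + 2] * zc;
    } else if (d.lag_mode == 1) {
      double zp = (d.cell_tp[c] >= 0) ? zval(i, d.cell_tp[c]) : 0.0;
      double zf = (d.cell_tf[c] >= 0) ? zval(i, d.cell_tf[c]) : 0.0;
      br = par[o_beta + 2] * zp + par[o_beta + 3] * zf;
    } else {
      double zp = (d.cell_tp[c] >= 0) ? zval(i, d.cell_tp[c]) : 0.0;
      double z2 = (d.cell_tp2[c] >= 0) ? zval(i, d.cell_tp2[c]) : 0.0;
      br = par[o_beta + 2] * zp + par[o_beta + 3] * z2;
    }
    int b_sE = (d.lag_mode == 0) ? 3 : 4;
    rs[c] = par[o_beta + b_tR] * d.ap[i] + mu_R + sig_R * par[o_rraw + c] + br;
    es[c] = par[o_beta + b_tE] * d.ap[i] + mu_E + sig_E * par[o_eraw + c] +
            par[o_beta + b_sE] * zc;
  }
  std::vector<double> dRew, dEff;
  if (grad) { dRew.assign(d.n_cell, 0.0); dEff.assign(d.n_cell, 0.0); }
  const int n_ch = d.ch_cell.size();
  for (int r = 0; r < n_ch; ++r) {
    int c = d.ch_cell[r];
    double v = rs[c] * d.ch_dr[r] - es[c] * d.ch_de[r];
    lp += d.ch_y[r] * v - soft_log1pexp(v);
    if (grad) {
      double e = d.ch_y[r] - ilogit(v);
      dRew[c] += e * d.ch_dr[r];
      dEff[c] += -e * d.ch_de[r];
    }
  }

  if (!grad) return lp;

  // ---- distribute cell-level gradients ----
  int b_sE = (d.lag_mode == 0) ? 3 : 4;
  for (int c = 0; c < d.n_cell; ++c) {
    int i = d.cell_i[c], tc = d.cell_tc[c];
    double gr = dRew[c], ge = dEff[c];
    grad[o_beta + b_tR] += gr * d.ap[i];
    grad[o_beta + b_tE] += ge * d.ap[i];
    grad[o_mu] += gr;
    grad[o_mu + 1] += ge;
    grad[o_rraw + c] += gr * sig_R;
    grad[o_eraw + c] += ge * sig_E;
    grad[o_lsre] += gr * sig_R * par[o_rraw + c];
    grad[o_lsre + 1] += ge * sig_E * par[o_eraw + c];
    double zc = zval(i, tc);
    grad[o_beta + b_sE] += ge * zc;
    Gz[i * T + tc] += ge * par[o_beta + b_sE];
    if (d.lag_mode == 0) {
      grad[o_beta + 2] += gr * zc;
      Gz[i * T + tc] += gr * par[o_beta + 2];
    } else if (d.lag_mode == 1) {
      if (d.cell_tp[c] >= 0) {
        grad[o_beta + 2] += gr * zval(i, d.cell_tp[c]);
        Gz[i * T + d.cell_tp[c]] += gr * par[o_beta + 2];
      }
      if (d.cell_tf[c] >= 0) {
        grad[o_beta + 3] += gr * zval(i, d.cell_tf[c]);
        Gz[i * T + d.cell_tf[c]] += gr * par[o_beta + 3];
      }
    } else {
      if (d.cell_tp[c] >= 0) {
        grad[o_beta + 2] += gr * zval(i, d.cell_tp[c]);
        Gz[i * T + d.cell_tp[c]] += gr * par[o_beta + 2];
      }
      if (d.cell_tp2[c] >= 0) {
        grad[o_beta + 3] += gr * zval(i, d.cell_tp2[c]);
        Gz[i * T + d.cell_tp2[c]] += gr * par[o_beta + 3];
      }
    }
  }

  // ---- backprop z -> theta ----
  // z_t = (theta_t - m) / s with m, s over the participant's valid occasions;
  // dz_t/dtheta_u = [1{u=t} - 1/n - z_t z_u / (n-1)] / s for u valid,
  // plus the direct 1{u=t}/s term when t itself is not a valid occasion.
  for (int i = 0; i < N; ++i) {
    if (!zok(i)) continue;
    double S0 = 0.0, S1 = 0.0;
    bool any = false;
    for (int t = 0; t < T; ++t) {
      double g = Gz[i * T + t];
      if (g != 0.0) {
        any = true;
        S0 += g;
        S1 += g * zval(i, t);
        dtheta[i * T + t] += g / ps[i];  // direct term
      }
    }
    if (!any) continue;
    for (int t = 0; t < T; ++t) {
      if (d.valid(i, t)) {
        dtheta[i * T + t] +=
          (-S0 / pn[i] - zval(i, t) * S1 / (pn[i] - 1)) / ps[i];
      }
    }
  }

  // ---- map dtheta to parameters ----
  for (int i = 0; i < N; ++i)
    for (int t = 0; t < T; ++t) {
      double g = dtheta[i * T + t];
      if (g == 0.0) continue;
      grad[o_tm + t] += g;
      int k = d.off_idx(i, t);
      if (k >= 0) {
        grad[o_off + k] += g * sig_t;
        grad[o_lst] += g * sig_t * par[o_off + k];
      }
    }
  return lp;
}

// [[Rcpp::export]]
List emamot_lp_grad(NumericVector par, List data, bool want_grad = true,
                    bool jacobian = true) {
  ModelData d = unpack(data);
  int dim = par.size();
  if (want_grad && jacobian) {
    NumericVector g(dim);
    double lp = lp_eval(d, REAL(par), REAL(g), true);
    return List::create(_["lp"] = lp, _["grad"] = g);
  }
  double lp = lp_eval(d, REAL(par), nullptr, jacobian);
  return List::create(_["lp"] = lp);
}

// Adaptive HMC: dual-averaging step size during warmup, diagonal metric
// estimated from a mid-warmup window, jittered number of leapfrog steps.
// [[Rcpp::export]]
List emamot_hmc(List data, NumericVector init, int n_warmup, int n_sample,
                int L_max = 24, double target_accept = 0.8,
                double init_step = 0.1) {
  ModelData d = unpack(data);
  const int dim = init.size();
  std::vector<double> q(init.begin(), init.end());
  std::vector<double> g(dim), gp(dim), qp(dim), p(dim);
  std::vector<double> minv(dim, 1.0);  // inverse metric (posterior variances)

  double lq = lp_eval(d, q.data(), g.data());
  if (!std::isfinite(lq)) stop("non-finite log density at initial values");

  // dual averaging state
  double eps = init_step, mu_da = std::log(10.0 * init_step);
  double h_bar = 0.0, log_eps_bar = std::log(init_step);
  const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
  int da_count = 0;

  // metric estimation window
  int win_lo = n_warmup / 4, win_hi = (3 * n_warmup) / 4;
  std::vector<double> acc_m(dim, 0.0), acc_s(dim, 0.0);
  int acc_n = 0;

  NumericMatrix draws(n_sample, dim);
  int n_div = 0;
  double acc_sum = 0.0; int acc_cnt = 0;

  int total = n_warmup + n_sample;
  for (int it = 0; it < total; ++it) {
    bool warm = it < n_warmup;
    // momentum: p ~ N(0, M) with M = diag(1/minv)
    double ke0 = 0.0;
    for (int j = 0; j < dim; ++j) {
      p[j] = norm_rand() / std::sqrt(minv[j]);
      ke0 += 0.5 * p[j] * p[j] * minv[j];
    }
    int L = 1 + (int)std::floor(unif_rand() * L_max);
    std::copy(q.begin(), q.end(), qp.begin());
    std::copy(g.begin(), g.end(), gp.begin());
    double lqp = lq;
    bool bad = false;
    for (int s = 0; s < L; ++s) {
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * gp[j];
      for (int j = 0; j < dim; ++j) qp[j] += eps * minv[j] * p[j];
      std::fill(gp.begin(), gp.end(), 0.0);
      lqp = lp_eval(d, qp.data(), gp.data());
      if (!std::isfinite(lqp)) { bad = true; break; }
      for (int j = 0; j < dim; ++j) p[j] += 0.5 * eps * gp[j];
    }
    double alpha;
    if (bad) { alpha = 0.0; if (!warm) ++n_div; }
    else {
      double ke1 = 0.0;
      for (int j = 0; j < dim; ++j) ke1 += 0.5 * p[j] * p[j] * minv[j];
      double dH = (lqp - ke1) - (lq - ke0);
      if (dH > 0) alpha = 1.0;
      else if (dH < -1000.0) { alpha = 0.0; if (!warm) ++n_div; }
      else alpha = std::exp(dH);
      if (unif_rand() < alpha) {
        std::swap(q, qp); std::swap(g, gp); lq = lqp;
      }
    }
    if (warm) {
      // dual averaging
      ++da_count;
      double eta = 1.0 / (da_count + t0);
      h_bar = (1.0 - eta) * h_bar + eta * (target_accept - alpha);
      double log_eps = mu_da - std::sqrt((double)da_count) / gamma * h_bar;
      double w = std::pow((double)da_count, -kappa);
      log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
      eps = std::exp(log_eps);
      if (it >= win_lo && it < win_hi) {
        ++acc_n;
        for (int j = 0; j < dim; ++j) {
          double dlt = q[j] - acc_m[j];
          acc_m[j] += dlt / acc_n;
          acc_s[j] += dlt * (q[j] - acc_m[j]);
        }
      }
      if (it == win_hi - 1 && acc_n > 10) {
        for (int j = 0; j < dim; ++j) {
          double v = acc_s[j] / (acc_n - 1);
          // regularize toward unit variance
          minv[j] = (acc_n * v + 5.0) / (acc_n + 5.0);
          if (minv[j] < 1e-6) minv[j] = 1e-6;
        }
        // restart step-size adaptation under the new metric
        da_count = 0; h_bar = 0.0;
        mu_da = std::log(10.0 * eps);
        log_eps_bar = std::log(eps);
      }
      if (it == n_warmup - 1) eps = std::exp(log_eps_bar);
    } else {
      acc_sum += alpha; ++acc_cnt;
      for (int j = 0; j < dim; ++j) draws(it - n_warmup, j) = q[j];
    }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["draws"] = draws,
    _["step_size"] = eps,
    _["accept_rate"] = acc_cnt ? acc_sum / acc_cnt : NA_REAL,
    _["n_divergent"] = n_div,
    _["inv_metric"] = NumericVector(minv.begin(), minv.end()));
}
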