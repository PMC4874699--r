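// Blocked adaptive random-walk Metropolis core for the population-policy
// state-space model. The joint log-posterior evaluated here must agree with
// the R-level joint_logposterior() (natural scale) to numerical precision;
// a unit test enforces that. Sampling happens on transformed scales
// (log for positive parameters and latent populations, logit for the
// bounded count factors), with Jacobians added to the target.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct SSM {
  int S, T;
  NumericMatrix ymin, ymax, H, D; // S x T; counts NA where unobserved
  NumericVector pr;               // hyperparameters, fixed order (see R side)
  NumericVector init_meanlog;     // length S
  double init_sdlog, floor_eps;
};

// pr layout:
// 0 b0_mean 1 b0_sd 2 b1_mean 3 b1_sd 4 g_mean 5 g_sd 6 g_lower
// 7 sproc_scale 8 somin_scale 9 somax_scale
// 10 thmin_lo 11 thmin_hi 12 thmax_lo 13 thmax_hi

struct Par {
  std::vector<double> b0; // S
  double b1, gam, sproc, thmin, thmax, somin, somax;
  std::vector<double> N;  // S*T natural scale
};

inline double halfnorm_ld(double x, double scale) {
  if (x < 0) return R_NegInf;
  return std::log(2.0) + R::dnorm(x, 0.0, scale, 1);
}
inline double truncnorm_ld(double x, double mean, double sd, double lower) {
  if (x < lower) return R_NegInf;
  return R::dnorm(x, mean, sd, 1) - R::pnorm(lower, mean, sd, 0, 1);
}
inline double unif_ld(double x, double lo, double hi) {
  if (x < lo || x > hi) return R_NegInf;
  return -std::log(hi - lo);
}

SSM make_ssm(List model) {
  SSM m;
  m.S = as<int>(model["S"]);
  m.T = as<int>(model["T"]);
  m.ymin = as<NumericMatrix>(model["ymin"]);
  m.ymax = as<NumericMatrix>(model["ymax"]);
  m.H = as<NumericMatrix>(model["H"]);
  m.D = as<NumericMatrix>(model["D"]);
  m.pr = as<NumericVector>(model["pr"]);
  m.init_meanlog = as<NumericVector>(model["init_meanlog"]);
  m.init_sdlog = as<double>(model["init_sdlog"]);
  m.floor_eps = as<double>(model["floor_eps"]);
  return m;
}

Par unpack(const SSM& m, const NumericVector& x) {
  Par p;
  p.b0.resize(m.S);
  for (int s = 0; s < m.S; ++s) p.b0[s] = x[s];
  p.b1 = x[m.S]; p.gam = x[m.S + 1]; p.sproc = x[m.S + 2];
  p.thmin = x[m.S + 3]; p.thmax = x[m.S + 4];
  p.somin = x[m.S + 5]; p.somax = x[m.S + 6];
  p.N.resize(m.S * m.T);
  for (int k = 0; k < m.S * m.T; ++k) p.N[k] = x[m.S + 7 + k];
  return p;
}

double lp_priors(const SSM& m, const Par& p) {
  double lp = 0.0;
  for (int s = 0; s < m.S; ++s) lp += R::dnorm(p.b0[s], m.pr[0], m.pr[1], 1);
  lp += R::dnorm(p.b1, m.pr[2], m.pr[3], 1);
  lp += truncnorm_ld(p.gam, m.pr[4], m.pr[5], m.pr[6]);
  lp += halfnorm_ld(p.sproc, m.pr[7]);
  lp += unif_ld(p.thmin, m.pr[10], m.pr[11]);
  lp += unif_ld(p.thmax, m.pr[12], m.pr[13]);
  lp += halfnorm_ld(p.somin, m.pr[8]);
  lp += halfnorm_ld(p.somax, m.pr[9]);
  return lp;
}

inline double lp_init(const SSM& m, const Par& p, int s) {
  return R::dlnorm(p.N[s * m.T], m.init_meanlog[s], m.init_sdlog, 1);
}

// process term for year t (t >= 1, 0-based)
inline double lp_proc(const SSM& m, const Par& p, int s, int t) {
  double r = p.b0[s] + p.b1 * m.D(s, t);
  double nd = p.N[s * m.T + t - 1] * std::exp(r) - p.gam * m.H(s, t);
  if (nd < m.floor_eps) nd = m.floor_eps;
  return R::dlnorm(p.N[s * m.T + t], std::log(nd), p.sproc, 1);
}

inline double lp_obs(double y, double Ntrue, double theta, double sobs) {
  if (ISNAN(y)) return 0.0;
  double mu = theta * Ntrue;
  if (mu <= 0) return R_NegInf;
  return R::dnbinom_mu(y, mu * mu / (sobs * sobs), mu, 1);
}

double lp_full(const SSM& m, const Par& p) {
  if (p.sproc <= 0 || p.somin <= 0 || p.somax <= 0) return R_NegInf;
  for (int k = 0; k < m.S * m.T; ++k)
    if (!R_finite(p.N[k]) || p.N[k] <= 0) return R_NegInf;
  double lp = lp_priors(m, p);
  if (!R_finite(lp)) return R_NegInf;
  for (int s = 0; s < m.S; ++s) {
    lp += lp_init(m, p, s);
    for (int t = 1; t < m.T; ++t) lp += lp_proc(m, p, s, t);
    for (int t = 0; t < m.T; ++t) {
      lp += lp_obs(m.ymin(s, t), p.N[s * m.T + t], p.thmin, p.somin);
      lp += lp_obs(m.ymax(s, t), p.N[s * m.T + t], p.thmax, p.somax);
    }
    if (!R_finite(lp)) return R_NegInf;
  }
  return lp;
}

// ---- block structure ----------------------------------------------------
// parameter index k (flat order matching unpack):
//   0..S-1   beta0[s]        identity
//   S        beta1           identity
//   S+1      gamma           log
//   S+2      sigma_proc      log
//   S+3      theta_min       logit on (lo, hi)
//   S+4      theta_max       logit on (lo, hi)
//   S+5      sigma_obs_min   log
//   S+6      sigma_obs_max   log
//   S+7+..   latent N[s,t]   log

enum Trans { IDENT, LOG, LOGIT_MIN, LOGIT_MAX };

inline Trans trans_of(const SSM& m, int k) {
  if (k <= m.S) return IDENT;
  if (k == m.S + 1 || k == m.S + 2 || k == m.S + 5 || k == m.S + 6) return LOG;
  if (k == m.S + 3) return LOGIT_MIN;
  if (k == m.S + 4) return LOGIT_MAX;
  return LOG; // latents
}

inline double to_natural(const SSM& m, int k, double x) {
  switch (trans_of(m, k)) {
  case IDENT: return x;
  case LOG: return std::exp(x);
  case LOGIT_MIN: {
    double lo = m.pr[10], hi = m.pr[11];
    return lo + (hi - lo) / (1.0 + std::exp(-x));
  }
  case LOGIT_MAX: {
    double lo = m.pr[12], hi = m.pr[13];
    return lo + (hi - lo) / (1.0 + std::exp(-x));
  }
  }
  return x;
}

inline double to_sampling(const SSM& m, int k, double v) {
  switch (trans_of(m, k)) {
  case IDENT: return v;
  case LOG: return std::log(v);
  case LOGIT_MIN: {
    double lo = m.pr[10], hi = m.pr[11];
    return std::log((v - lo) / (hi - v));
  }
  case LOGIT_MAX: {
    double lo = m.pr[12], hi = m.pr[13];
    return std::log((v - lo) / (hi - v));
  }
  }
  return v;
}

inline double log_jacobian(const SSM& m, int k, double x, double v) {
  switch (trans_of(m, k)) {
  case IDENT: return 0.0;
  case LOG: return x;
  case LOGIT_MIN: {
    double lo = m.pr[10], hi = m.pr[11];
    return std::log((v - lo) * (hi - v) / (hi - lo));
  }
  case LOGIT_MAX: {
    double lo = m.pr[12], hi = m.pr[13];
    return std::log((v - lo) * (hi - v) / (hi - lo));
  }
  }
  return 0.0;
}

// log target restricted to the terms involving parameter k (plus its own
// prior and Jacobian); x is the sampling-scale value, p must already hold
// the corresponding natural value.
double lp_local(const SSM& m, const Par& p, int k, double x) {
  int S = m.S, T = m.T;
  double lp = 0.0;
  if (k < S) { // beta0[s]
    lp = R::dnorm(p.b0[k], m.pr[0], m.pr[1], 1);
    for (int t = 1; t < T; ++t) lp += lp_proc(m, p, k, t);
    return lp;
  }
  if (k == S) { // beta1
    lp = R::dnorm(p.b1, m.pr[2], m.pr[3], 1);
    for (int s = 0; s < S; ++s)
      for (int t = 1; t < T; ++t) lp += lp_proc(m, p, s, t);
    return lp;
  }
  if (k == S + 1) { // gamma (log scale)
    lp = truncnorm_ld(p.gam, m.pr[4], m.pr[5], m.pr[6]) + x;
    for (int s = 0; s < S; ++s)
      for (int t = 1; t < T; ++t) lp += lp_proc(m, p, s, t);
    return lp;
  }
  if (k == S + 2) { // sigma_proc (log scale)
    lp = halfnorm_ld(p.sproc, m.pr[7]) + x;
    for (int s = 0; s < S; ++s)
      for (int t = 1; t < T; ++t) lp += lp_proc(m, p, s, t);
    return lp;
  }
  if (k == S + 3) { // theta_min (logit scale)
    lp = unif_ld(p.thmin, m.pr[10], m.pr[11]) +
      log_jacobian(m, k, x, p.thmin);
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T; ++t)
        lp += lp_obs(m.ymin(s, t), p.N[s * T + t], p.thmin, p.somin);
    return lp;
  }
  if (k == S + 4) { // theta_max
    lp = unif_ld(p.thmax, m.pr[12], m.pr[13]) +
      log_jacobian(m, k, x, p.thmax);
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T; ++t)
        lp += lp_obs(m.ymax(s, t), p.N[s * T + t], p.thmax, p.somax);
    return lp;
  }
  if (k == S + 5) { // sigma_obs_min
    lp = halfnorm_ld(p.somin, m.pr[8]) + x;
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T; ++t)
        lp += lp_obs(m.ymin(s, t), p.N[s * T + t], p.thmin, p.somin);
    return lp;
  }
  if (k == S + 6) { // sigma_obs_max
    lp = halfnorm_ld(p.somax, m.pr[9]) + x;
    for (int s = 0; s < S; ++s)
      for (int t = 0; t < T; ++t)
        lp += lp_obs(m.ymax(s, t), p.N[s * T + t], p.thmax, p.somax);
    return lp;
  }
  // latent N[s,t], sampled as log N: Jacobian + local chain and obs terms
  int idx = k - (S + 7);
  int s = idx / T, t = idx % T;
  lp = x; // log-Jacobian of exp()
  lp += (t == 0) ? lp_init(m, p, s) : lp_proc(m, p, s, t);
  if (t < T - 1) lp += lp_proc(m, p, s, t + 1);
  lp += lp_obs(m.ymin(s, t), p.N[s * T + t], p.thmin, p.somin);
  lp += lp_obs(m.ymax(s, t), p.N[s * T + t], p.thmax, p.somax);
  return lp;
}

void set_natural(const SSM& m, Par& p, int k, double v) {
  int S = m.S;
  if (k < S) p.b0[k] = v;
  else if (k == S) p.b1 = v;
  else if (k == S + 1) p.gam = v;
  else if (k == S + 2) p.sproc = v;
  else if (k == S + 3) p.thmin = v;
  else if (k == S + 4) p.thmax = v;
  else if (k == S + 5) p.somin = v;
  else if (k == S + 6) p.somax = v;
  else p.N[k - (S + 7)] = v;
}

double get_natural(const SSM& m, const Par& p, int k);

// full log target on the sampling scale (natural posterior + Jacobians)
double lp_total(const SSM& m, const Par& p, const std::vector<double>& x) {
  double lp = lp_full(m, p);
  if (!R_finite(lp)) return R_NegInf;
  int npar = m.S + 7 + m.S * m.T;
  for (int k = 0; k < npar; ++k) {
    double v = get_natural(m, p, k);
    lp += log_jacobian(m, k, x[k], v);
  }
  return lp;
}

double get_natural(const SSM& m, const Par& p, int k) {
  int S = m.S;
  if (k < S) return p.b0[k];
  if (k == S) return p.b1;
  if (k == S + 1) return p.gam;
  if (k == S + 2) return p.sproc;
  if (k == S + 3) return p.thmin;
  if (k == S + 4) return p.thmax;
  if (k == S + 5) return p.somin;
  if (k == S + 6) return p.somax;
  return p.N[k - (S + 7)];
}

} // namespace

// Natural-scale joint log-posterior (priors + initial-condition + process +
// observation terms); must match the R reference implementation.
// [[Rcpp::export]]
double cpp_ssm_logposterior(NumericVector par, List model) {
  SSM m = make_ssm(model);
  Par p = unpack(m, par);
  return lp_full(m, p);
}

// Component-wise adaptive random-walk Metropolis. init: n_chains x npar,
// NATURAL scale. fixed: parameters held at their init value. Returns
// per-chain matrices of retained natural-scale draws plus acceptance rates.
// [[Rcpp::export]]
List cpp_ssm_sample(List model, NumericMatrix init, LogicalVector fixed,
                    int n_adapt, int n_iter, int thin,
                    double target_acc = 0.3, double init_step = 0.1) {
  SSM m = make_ssm(model);
  const int npar = m.S + 7 + m.S * m.T;
  if (init.ncol() != npar) stop("init has wrong number of columns");
  const int n_chains = init.nrow();
  const int n_ret = n_iter / thin;

  RNGScope scope;
  List chains(n_chains);
  NumericMatrix acc_rate(n_chains, npar);

  for (int c = 0; c < n_chains; ++c) {
    // sampling-scale state
    std::vector<double> x(npar);
    NumericVector nat0 = init(c, _);
    Par p = unpack(m, nat0);
    for (int k = 0; k < npar; ++k) x[k] = to_sampling(m, k, nat0[k]);
    if (!R_finite(lp_full(m, p)))
      stop("initialization gave a non-finite log-posterior in chain %d", c + 1);

    std::vector<double> lstep(npar, std::log(init_step));
    std::vector<long> n_acc(npar, 0), n_prop(npar, 0);
    // scale-ridge direction: latents up, count factors down; fixed frozen
    std::vector<double> sdir(npar, 0.0);
    int scale_dim = 0;
    for (int k = m.S + 7; k < npar; ++k)
      if (!fixed[k]) { sdir[k] = 1.0; scale_dim++; }
    if (!fixed[m.S + 3]) { sdir[m.S + 3] = -1.0; }
    if (!fixed[m.S + 4]) { sdir[m.S + 4] = -1.0; }
    double lstep_scale = std::log(init_step);
    long n_acc_scale = 0, n_prop_scale = 0;
    NumericMatrix out(n_ret, npar);
    int ret = 0;

    for (int it = 0; it < n_adapt + n_iter; ++it) {
      bool adapting = it < n_adapt;
      double rm = adapting ? std::pow((double)(it + 1), -0.6) : 0.0;
      for (int k = 0; k < npar; ++k) {
        if (fixed[k]) continue;
        double lp0 = lp_local(m, p, k, x[k]);
        double xn = x[k] + std::exp(lstep[k]) * R::norm_rand();
        double vn = to_natural(m, k, xn);
        double vold = get_natural(m, p, k);
        set_natural(m, p, k, vn);
        double lp1 = lp_local(m, p, k, xn);
        double a = std::exp(std::min(0.0, lp1 - lp0));
        if (!R_finite(lp1)) a = 0.0;
        if (R::unif_rand() < a) {
          x[k] = xn;
        } else {
          set_natural(m, p, k, vold);
        }
        if (adapting) {
          lstep[k] += rm * (a - target_acc);
          if (lstep[k] < -12.0) lstep[k] = -12.0;
          if (lstep[k] > 5.0) lstep[k] = 5.0;
        } else {
          n_prop[k]++;
          if (x[k] == xn) n_acc[k]++;
        }
      }
      // joint scale block: shift all latent log-populations together and the
      // count factors oppositely, along the posterior's scale ridge
      if (scale_dim > 0) {
        double lp0 = lp_total(m, p, x);
        double u = std::exp(lstep_scale) * R::norm_rand();
        std::vector<double> xs = x;
        Par ps = p;
        for (int k = 0; k < npar; ++k) {
          if (sdir[k] == 0.0) continue;
          xs[k] = x[k] + sdir[k] * u;
          set_natural(m, ps, k, to_natural(m, k, xs[k]));
        }
        double lp1 = lp_total(m, ps, xs);
        double a = R_finite(lp1) ? std::exp(std::min(0.0, lp1 - lp0)) : 0.0;
        if (R::unif_rand() < a) {
          x = xs;
          p = ps;
          if (!adapting) n_acc_scale++;
        }
        if (adapting) {
          lstep_scale += rm * (a - target_acc);
          if (lstep_scale < -12.0) lstep_scale = -12.0;
          if (lstep_scale > 5.0) lstep_scale = 5.0;
        } else {
          n_prop_scale++;
        }
      }
      if (!adapting && ((it - n_adapt + 1) % thin == 0) && ret < n_ret) {
        for (int k = 0; k < npar; ++k) out(ret, k) = get_natural(m, p, k);
        ret++;
      }
    }
    for (int k = 0; k < npar; ++k)
      acc_rate(c, k) = n_prop[k] > 0 ? (double)n_acc[k] / n_prop[k] : NA_REAL;
    chains[c] = out;
  }
  return List::create(_["chains"] = chains, _["acceptance"] = acc_rate);
}
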