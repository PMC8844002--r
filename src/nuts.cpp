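// Hierarchical two-alternative path-choice model and its No-U-Turn sampler.
//
// Unconstrained parameter vector z (length P = 2 + J + 1 + K):
//   z[0] = d, z[1] = e                      (population hyperparameters)
//   z[2 .. 2+J-1]  = log beta_j             (participant sun-cost factors)
//   z[2+J]         = logit rho              (perceived tree-shade intensity)
//   z[3+J .. end]  = log tau_k              (per-choice-set cost scales)
//
// Priors: d, e ~ Normal(0, 1); beta_j ~ Gamma(exp(d+e), exp(d-e)) (shape,
// rate); rho ~ Beta(1, 1); tau_k ~ Gamma(tau_shape, tau_rate). Likelihood:
// y_n ~ Bernoulli(sigmoid(-dc_n / tau_k)) with
// dc_n = beta_j * (dsun_n + (1 - rho) dtree_n) + dshade_n + rho dtree_n,
// the option cost difference on the pre-scaled length scale.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double x) {
  return x > 0 ? x + std::log1p(std::exp(-x)) : std::log1p(std::exp(x));
}
static inline double sigmoid(double x) {
  return x > 0 ? 1.0 / (1.0 + std::exp(-x)) : std::exp(x) / (1.0 + std::exp(x));
}

struct ChoiceModel {
  std::vector<double> dsun, dtree, dshade;
  std::vector<int> y, pid, setk;  // pid, setk zero-based
  int N, J, K, P;
  double tau_shape, tau_rate;

  explicit ChoiceModel(const List& m) {
    NumericVector ds = m["dsun"], dt = m["dtree"], dh = m["dshade"];
    IntegerVector yy = m["y"], pp = m["pid"], ss = m["setk"];
    dsun.assign(ds.begin(), ds.end());
    dtree.assign(dt.begin(), dt.end());
    dshade.assign(dh.begin(), dh.end());
    N = dsun.size();
    y.resize(N); pid.resize(N); setk.resize(N);
    for (int n = 0; n < N; ++n) {
      y[n] = yy[n]; pid[n] = pp[n] - 1; setk[n] = ss[n] - 1;
    }
    J = as<int>(m["J"]); K = as<int>(m["K"]);
    tau_shape = as<double>(m["tau_shape"]); tau_rate = as<double>(m["tau_rate"]);
    P = 2 + J + 1 + K;
  }

  // Log posterior density (up to a constant) and its gradient.
  double lp_grad(const std::vector<double>& z, std::vector<double>& g) const {
    std::fill(g.begin(), g.end(), 0.0);
    const double d = z[0], e = z[1];
    const double shape = std::exp(d + e), rate = std::exp(d - e);
    if (!R_finite(shape) || !R_finite(rate)) return R_NegInf;

    std::vector<double> beta(J), tau(K);
    double S1 = 0.0, S2 = 0.0;
    for (int j = 0; j < J; ++j) {
      beta[j] = std::exp(z[2 + j]);
      if (!R_finite(beta[j])) return R_NegInf;
      S1 += z[2 + j]; S2 += beta[j];
    }
    const double zrho = z[2 + J];
    const double rho = sigmoid(zrho);
    for (int k = 0; k < K; ++k) {
      tau[k] = std::exp(z[3 + J + k]);
      if (!R_finite(tau[k]) || tau[k] <= 0) return R_NegInf;
    }

    double lp = -0.5 * (d * d + e * e);
    g[0] = -d; g[1] = -e;

    // Gamma(shape, rate) prior on beta_j plus the log-beta Jacobian.
    const double lgr = std::log(rate), dig = R::digamma(shape);
    lp += J * (shape * lgr - R::lgammafn(shape)) + shape * S1 - rate * S2;
    g[0] += shape * (J * (lgr - dig) + S1) + J * shape - rate * S2;
    g[1] += shape * (J * (lgr - dig) + S1) - J * shape + rate * S2;
    for (int j = 0; j < J; ++j) g[2 + j] = shape - rate * beta[j];

    // Beta(1,1) prior on rho contributes only the logit Jacobian.
    lp += -softplus(zrho) - softplus(-zrho);
    g[2 + J] = 1.0 - 2.0 * rho;

    // Gamma(tau_shape, tau_rate) prior on tau_k plus log-tau Jacobian.
    for (int k = 0; k < K; ++k) {
      lp += tau_shape * z[3 + J + k] - tau_rate * tau[k];
      g[3 + J + k] = tau_shape - tau_rate * tau[k];
    }

    // Bernoulli likelihood through the logistic choice rule.
    const double drho = rho * (1.0 - rho);
    for (int n = 0; n < N; ++n) {
      const int j = pid[n], k = setk[n];
      const double w = dsun[n] + (1.0 - rho) * dtree[n];
      const double dc = beta[j] * w + dshade[n] + rho * dtree[n];
      const double eta = -dc / tau[k];
      lp += y[n] * eta - softplus(eta);
      const double r = y[n] - sigmoid(eta);
      g[2 + j] += r * (-w / tau[k]) * beta[j];
      g[2 + J] += r * (-(dtree[n] * (1.0 - beta[j])) / tau[k]) * drho;
      g[3 + J + k] += r * (dc / tau[k]);
    }
    if (!R_finite(lp)) return R_NegInf;
    return lp;
  }
};

// [[Rcpp::export(name = ".choice_logpost_cpp")]]
List choice_logpost_cpp(List model, NumericVector z) {
  ChoiceModel m(model);
  if ((int)z.size() != m.P) stop("z has length %d, expected %d", z.size(), m.P);
  std::vector<double> zz(z.begin(), z.end()), g(m.P, 0.0);
  double lp = m.lp_grad(zz, g);
  return List::create(_["lp"] = lp, _["grad"] = NumericVector(g.begin(), g.end()));
}

// ---------------------------------------------------------------------------
// NUTS (Hoffman & Gelman 2014, Algorithm 6) with dual-averaging step-size
// adaptation and windowed diagonal mass-matrix estimation during warmup.

struct State {
  std::vector<double> z, p, g;
  double lp;
};

struct Nuts {
  const ChoiceModel& m;
  int P;
  std::vector<double> m_inv;  // diagonal inverse mass
  double eps;
  int max_depth;
  double delta;  // target acceptance statistic
  // dual averaging state
  double mu, log_eps_bar, Hbar;
  int da_count;
  // per-iteration accumulators
  double alpha_sum; int n_alpha;
  bool divergent;

  Nuts(const ChoiceModel& model, double target_accept, int max_treedepth)
    : m(model), P(model.P), m_inv(model.P, 1.0), eps(1.0),
      max_depth(max_treedepth), delta(target_accept),
      mu(0), log_eps_bar(0), Hbar(0), da_count(0),
      alpha_sum(0), n_alpha(0), divergent(false) {}

  double kinetic(const std::vector<double>& p) const {
    double k = 0;
    for (int i = 0; i < P; ++i) k += p[i] * p[i] * m_inv[i];
    return 0.5 * k;
  }

  void sample_momentum(std::vector<double>& p) const {
    for (int i = 0; i < P; ++i) p[i] = R::norm_rand() / std::sqrt(m_inv[i]);
  }

  // One leapfrog step of signed size e, in place.
  void leapfrog(State& s, double e) const {
    for (int i = 0; i < P; ++i) s.p[i] += 0.5 * e * s.g[i];
    for (int i = 0; i < P; ++i) s.z[i] += e * m_inv[i] * s.p[i];
    s.lp = m.lp_grad(s.z, s.g);
    if (!R_finite(s.lp)) { s.lp = R_NegInf; std::fill(s.g.begin(), s.g.end(), 0.0); }
    for (int i = 0; i < P; ++i) s.p[i] += 0.5 * e * s.g[i];
  }

  bool no_uturn(const std::vector<double>& zminus, const std::vector<double>& zplus,
                const std::vector<double>& pminus, const std::vector<double>& pplus) const {
    double a = 0, b = 0;
    for (int i = 0; i < P; ++i) {
      double dz = zplus[i] - zminus[i];
      a += dz * m_inv[i] * pminus[i];
      b += dz * m_inv[i] * pplus[i];
    }
    return a >= 0 && b >= 0;
  }

  // Recursive doubling (Hoffman & Gelman 2014, BuildTree). Builds a subtree
  // of 2^depth leapfrog steps in direction v from `start`; reports the
  // subtree's backward/forward ends, a proposal drawn uniformly from the
  // slice-admissible states, and the count of admissible states. Returns
  // false when the subtree diverged or made a U-turn.
  bool build_tree(const State& start, int v, int depth, double logu, double H0,
                  State& s_minus, State& s_plus, State& prop, double& n_in) {
    if (depth == 0) {
      State s = start;
      leapfrog(s, v * eps);
      double H1 = s.lp - kinetic(s.p);
      if (!R_finite(H1)) H1 = R_NegInf;
      n_in = (logu <= H1) ? 1.0 : 0.0;
      bool ok = (logu < H1 + 1000.0);
      if (!ok) divergent = true;
      double a = std::exp(std::min(0.0, H1 - H0));
      alpha_sum += R_finite(a) ? a : 0.0;
      n_alpha += 1;
      s_minus = s; s_plus = s; prop = s;
      return ok;
    }
    State m1, p1, prop1; double n1 = 0;
    bool ok1 = build_tree(start, v, depth - 1, logu, H0, m1, p1, prop1, n1);
    if (!ok1) { s_minus = m1; s_plus = p1; prop = prop1; n_in = n1; return false; }
    const State& far = (v == 1) ? p1 : m1;
    State m2, p2, prop2; double n2 = 0;
    bool ok2 = build_tree(far, v, depth - 1, logu, H0, m2, p2, prop2, n2);
    if (v == 1) { s_minus = m1; s_plus = p2; } else { s_minus = m2; s_plus = p1; }
    prop = prop1;
    if (n2 > 0 && R::unif_rand() < n2 / (n1 + n2)) prop = prop2;
    n_in = n1 + n2;
    return ok2 && no_uturn(s_minus.z, s_plus.z, s_minus.p, s_plus.p);
  }

  // Heuristic initial step size (Hoffman & Gelman, Algorithm 4).
  void find_reasonable_epsilon(const State& s0) {
    eps = 1.0;
    State s = s0;
    sample_momentum(s.p);
    double H0 = s.lp - kinetic(s.p);
    State s1 = s;
    leapfrog(s1, eps);
    double H1 = s1.lp - kinetic(s1.p);
    double logr = R_finite(H1) ? H1 - H0 : R_NegInf;
    double a = (logr > std::log(0.5)) ? 1.0 : -1.0;
    for (int it = 0; it < 50 && a * logr > -a * std::log(2.0); ++it) {
      eps *= std::pow(2.0, a);
      s1 = s;
      leapfrog(s1, eps);
      H1 = s1.lp - kinetic(s1.p);
      logr = R_finite(H1) ? H1 - H0 : R_NegInf;
    }
    if (!R_finite(eps) || eps <= 0) eps = 1e-3;
  }

  void da_init() { mu = std::log(10.0 * eps); log_eps_bar = 0.0; Hbar = 0.0; da_count = 0; }

  void da_update() {
    const double gamma = 0.05, t0 = 10.0, kappa = 0.75;
    da_count += 1;
    double a = n_alpha > 0 ? alpha_sum / n_alpha : 0.0;
    Hbar = (1.0 - 1.0 / (da_count + t0)) * Hbar + (delta - a) / (da_count + t0);
    double log_eps = mu - std::sqrt((double)da_count) / gamma * Hbar;
    double w = std::pow((double)da_count, -kappa);
    log_eps_bar = w * log_eps + (1.0 - w) * log_eps_bar;
    eps = std::exp(log_eps);
  }

  // One NUTS transition from s (updated in place). Returns tree depth used.
  int transition(State& s) {
    divergent = false; alpha_sum = 0; n_alpha = 0;
    sample_momentum(s.p);
    double H0 = s.lp - kinetic(s.p);
    double logu = H0 - R::exp_rand();
    State sm = s, sp = s, prop = s;
    double n = 1.0;
    int depth = 0;
    bool ok = true;
    while (ok && depth < max_depth) {
      int v = (R::unif_rand() < 0.5) ? -1 : 1;
      const State& start = (v == 1) ? sp : sm;
      State m2, p2, prop1 = prop; double n1 = 0;
      bool ok1 = build_tree(start, v, depth, logu, H0, m2, p2, prop1, n1);
      if (v == 1) sp = p2; else sm = m2;
      if (ok1 && n1 > 0 && R::unif_rand() < std::min(1.0, n1 / n)) prop = prop1;
      n += n1;
      ok = ok1 && no_uturn(sm.z, sp.z, sm.p, sp.p);
      depth += 1;
    }
    s = prop;
    return depth;
  }
};

// [[Rcpp::export(name = ".run_nuts_chain_cpp")]]
List run_nuts_chain_cpp(List model, NumericVector init, int tune, int draws,
                        double target_accept, int max_depth) {
  ChoiceModel m(model);
  if ((int)init.size() != m.P) stop("init has length %d, expected %d", init.size(), m.P);
  Nuts nuts(m, target_accept, max_depth);

  State s;
  s.z.assign(init.begin(), init.end());
  s.p.assign(m.P, 0.0);
  s.g.assign(m.P, 0.0);
  s.lp = m.lp_grad(s.z, s.g);
  if (!R_finite(s.lp)) stop("initial point has non-finite log posterior");

  nuts.find_reasonable_epsilon(s);
  nuts.da_init();

  // Stan-style warmup schedule: step-size-only buffers around expanding
  // variance-estimation windows (skipped when warmup is short).
  int init_buf = 75, term_buf = 50, base_win = 25;
  bool adapt_mass = tune >= init_buf + term_buf + base_win;
  int win_start = init_buf, win_size = base_win;
  int win_end = adapt_mass ? win_start + win_size : tune + 1;
  std::vector<double> w_mean(m.P, 0.0), w_m2(m.P, 0.0);
  int w_n = 0;

  double accept_sum = 0.0;
  int n_div_warm = 0;

  for (int it = 0; it < tune; ++it) {
    nuts.transition(s);
    if (nuts.divergent) ++n_div_warm;
    nuts.da_update();
    if (adapt_mass && it >= win_start && it < win_end) {
      ++w_n;  // Welford accumulation of the unconstrained draws
      for (int i = 0; i < m.P; ++i) {
        double dlt = s.z[i] - w_mean[i];
        w_mean[i] += dlt / w_n;
        w_m2[i] += dlt * (s.z[i] - w_mean[i]);
      }
      if (it == win_end - 1) {
        if (w_n > 1) {
          for (int i = 0; i < m.P; ++i) {
            double var = w_m2[i] / (w_n - 1);
            nuts.m_inv[i] = var * w_n / (w_n + 5.0) + 1e-3 * (5.0 / (w_n + 5.0));
          }
        }
        std::fill(w_mean.begin(), w_mean.end(), 0.0);
        std::fill(w_m2.begin(), w_m2.end(), 0.0);
        w_n = 0;
        win_start = win_end;
        win_size *= 2;
        win_end = win_start + win_size;
        // last window absorbs the remainder before the terminal buffer
        if (win_end + win_size > tune - term_buf) win_end = tune - term_buf;
        if (win_end <= win_start) win_end = tune + 1;  // no further windows
        nuts.find_reasonable_epsilon(s);
        nuts.da_init();
      }
    }
  }
  nuts.eps = tune > 0 ? std::exp(nuts.log_eps_bar) : nuts.eps;

  NumericMatrix out(draws, m.P);
  int n_div = 0;
  for (int it = 0; it < draws; ++it) {
    int dep = nuts.transition(s);
    (void)dep;
    if (nuts.divergent) ++n_div;
    accept_sum += nuts.n_alpha > 0 ? nuts.alpha_sum / nuts.n_alpha : 0.0;
    for (int i = 0; i < m.P; ++i) out(it, i) = s.z[i];
  }

  return List::create(
    _["draws"] = out,
    _["divergent"] = n_div,
    _["divergent_warmup"] = n_div_warm,
    _["step_size"] = nuts.eps,
    _["accept_stat"] = draws > 0 ? accept_sum / draws : NA_REAL);
}
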