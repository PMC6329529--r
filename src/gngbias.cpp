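#include <Rcpp.h>
using namespace Rcpp;

// Core natural-space parameter layout shared by all model variants:
// pars = [rho_app, rho_av, lam_app, lam_av, b_go, b_pav, xi, m_ret]
// Valence-invariant models simply repeat the shared value in both slots.

static inline double p_go_soft(double qg, double qn, double xi) {
  double m = qg > qn ? qg : qn;
  double eg = std::exp(qg - m), en = std::exp(qn - m);
  return (1.0 - xi) * eg / (eg + en) + 0.5 * xi;
}

// Sequential session log-likelihood.  action: 1 = go, 2 = nogo, 0 = missing.
// valence: 1 = win trial, 0 = avoid-loss trial.  skip: 1-based trial positions
// whose log-probability is excluded from `total` (their realized action and
// outcome still drive learning: "informed" handling).
// [[Rcpp::export]]
List cpp_session_loglik(IntegerVector stim, IntegerVector action,
                        IntegerVector valence, NumericVector outcome,
                        NumericVector pars, bool forget, bool decay_v,
                        IntegerVector skip) {
  int n = stim.size();
  double rho_app = pars[0], rho_av = pars[1];
  double lam_app = pars[2], lam_av = pars[3];
  double b_go = pars[4], b_pav = pars[5], xi = pars[6], m_ret = pars[7];

  std::vector<bool> skipped(n + 1, false);
  for (int i = 0; i < skip.size(); ++i)
    if (skip[i] >= 1 && skip[i] <= n) skipped[skip[i]] = true;

  double Q[4][2] = {{0, 0}, {0, 0}, {0, 0}, {0, 0}};
  double V[4] = {0, 0, 0, 0};
  NumericVector logp(n, NA_REAL);
  double total = 0.0;

  for (int t = 0; t < n; ++t) {
    int a = action[t];
    if (a == 0) continue;  // missing response: state carried forward intact
    int s = stim[t] - 1;
    double pg = p_go_soft(Q[s][0] + b_go + b_pav * V[s], Q[s][1], xi);
    double lp = (a == 1) ? std::log(pg) : std::log1p(-pg);
    logp[t] = lp;
    if (!skipped[t + 1]) total += lp;

    double rho = valence[t] == 1 ? rho_app : rho_av;
    double lam = valence[t] == 1 ? lam_app : lam_av;
    double target = rho * outcome[t];
    int ai = a - 1;
    if (forget) {
      for (int ss = 0; ss < 4; ++ss)
        for (int aa = 0; aa < 2; ++aa)
          if (!(ss == s && aa == ai)) Q[ss][aa] *= m_ret;
      if (decay_v)
        for (int ss = 0; ss < 4; ++ss)
          if (ss != s) V[ss] *= m_ret;
    }
    Q[s][ai] += lam * (target - Q[s][ai]);
    V[s] += lam * (target - V[s]);
  }
  return List::create(_["total"] = total, _["trial_logp"] = logp);
}

// Session log-likelihood totals for a matrix of parameter draws (rows).
// [[Rcpp::export]]
NumericVector cpp_session_loglik_mat(IntegerVector stim, IntegerVector action,
                                     IntegerVector valence, NumericVector outcome,
                                     NumericMatrix pars, bool forget, bool decay_v,
                                     IntegerVector skip) {
  int nd = pars.nrow();
  NumericVector out(nd);
  for (int i = 0; i < nd; ++i) {
    NumericVector p = pars(i, _);
    List r = cpp_session_loglik(stim, action, valence, outcome, p, forget,
                                decay_v, skip);
    out[i] = as<double>(r["total"]);
  }
  return out;
}

// Simulate one session.  correct_go: 1 if the rewarded policy is go.
// valid: 1 if the better outcome for the chosen action is delivered.
// Uses R's RNG so set.seed() in R controls the draw.
// [[Rcpp::export]]
List cpp_simulate_session(IntegerVector stim, IntegerVector valence,
                          IntegerVector correct_go, IntegerVector valid,
                          NumericVector pars, bool forget, bool decay_v) {
  int n = stim.size();
  double rho_app = pars[0], rho_av = pars[1];
  double lam_app = pars[2], lam_av = pars[3];
  double b_go = pars[4], b_pav = pars[5], xi = pars[6], m_ret = pars[7];

  double Q[4][2] = {{0, 0}, {0, 0}, {0, 0}, {0, 0}};
  double V[4] = {0, 0, 0, 0};
  IntegerVector action(n);
  NumericVector outcome(n);

  for (int t = 0; t < n; ++t) {
    int s = stim[t] - 1;
    double pg = p_go_soft(Q[s][0] + b_go + b_pav * V[s], Q[s][1], xi);
    int a = (R::runif(0, 1) < pg) ? 1 : 2;
    bool correct = (a == 1) == (correct_go[t] == 1);
    double best = valence[t] == 1 ? 1.0 : 0.0;
    double worst = valence[t] == 1 ? 0.0 : -1.0;
    double r = (valid[t] == 1) == correct ? best : worst;
    action[t] = a;
    outcome[t] = r;

    double rho = valence[t] == 1 ? rho_app : rho_av;
    double lam = valence[t] == 1 ? lam_app : lam_av;
    double target = rho * r;
    int ai = a - 1;
    if (forget) {
      for (int ss = 0; ss < 4; ++ss)
        for (int aa = 0; aa < 2; ++aa)
          if (!(ss == s && aa == ai)) Q[ss][aa] *= m_ret;
      if (decay_v)
        for (int ss = 0; ss < 4; ++ss)
          if (ss != s) V[ss] *= m_ret;
    }
    Q[s][ai] += lam * (target - Q[s][ai]);
    V[s] += lam * (target - V[s]);
  }
  return List::create(_["action"] = action, _["outcome"] = outcome);
}

// ---------------------------------------------------------------------------
// Two-armed informed/agnostic hidden-trial audit.
//
// Learners make binary choices between actions with deterministic returns.
// learner codes: 0 = Rescorla-Wagner + softmax(tau); 1 = eta-greedy;
// 2 = observation-violating eta-greedy (exploratory actions update values
// only on better-than-expected prediction errors).
//
// Because returns are deterministic and Q0 = 0, a Q value after k applied
// updates at rate eps is r * (1 - (1-eps)^k); the hidden-trial state is fully
// described by the pair of applied-update counts, which keeps the agnostic
// marginalization over hidden action sequences enumerable.
// ---------------------------------------------------------------------------

struct HiddenState { int k1, k2; double logw; };

static inline double policy_p1(int learner, double q1, double q2, double tau,
                               double eta) {
  if (learner == 0) {
    // tau multiplies action values, playing the role the motivational
    // exchange rate plays in the full task models
    double d = tau * (q2 - q1);
    if (d > 500) return std::exp(-d) / (1.0 + std::exp(-d));
    return 1.0 / (1.0 + std::exp(d));
  }
  if (q1 > q2) return 1.0 - 0.5 * eta;
  if (q1 < q2) return 0.5 * eta;
  return 0.5;
}

// whether the chosen action's value update is applied
static inline bool update_applied(int learner, int a, double q1, double q2,
                                  double r) {
  if (learner != 2) return true;
  double qa = a == 0 ? q1 : q2;
  bool greedy = (a == 0) ? (q1 >= q2) : (q2 >= q1);
  if (greedy) return true;
  return (r - qa) > 0;  // exploratory: keep only better-than-expected PEs
}

static void enumerate_hidden(int learner, double eps, double tau, double eta,
                             double r1, double r2, int depth, int n_hidden,
                             int k1, int k2, double logw,
                             std::map<std::pair<int, int>, double>& acc) {
  if (logw < -34.0 * 2.302585) return;  // prune below 1e-34
  if (depth == n_hidden) {
    auto key = std::make_pair(k1, k2);
    auto it = acc.find(key);
    if (it == acc.end()) acc[key] = logw;
    else it->second = std::max(it->second, logw) +
      std::log1p(std::exp(-std::fabs(it->second - logw)));
    return;
  }
  double q1 = r1 * (1.0 - std::pow(1.0 - eps, k1));
  double q2 = r2 * (1.0 - std::pow(1.0 - eps, k2));
  double p1 = policy_p1(learner, q1, q2, tau, eta);
  if (p1 > 0)
    enumerate_hidden(learner, eps, tau, eta, r1, r2, depth + 1, n_hidden,
                     k1 + (update_applied(learner, 0, q1, q2, r1) ? 1 : 0), k2,
                     logw + std::log(p1), acc);
  if (p1 < 1)
    enumerate_hidden(learner, eps, tau, eta, r1, r2, depth + 1, n_hidden, k1,
                     k2 + (update_applied(learner, 1, q1, q2, r2) ? 1 : 0),
                     logw + std::log1p(-p1), acc);
}

static inline double lse(const std::vector<double>& v) {
  double m = R_NegInf;
  for (double x : v) if (x > m) m = x;
  if (!R_finite(m)) return R_NegInf;
  double s = 0;
  for (double x : v) s += std::exp(x - m);
  return m + std::log(s);
}

// [[Rcpp::export]]
List cpp_bias_experiment(int n_epochs, int n_trials, int n_hidden,
                         double eps_true, double tau, double eta, int learner,
                         NumericVector returns, NumericVector grid,
                         bool keep_grid) {
  int G = grid.size();
  double r1 = returns[0], r2 = returns[1];

  // hidden-state weights per grid point (epoch-independent)
  std::vector<std::vector<HiddenState>> states(G);
  for (int g = 0; g < G; ++g) {
    std::map<std::pair<int, int>, double> acc;
    enumerate_hidden(learner, grid[g], tau, eta, r1, r2, 0, n_hidden, 0, 0,
                     0.0, acc);
    for (auto& kv : acc)
      states[g].push_back({kv.first.first, kv.first.second, kv.second});
  }

  NumericVector eps_inf(n_epochs), eps_agn(n_epochs), eps_hid(n_epochs);
  NumericVector lph_inf(n_epochs), lph_agn(n_epochs);
  NumericMatrix gh, gvi, gva;
  if (keep_grid) {
    gh = NumericMatrix(n_epochs, G);
    gvi = NumericMatrix(n_epochs, G);
    gva = NumericMatrix(n_epochs, G);
  }

  std::vector<int> act(n_trials);
  std::vector<double> llh(G), llvi(G), llva(G), tmp1(G), tmp2(G);

  for (int e = 0; e < n_epochs; ++e) {
    // generate one epoch with the true learning rate
    {
      double q1 = 0, q2 = 0;
      for (int t = 0; t < n_trials; ++t) {
        double p1 = policy_p1(learner, q1, q2, tau, eta);
        int a = (R::runif(0, 1) < p1) ? 0 : 1;
        act[t] = a;
        double r = a == 0 ? r1 : r2;
        if (update_applied(learner, a, q1, q2, r)) {
          if (a == 0) q1 += eps_true * (r - q1);
          else q2 += eps_true * (r - q2);
        }
      }
    }

    for (int g = 0; g < G; ++g) {
      double eps = grid[g];
      // hidden replay (realized actions) and informed continuation
      double q1 = 0, q2 = 0, lh = 0, lv = 0;
      for (int t = 0; t < n_trials; ++t) {
        double p1 = policy_p1(learner, q1, q2, tau, eta);
        double lp = act[t] == 0 ? std::log(p1) : std::log1p(-p1);
        if (t < n_hidden) lh += lp; else lv += lp;
        double r = act[t] == 0 ? r1 : r2;
        if (update_applied(learner, act[t], q1, q2, r)) {
          if (act[t] == 0) q1 += eps * (r - q1);
          else q2 += eps * (r - q2);
        }
      }
      llh[g] = lh;
      llvi[g] = lv;

      // agnostic: marginalize the hidden action sequence
      std::vector<double> terms;
      terms.reserve(states[g].size());
      for (const HiddenState& st : states[g]) {
        double a1 = r1 * (1.0 - std::pow(1.0 - eps, st.k1));
        double a2 = r2 * (1.0 - std::pow(1.0 - eps, st.k2));
        double lvs = 0;
        for (int t = n_hidden; t < n_trials; ++t) {
          double p1 = policy_p1(learner, a1, a2, tau, eta);
          lvs += act[t] == 0 ? std::log(p1) : std::log1p(-p1);
          double r = act[t] == 0 ? r1 : r2;
          if (update_applied(learner, act[t], a1, a2, r)) {
            if (act[t] == 0) a1 += eps * (r - a1);
            else a2 += eps * (r - a2);
          }
        }
        terms.push_back(st.logw + lvs);
      }
      llva[g] = lse(terms);
    }

    int bi = 0, ba = 0, bh = 0;
    for (int g = 1; g < G; ++g) {
      if (llvi[g] > llvi[bi]) bi = g;
      if (llva[g] > llva[ba]) ba = g;
      if (llh[g] > llh[bh]) bh = g;
    }
    eps_inf[e] = grid[bi];
    eps_agn[e] = grid[ba];
    eps_hid[e] = grid[bh];

    for (int g = 0; g < G; ++g) { tmp1[g] = llh[g] + llvi[g]; tmp2[g] = llh[g] + llva[g]; }
    lph_inf[e] = lse(tmp1) - lse(llvi);
    lph_agn[e] = lse(tmp2) - lse(llva);

    if (keep_grid)
      for (int g = 0; g < G; ++g) { gh(e, g) = llh[g]; gvi(e, g) = llvi[g]; gva(e, g) = llva[g]; }
  }

  List out = List::create(
      _["eps_ml_informed"] = eps_inf, _["eps_ml_agnostic"] = eps_agn,
      _["eps_ml_hidden"] = eps_hid, _["log_ph_informed"] = lph_inf,
      _["log_ph_agnostic"] = lph_agn);
  if (keep_grid) {
    out["ll_hidden"] = gh;
    out["ll_visible_informed"] = gvi;
    out["ll_visible_agnostic"] = gva;
  }
  return out;
}
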