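// Trial-loop engines for the bandit agents.
//
// Two entry points:
//   bb_forward_cpp()  - run an agent through an observed choice/reward
//                       sequence, returning the negative log-likelihood of
//                       the choices and (optionally) per-trial latents.
//   bb_simulate_cpp() - run an agent in closed loop against the generative
//                       two-armed bandit environment, sampling choices and
//                       rewards; uses R's RNG so set.seed() governs it.
//
// Choices are coded -1 (left) / +1 (right); rewards 0/1. A missing choice
// is coded 0 and is skipped without any state update.

#include <Rcpp.h>
using namespace Rcpp;

static const double P_FLOOR = 1e-12;

static inline double sigmoid(double x) {
  if (x >= 0) {
    return 1.0 / (1.0 + std::exp(-x));
  } else {
    double e = std::exp(x);
    return e / (1.0 + e);
  }
}

struct Agent {
  int model; // 1 RL4p, 2 RLCF, 3 RFLR, 4 RLFQ3p, 5 RL_meta, 6 PearceHall,
             // 7 BIfp, 8 BRLfwr, 9 BRLfw, 10 BRLwrp
  // parameters (subset used per model)
  double a_pos, a_neg, beta, phi, alpha, tau, zeta, alpha_nu0, psi, q;
  double alpha_w, rho1, rho2;
  double q0; // forgetting attractor (PearceHall)
  // state
  double qL, qR; // action values for c = -1 / +1
  double Dr;     // RFLR value difference
  double b;      // belief P(z = +1)
  double w1, w2;
  double an_t;   // RL_meta adapted negative learning rate
  double omega;  // RL_meta expected uncertainty
  double anu_t;  // PearceHall associability

  void reset() {
    qL = 0.5; qR = 0.5;
    Dr = 0.0;
    b = 0.5;
    w1 = rho1; w2 = rho2;
    an_t = a_neg;
    omega = 0.0;
    anu_t = alpha_nu0;
  }

  double qval(int c) const {
    switch (model) {
      case 7: { // BIfp: implied expected reward under the belief
        double bc = (c == 1) ? b : 1.0 - b;
        return rho1 * bc + rho2 * (1.0 - bc);
      }
      case 8: case 9: case 10: {
        double bc = (c == 1) ? b : 1.0 - b;
        return w1 * bc + w2 * (1.0 - bc);
      }
      default:
        return (c == 1) ? qR : qL;
    }
  }

  // value difference entering the policy
  double policy_D() const {
    switch (model) {
      case 3: return Dr;
      case 7: return 2.0 * b - 1.0;
      default: return qval(1) - qval(-1);
    }
  }

  double policy_beta() const { return (model == 3) ? 1.0 : beta; }
  double policy_phi()  const { return (model == 4) ? 0.0 : phi; }

  // P(c_t = +1) given previous choice (0 if none)
  double p_right(int prev) const {
    return sigmoid(policy_beta() * policy_D() + policy_phi() * (double)prev);
  }

  // prediction error given observed reward, before any update
  double rpe(int c, int r) const {
    if (model == 3) return NA_REAL; // RFLR has no RPE formulation
    return (double)r - qval(c);
  }

  void belief_step(int c, int r) {
    // filter: multiply prior by reward likelihood, normalize
    double likP = (c == 1) ? ((r == 1) ? rho1 : 1.0 - rho1)
                           : ((r == 1) ? rho2 : 1.0 - rho2);
    double likM = (c == -1) ? ((r == 1) ? rho1 : 1.0 - rho1)
                            : ((r == 1) ? rho2 : 1.0 - rho2);
    double num = b * likP;
    double den = num + (1.0 - b) * likM;
    if (den <= 0.0) stop("belief normalizer is zero; rho2_model must be > 0");
    double post = num / den;
    // transition with switch probability q
    b = (1.0 - q) * post + q * (1.0 - post);
  }

  void update(int c, int r) {
    switch (model) {
      case 1: { // RL4p
        double d = (double)r - qval(c);
        double a = (d >= 0) ? a_pos : a_neg;
        if (c == 1) qR += a * d; else qL += a * d;
        break;
      }
      case 2: { // RLCF: counterfactual update with the same alpha_t
        double d = (double)r - qval(c);
        double a = (d >= 0) ? a_pos : a_neg;
        double dcf = (1.0 - (double)r) - qval(-c);
        if (c == 1) { qR += a * d; qL += a * dcf; }
        else        { qL += a * d; qR += a * dcf; }
        break;
      }
      case 3: { // RFLR
        Dr = std::exp(-1.0 / tau) * Dr + alpha * (double)r * (double)c;
        break;
      }
      case 4: { // RLFQ3p: forgetting of the unchosen value
        double d = (double)r - qval(c);
        double a = (d >= 0) ? a_pos : a_neg;
        if (c == 1) { qR += a * d; qL *= zeta; }
        else        { qL += a * d; qR *= zeta; }
        break;
      }
      case 5: { // RL_meta: delta -> nu -> alpha_minus -> omega -> Q
        double d = (double)r - qval(c);
        double nu = std::fabs(d) - omega;
        if (d < 0) {
          an_t = psi * (nu + a_neg) + (1.0 - psi) * an_t;
          if (an_t < 0.0) an_t = 0.0;
          if (an_t > 1.0) an_t = 1.0; // keep Q within the reward range
        }
        omega += alpha_nu0 * nu;
        double a = (d >= 0) ? a_pos : an_t;
        if (c == 1) { qR += a * d; qL *= zeta; }
        else        { qL += a * d; qR *= zeta; }
        break;
      }
      case 6: { // PearceHall: associability update precedes the Q step
        double d = (double)r - qval(c);
        anu_t += psi * (std::fabs(d) - anu_t);
        double a = anu_t * ((d >= 0) ? a_pos : a_neg);
        if (c == 1) { qR += a * d; qL = q0 + zeta * (qL - q0); }
        else        { qL += a * d; qR = q0 + zeta * (qR - q0); }
        break;
      }
      case 7: { // BIfp: pure inference
        belief_step(c, r);
        break;
      }
      case 8: case 9: case 10: { // BRL family
        double bc = (c == 1) ? b : 1.0 - b;
        double d = (double)r - (w1 * bc + w2 * (1.0 - bc));
        w1 += alpha_w * d * bc;
        if (model == 9 || model == 10) w2 += alpha_w * d * (1.0 - bc);
        belief_step(c, r);
        break;
      }
      default:
        stop("unknown model code");
    }
  }
};

static Agent make_agent(int model, NumericVector par, double rho1m, double rho2m,
                        int zeta_conv) {
  Agent ag;
  ag.model = model;
  ag.rho1 = rho1m; ag.rho2 = rho2m;
  ag.q0 = 0.5;
  ag.a_pos = ag.a_neg = ag.beta = ag.phi = ag.alpha = ag.tau = 0.0;
  ag.zeta = ag.alpha_nu0 = ag.psi = ag.q = ag.alpha_w = 0.0;
  switch (model) {
    case 1: case 2: // [a_pos, a_neg, beta, phi]
      if (par.size() != 4) stop("RL4p/RLCF expect 4 parameters");
      ag.a_pos = par[0]; ag.a_neg = par[1]; ag.beta = par[2]; ag.phi = par[3];
      break;
    case 3: // [alpha, phi, tau]
      if (par.size() != 3) stop("RFLR expects 3 parameters");
      ag.alpha = par[0]; ag.phi = par[1]; ag.tau = par[2];
      if (ag.tau <= 0) stop("tau must be > 0");
      break;
    case 4: // [a_pos, a_neg, beta]
      if (par.size() != 3) stop("RLFQ3p expects 3 parameters");
      ag.a_pos = par[0]; ag.a_neg = par[1]; ag.beta = par[2];
      ag.zeta = (zeta_conv == 0) ? 1.0 - (ag.a_pos + ag.a_neg) / 2.0
                                 : (ag.a_pos + ag.a_neg) / 2.0;
      break;
    case 5: // [a_pos, a_neg0, beta, phi, zeta, alpha_nu, psi]
      if (par.size() != 7) stop("RL_meta expects 7 parameters");
      ag.a_pos = par[0]; ag.a_neg = par[1]; ag.beta = par[2]; ag.phi = par[3];
      ag.zeta = par[4]; ag.alpha_nu0 = par[5]; ag.psi = par[6];
      break;
    case 6: // [a_pos, a_neg, phi, alpha_nu0, zeta, psi, beta]
      if (par.size() != 7) stop("PearceHall expects 7 parameters");
      ag.a_pos = par[0]; ag.a_neg = par[1]; ag.phi = par[2];
      ag.alpha_nu0 = par[3]; ag.zeta = par[4]; ag.psi = par[5]; ag.beta = par[6];
      break;
    case 7: // [beta, phi, q]
      if (par.size() != 3) stop("BIfp expects 3 parameters");
      ag.beta = par[0]; ag.phi = par[1]; ag.q = par[2];
      break;
    case 8: case 9: // [beta, phi, q, alpha_w]
      if (par.size() != 4) stop("BRLfwr/BRLfw expect 4 parameters");
      ag.beta = par[0]; ag.phi = par[1]; ag.q = par[2]; ag.alpha_w = par[3];
      break;
    case 10: // [beta, phi, q, alpha_w, rho1, rho2]
      if (par.size() != 6) stop("BRLwrp expects 6 parameters");
      ag.beta = par[0]; ag.phi = par[1]; ag.q = par[2]; ag.alpha_w = par[3];
      ag.rho1 = par[4]; ag.rho2 = par[5];
      break;
    default:
      stop("unknown model code");
  }
  ag.reset();
  return ag;
}

// [[Rcpp::export]]
List bb_forward_cpp(int model, NumericVector par, IntegerVector choice,
                    IntegerVector reward, LogicalVector session_start,
                    double rho1m, double rho2m, int zeta_conv,
                    bool want_latents) {
  int n = choice.size();
  if (reward.size() != n || session_start.size() != n)
    stop("choice, reward and session_start must have equal length");
  Agent ag = make_agent(model, par, rho1m, rho2m, zeta_conv);

  NumericVector pr, bel, ql, qr, vd, delta, ll;
  if (want_latents) {
    pr = NumericVector(n, NA_REAL); bel = NumericVector(n, NA_REAL);
    ql = NumericVector(n, NA_REAL); qr = NumericVector(n, NA_REAL);
    vd = NumericVector(n, NA_REAL); delta = NumericVector(n, NA_REAL);
    ll = NumericVector(n, NA_REAL);
  }

  double nll = 0.0;
  int n_used = 0;
  int prev = 0;
  bool is_belief = (model >= 7);

  for (int t = 0; t < n; ++t) {
    if (session_start[t]) { ag.reset(); prev = 0; }
    int c = choice[t];
    if (c == NA_INTEGER || c == 0) continue; // missed trial: no update
    int r = reward[t];
    if (r == NA_INTEGER) stop("observed choice with missing reward at trial %d", t + 1);

    double p = ag.p_right(prev);
    double pc = (c == 1) ? p : 1.0 - p;
    if (pc < P_FLOOR) pc = P_FLOOR;
    nll -= std::log(pc);
    ++n_used;

    if (want_latents) {
      pr[t] = p;
      vd[t] = ag.policy_D();
      if (is_belief) bel[t] = ag.b;
      ql[t] = ag.qval(-1); qr[t] = ag.qval(1);
      delta[t] = ag.rpe(c, r);
      ll[t] = std::log(pc);
    }

    ag.update(c, r);
    prev = c;
  }

  List out = List::create(_["nll"] = nll, _["n_used"] = n_used);
  if (want_latents) {
    out["p_right"] = pr; out["belief_right"] = bel;
    out["q_left"] = ql; out["q_right"] = qr;
    out["value_diff"] = vd; out["rpe"] = delta; out["loglik"] = ll;
  }
  return out;
}

// [[Rcpp::export]]
List bb_simulate_cpp(int model, NumericVector par, int n_trials,
                     double rho1e, double rho2e, int switch_mode,
                     int bmin, int bmax, double q_env,
                     double rho1m, double rho2m, int zeta_conv) {
  if (n_trials < 1) stop("n_trials must be >= 1");
  Agent ag = make_agent(model, par, rho1m, rho2m, zeta_conv);

  IntegerVector choice(n_trials), reward(n_trials), state(n_trials);
  IntegerVector block(n_trials), earned(n_trials);
  NumericVector pr(n_trials), bel(n_trials, NA_REAL), ql(n_trials), qr(n_trials);
  NumericVector vd(n_trials), delta(n_trials);
  bool is_belief = (model >= 7);

  int z = (unif_rand() < 0.5) ? -1 : 1;
  int blk = 0, count = 0;
  int target = bmin + (int)std::floor(unif_rand() * (double)(bmax - bmin + 1));
  if (target > bmax) target = bmax;
  int prev = 0;

  for (int t = 0; t < n_trials; ++t) {
    double p = ag.p_right(prev);
    int c = (unif_rand() < p) ? 1 : -1;
    double p_rew = (c == z) ? rho1e : rho2e;
    int r = (unif_rand() < p_rew) ? 1 : 0;

    choice[t] = c; reward[t] = r; state[t] = z;
    block[t] = blk; earned[t] = count;
    pr[t] = p; vd[t] = ag.policy_D();
    if (is_belief) bel[t] = ag.b;
    ql[t] = ag.qval(-1); qr[t] = ag.qval(1);
    delta[t] = ag.rpe(c, r);

    ag.update(c, r);
    prev = c;

    if (switch_mode == 0) { // cumulative earned rewards
      if (r == 1) ++count;
      if (count >= target) {
        z = -z; ++blk; count = 0;
        target = bmin + (int)std::floor(unif_rand() * (double)(bmax - bmin + 1));
        if (target > bmax) target = bmax;
      }
    } else { // per-trial switch probability
      if (unif_rand() < q_env) { z = -z; ++blk; }
    }
  }

  return List::create(
    _["choice"] = choice, _["reward"] = reward, _["state"] = state,
    _["block_index"] = block, _["rewards_earned_in_block"] = earned,
    _["p_right"] = pr, _["belief_right"] = bel,
    _["q_left"] = ql, _["q_right"] = qr,
    _["value_diff"] = vd, _["rpe"] = delta);
}
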