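#' The model registry
#'
#' Ten agents are available for the two-armed bandit task. All share the
#' softmax-with-stickiness policy \eqn{P(c_t = 1) = \sigma(\beta D_t + \phi
#' c_{t-1})}, where \eqn{D_t} is the model's value difference between the
#' right and left port, \eqn{\beta} an inverse temperature and \eqn{\phi} a
#' stickiness (perseveration) weight. They differ in how \eqn{D_t} is
#' maintained:
#'
#' * `RL4p` — Q-learning with separate learning rates for positive
#'   (`alpha_pos`) and negative (`alpha_neg`) reward prediction errors.
#' * `RLCF` — RL4p plus a counterfactual update of the unchosen value with
#'   the same trial learning rate applied to \eqn{1 - r - Q(-c)}.
#' * `RFLR` — recursively formulated logistic regression,
#'   \eqn{D_{t+1} = e^{-1/\tau} D_t + \alpha r_t c_t}, with \eqn{\beta}
#'   fixed at 1 and the stickiness left unconstrained in sign.
#' * `RLFQ3p` — Q-learning with forgetting: the unchosen value decays by a
#'   factor \eqn{\zeta} tied to the learning rates (see
#'   [rlfq3p_zeta()]); no stickiness term (forgetting plays that role).
#' * `RL_meta` — forgetting Q-learning whose negative learning rate adapts
#'   to unexpected uncertainty \eqn{\nu_t = |\delta_t| - \omega_{t-1}},
#'   where \eqn{\omega} is a running estimate of \eqn{|\delta|}.
#' * `PearceHall` — forgetting Q-learning with a Pearce-Hall associability
#'   \eqn{\alpha_\nu} tracking recent \eqn{|\delta|} and multiplying the
#'   learning rates; unchosen values decay toward the initial value 0.5.
#' * `BIfp` — Bayesian inference with fixed parameters: a two-state hidden
#'   Markov filter over the rewarded side with assumed reward
#'   probabilities (0.75 / 1e-4) and fitted switch rate `q`;
#'   \eqn{D_t = 2 b_t(1) - 1} where \eqn{b} is the belief.
#' * `BRLfwr` / `BRLfw` / `BRLwrp` — hybrid belief-state RL:
#'   \eqn{Q(c) = w_1 b(c) + w_2 b(-c)} with gradient updates of the
#'   weights; `fwr` fixes \eqn{w_2} at the assumed incorrect-choice reward
#'   probability, `fw` learns both weights, `wrp` additionally fits the
#'   assumed reward probabilities.
#'
#' @return A tibble with one row per model: `model`, `k` (number of free
#'   parameters) and `params` (list column of parameter names, in the
#'   order expected by [fit_agent()] and [simulate_agent()]).
#' @export
#' @examples
#' bb_models()
bb_models <- function() {
  tibble::tibble(
    model = c("RL4p", "RLCF", "RFLR", "RLFQ3p", "RL_meta", "PearceHall",
              "BIfp", "BRLfwr", "BRLfw", "BRLwrp"),
    code = 1:10,
    k = c(4L, 4L, 3L, 3L, 7L, 7L, 3L, 4L, 4L, 6L),
    params = list(
      c("alpha_pos", "alpha_neg", "beta", "phi"),
      c("alpha_pos", "alpha_neg", "beta", "phi"),
      c("alpha", "phi", "tau"),
      c("alpha_pos", "alpha_neg", "beta"),
      c("alpha_pos", "alpha_neg", "beta", "phi", "zeta", "alpha_nu", "psi"),
      c("alpha_pos", "alpha_neg", "phi", "alpha_nu0", "zeta", "psi", "beta"),
      c("beta", "phi", "q"),
      c("beta", "phi", "q", "alpha_w"),
      c("beta", "phi", "q", "alpha_w"),
      c("beta", "phi", "q", "alpha_w", "rho1", "rho2")
    )
  )
}

model_code <- function(model) {
  reg <- bb_models()
  i <- match(model, reg$model)
  if (is.na(i)) {
    stop("unknown model '", model, "'; see bb_models()", call. = FALSE)
  }
  reg$code[i]
}

model_param_names <- function(model) {
  reg <- bb_models()
  reg$params[[match(model, reg$model)]]
}

model_k <- function(model) {
  reg <- bb_models()
  reg$k[match(model, reg$model)]
}

check_theta <- function(model, theta) {
  nm <- model_param_names(model)
  if (!is.null(names(theta)) && all(nm %in% names(theta))) {
    theta <- theta[nm]
  }
  if (length(theta) != length(nm)) {
    stop(sprintf("model %s expects %d parameters (%s)", model, length(nm),
                 paste(nm, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(as.numeric(theta), nm)
}

zeta_conv_code <- function(zeta_convention) {
  match.arg(zeta_convention, c("one_minus_mean", "mean"))
  if (zeta_convention == "one_minus_mean") 0L else 1L
}

#' Forgetting factor of the three-parameter forgetting Q-learner
#'
#' The decay applied to the unchosen action value is tied to the learning
#' rates. The default convention, \eqn{\zeta = 1 - (\alpha_+ +
#' \alpha_-)/2}, makes the model exactly equivalent to `RFLR` when
#' \eqn{\alpha_+ = \alpha_-} (decay \eqn{1 - \alpha} maps onto
#' \eqn{e^{-1/\tau}}). The alternative reading \eqn{\zeta = (\alpha_+ +
#' \alpha_-)/2} is available via `convention = "mean"`.
#'
#' @param alpha_pos,alpha_neg Learning rates in `[0, 1]`.
#' @param convention `"one_minus_mean"` (default) or `"mean"`.
#' @return The decay factor in `[0, 1]`.
#' @export
rlfq3p_zeta <- function(alpha_pos, alpha_neg,
                        convention = c("one_minus_mean", "mean")) {
  convention <- match.arg(convention)
  m <- (alpha_pos + alpha_neg) / 2
  if (convention == "one_minus_mean") 1 - m else m
}

#' Softmax choice policy with stickiness
#'
#' @param value_diff Value difference \eqn{D = Q(+1) - Q(-1)}.
#' @param prev_choice Previous choice (-1/+1), or `NULL`/`NA` on the first
#'   trial of a session, in which case the stickiness term is dropped.
#' @param beta Inverse temperature (>= 0).
#' @param phi Stickiness weight.
#' @return Probability of choosing the right port (+1), strictly in (0, 1).
#' @export
#' @examples
#' choice_prob(0, NULL, beta = 1, phi = 0)        # 0.5
#' choice_prob(1, NULL, beta = 1, phi = 0)        # plogis(1)
choice_prob <- function(value_diff, prev_choice, beta, phi) {
  prev <- if (is.null(prev_choice) || is.na(prev_choice)) 0 else prev_choice
  stopifnot(prev %in% c(-1, 0, 1))
  stats::plogis(beta * value_diff + phi * prev)
}

#' One Q-learning update step
#'
#' Applies the delta rule \eqn{\Delta Q(c) = \alpha_t \delta_t} with
#' \eqn{\delta_t = r - Q(c)} and \eqn{\alpha_t = \alpha_+} when
#' \eqn{\delta_t \ge 0}, else \eqn{\alpha_-}. `mode = "RLCF"` additionally
#' moves the unchosen value by the same rate applied to the counterfactual
#' error \eqn{1 - r - Q(-c)}; `mode = "RLFQ3p"` instead decays the
#' unchosen value by the forgetting factor.
#'
#' @param q Named or length-2 numeric: values for choices `-1` and `+1`
#'   (in that order).
#' @param choice Choice made, -1 or +1.
#' @param reward Reward observed, 0 or 1.
#' @param alpha_pos,alpha_neg Learning rates.
#' @param mode One of `"RL4p"`, `"RLCF"`, `"RLFQ3p"`.
#' @param zeta_convention Forgetting convention for `RLFQ3p`; see
#'   [rlfq3p_zeta()].
#' @return List with updated `q` and the prediction error `delta`.
#' @export
rl_update <- function(q, choice, reward, alpha_pos, alpha_neg,
                      mode = c("RL4p", "RLCF", "RLFQ3p"),
                      zeta_convention = "one_minus_mean") {
  mode <- match.arg(mode)
  stopifnot(choice %in% c(-1, 1), reward %in% c(0, 1), length(q) == 2)
  ic <- if (choice == 1) 2L else 1L
  iu <- 3L - ic
  delta <- reward - q[ic]
  a <- if (delta >= 0) alpha_pos else alpha_neg
  q[ic] <- q[ic] + a * delta
  if (mode == "RLCF") {
    delta_cf <- (1 - reward) - q[iu]
    q[iu] <- q[iu] + a * delta_cf
  } else if (mode == "RLFQ3p") {
    q[iu] <- q[iu] * rlfq3p_zeta(alpha_pos, alpha_neg, zeta_convention)
  }
  list(q = q, delta = delta)
}

#' One RFLR update of the value difference
#'
#' \eqn{D_{t+1} = e^{-1/\tau} D_t + \alpha r_t c_t}.
#'
#' @param value_diff Current value difference.
#' @param choice,reward Choice (-1/+1) and reward (0/1).
#' @param alpha Reward weight.
#' @param tau Decay timescale (> 0).
#' @return Updated value difference.
#' @export
rflr_update <- function(value_diff, choice, reward, alpha, tau) {
  stopifnot(tau > 0, choice %in% c(-1, 1), reward %in% c(0, 1))
  exp(-1 / tau) * value_diff + alpha * reward * choice
}

#' One Bayesian belief update
#'
#' Forward step of the two-state hidden Markov filter over the rewarded
#' side: multiply the prior belief by the reward likelihood under the
#' assumed reward probabilities, normalize, then apply the symmetric
#' transition with switch probability `q`.
#'
#' @param belief Prior probability that the hidden state is +1 (right).
#' @param choice,reward Observed choice (-1/+1) and reward (0/1).
#' @param rho1,rho2 Assumed reward probability for a correct / incorrect
#'   choice. `rho2` must be > 0.
#' @param q Assumed per-trial hidden-state switch probability.
#' @return Posterior-predictive belief for the next trial, in (0, 1).
#' @export
#' @examples
#' belief_update(0.5, 1, 1, 0.75, 1e-4, 0.05) # ~0.94988
belief_update <- function(belief, choice, reward, rho1, rho2, q) {
  stopifnot(belief >= 0, belief <= 1, rho2 > 0,
            choice %in% c(-1, 1), reward %in% c(0, 1))
  lik <- function(z) {
    p <- if (choice == z) rho1 else rho2
    if (reward == 1) p else 1 - p
  }
  num <- belief * lik(1)
  den <- num + (1 - belief) * lik(-1)
  post <- num / den
  (1 - q) * post + q * (1 - post)
}

#' Belief-state RL value computation and weight update
#'
#' \eqn{Q(c) = w_1 b(c) + w_2 b(-c)}; the weights follow the gradient
#' updates \eqn{\Delta w_1 = \alpha \delta b(c_t)}, \eqn{\Delta w_2 =
#' \alpha \delta b(-c_t)}, with \eqn{w_2} held fixed for the `fwr`
#' variant.
#'
#' @param belief Belief that the hidden state is +1.
#' @param choice,reward Observed choice and reward.
#' @param w1,w2 Current reward weights.
#' @param alpha_w Weight learning rate.
#' @param variant `"fwr"` (fix `w2`), `"fw"` or `"wrp"` (update both).
#' @return List with `q_right`, `q_left`, `value_diff`, `delta`, and
#'   updated `w1`, `w2`.
#' @export
brl_value_and_weights <- function(belief, choice, reward, w1, w2, alpha_w,
                                  variant = c("fwr", "fw", "wrp")) {
  variant <- match.arg(variant)
  stopifnot(choice %in% c(-1, 1), reward %in% c(0, 1))
  bc <- if (choice == 1) belief else 1 - belief
  q_right <- w1 * belief + w2 * (1 - belief)
  q_left <- w1 * (1 - belief) + w2 * belief
  delta <- reward - (w1 * bc + w2 * (1 - bc))
  w1_new <- w1 + alpha_w * delta * bc
  w2_new <- if (variant == "fwr") w2 else w2 + alpha_w * delta * (1 - bc)
  list(q_right = q_right, q_left = q_left, value_diff = q_right - q_left,
       delta = delta, w1 = w1_new, w2 = w2_new)
}

#' Value difference of the fixed-parameter Bayesian agent
#'
#' @param belief Belief that the hidden state is +1.
#' @return \eqn{D = 2b - 1 \in [-1, 1]}.
#' @export
bifp_value_diff <- function(belief) {
  stopifnot(belief >= 0, belief <= 1)
  2 * belief - 1
}

#' One meta-learning update step
#'
#' Update order: \eqn{\delta \to \nu_t \to \alpha^-_t \to \omega_t \to Q}.
#' The adapted negative learning rate \eqn{\alpha^-_t = \psi(\nu_t +
#' \alpha^-_0) + (1-\psi)\alpha^-_{t-1}} (only when \eqn{\delta < 0}) is
#' clamped to `[0, 1]`; \eqn{\omega_t = \omega_{t-1} + \alpha_\nu \nu_t};
#' the unchosen value decays by `zeta`.
#'
#' @param state List with `q` (length-2 values for -1/+1), `alpha_neg_t`,
#'   `omega`.
#' @param choice,reward Observed choice and reward.
#' @param params Named vector/list with `alpha_pos`, `alpha_neg` (the
#'   baseline \eqn{\alpha^-_0}), `zeta`, `alpha_nu`, `psi`.
#' @return Updated state, plus `delta` and `nu`.
#' @export
meta_update <- function(state, choice, reward, params) {
  stopifnot(choice %in% c(-1, 1), reward %in% c(0, 1))
  p <- as.list(params)
  ic <- if (choice == 1) 2L else 1L
  iu <- 3L - ic
  delta <- reward - state$q[ic]
  nu <- abs(delta) - state$omega
  if (delta < 0) {
    a <- p$psi * (nu + p$alpha_neg) + (1 - p$psi) * state$alpha_neg_t
    state$alpha_neg_t <- min(max(a, 0), 1)
  }
  state$omega <- state$omega + p$alpha_nu * nu
  rate <- if (delta >= 0) p$alpha_pos else state$alpha_neg_t
  state$q[ic] <- state$q[ic] + rate * delta
  state$q[iu] <- state$q[iu] * p$zeta
  state$delta <- delta
  state$nu <- nu
  state
}

#' One Pearce-Hall update step
#'
#' The associability is refreshed first, \eqn{\alpha_\nu \leftarrow
#' \alpha_\nu + \psi(|\delta| - \alpha_\nu)}, and the refreshed value
#' scales the learning rate in the Q step; the unchosen value decays
#' toward the attractor `q0`.
#'
#' @param state List with `q` (length-2) and `alpha_nu_t`.
#' @param choice,reward Observed choice and reward.
#' @param params Named vector/list with `alpha_pos`, `alpha_neg`, `psi`,
#'   `zeta`, and optionally `q0` (default 0.5).
#' @return Updated state, plus `delta`.
#' @export
pearcehall_update <- function(state, choice, reward, params) {
  stopifnot(choice %in% c(-1, 1), reward %in% c(0, 1))
  p <- as.list(params)
  q0 <- if (is.null(p$q0)) 0.5 else p$q0
  ic <- if (choice == 1) 2L else 1L
  iu <- 3L - ic
  delta <- reward - state$q[ic]
  state$alpha_nu_t <- state$alpha_nu_t + p$psi * (abs(delta) - state$alpha_nu_t)
  rate <- state$alpha_nu_t * (if (delta >= 0) p$alpha_pos else p$alpha_neg)
  state$q[ic] <- state$q[ic] + rate * delta
  state$q[iu] <- q0 + p$zeta * (state$q[iu] - q0)
  state$delta <- delta
  state
}

#' Pseudo reward prediction error
#'
#' Observed minus expected reward for the chosen option, evaluated with
#' the pre-update state. For the pure inference agent the expectation is
#' \eqn{\rho_1 b(c) + \rho_2 b(-c)}; `RFLR` has no RPE formulation and
#' raises an error.
#'
#' @param model Model name (see [bb_models()]).
#' @param state For RL-family models, a list with `q` (length-2 values for
#'   -1/+1); for belief models, a list with `belief` and, for the BRL
#'   family, `w1`, `w2`; for `BIfp`, optionally `rho1`, `rho2` (defaults
#'   0.75 / 1e-4).
#' @param choice,reward Observed choice and reward.
#' @return The prediction error \eqn{\delta}.
#' @export
pseudo_rpe <- function(model, state, choice, reward) {
  stopifnot(choice %in% c(-1, 1), reward %in% c(0, 1))
  if (model == "RFLR") {
    stop("RFLR does not define a reward prediction error", call. = FALSE)
  }
  bc <- function(b) if (choice == 1) b else 1 - b
  expected <- switch(model,
    BIfp = {
      rho1 <- if (is.null(state$rho1)) 0.75 else state$rho1
      rho2 <- if (is.null(state$rho2)) 1e-4 else state$rho2
      rho1 * bc(state$belief) + rho2 * (1 - bc(state$belief))
    },
    BRLfwr = , BRLfw = , BRLwrp =
      state$w1 * bc(state$belief) + state$w2 * (1 - bc(state$belief)),
    {
      ic <- if (choice == 1) 2L else 1L
      state$q[ic]
    }
  )
  reward - expected
}

#' Run an agent over an observed trial table
#'
#' Plays the agent forward through the recorded choices and rewards
#' (latent state evolving on every observed trial, resetting at session
#' boundaries) and appends the per-trial latents: `p_right` (probability
#' of choosing right under the policy), `belief_right` (belief models),
#' `q_left`, `q_right`, `value_diff`, `rpe`, and `loglik` of the observed
#' choice. Missed trials (missing choice) are passed through untouched.
#'
#' @param data A trial tibble with columns `choice`, `reward` and
#'   (optionally) `subject_id`, `session_id`.
#' @param model Model name; see [bb_models()].
#' @param theta Named parameter vector for the model.
#' @param rho1_model,rho2_model Assumed reward probabilities of the belief
#'   models.
#' @param zeta_convention See [rlfq3p_zeta()].
#' @return `data` with latent columns appended.
#' @export
run_agent <- function(data, model, theta, rho1_model = 0.75,
                      rho2_model = 1e-4,
                      zeta_convention = "one_minus_mean") {
  theta <- check_theta(model, theta)
  fw <- bb_forward_cpp(model_code(model), unname(theta),
                       choice_int(data), reward_int(data),
                       session_starts(data), rho1_model, rho2_model,
                       zeta_conv_code(zeta_convention), TRUE)
  data$p_right <- fw$p_right
  data$belief_right <- fw$belief_right
  data$q_left <- fw$q_left
  data$q_right <- fw$q_right
  data$value_diff <- fw$value_diff
  data$rpe <- fw$rpe
  data$loglik <- fw$loglik
  data
}

# integer choice vector with NA -> 0 (skipped by the C++ loop)
choice_int <- function(data) {
  c_ <- data$choice
  c_[is.na(c_)] <- 0
  as.integer(c_)
}

reward_int <- function(data) {
  r <- data$reward
  out <- as.integer(r)
  out[is.na(r)] <- NA_integer_
  out
}

# logical flag marking the first row of each (subject, session)
session_starts <- function(data) {
  key <- paste(
    if ("subject_id" %in% names(data)) data$subject_id else "s",
    if ("session_id" %in% names(data)) data$session_id else "1"
  )
  n <- nrow(data)
  if (n == 0) return(logical(0))
  c(TRUE, key[-1] != key[-n])
}
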