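# Shared fixtures and independent reference implementations used as
# oracles against the C++ trial loop.

# brute-force HMM forward: enumerate all hidden-state paths z_{1..T+1}
# and return P(z_{T+1} = +1 | c_{1:T}, r_{1:T})
brute_force_belief <- function(choices, rewards, rho1, rho2, q) {
  T_ <- length(choices)
  paths <- as.matrix(expand.grid(rep(list(c(-1, 1)), T_ + 1)))
  w <- rep(0.5, nrow(paths)) # uniform prior on z_1
  for (t in seq_len(T_)) {
    trans <- ifelse(paths[, t + 1] == paths[, t], 1 - q, q)
    p_rew <- ifelse(choices[t] == paths[, t], rho1, rho2)
    lik <- if (rewards[t] == 1) p_rew else 1 - p_rew
    w <- w * trans * lik
  }
  sum(w[paths[, T_ + 1] == 1]) / sum(w)
}

# plain-R forward pass over observed choices/rewards using the exported
# single-step updates; independent of the compiled loop
r_reference_forward <- function(model, theta, choices, rewards,
                                rho1m = 0.75, rho2m = 1e-4) {
  theta <- as.list(theta)
  n <- length(choices)
  p_right <- numeric(n)
  rpe <- rep(NA_real_, n)
  q <- c(0.5, 0.5) # values for -1 / +1
  D <- 0
  b <- 0.5
  w1 <- rho1m; w2 <- rho2m
  meta <- list(q = q, alpha_neg_t = theta$alpha_neg, omega = 0)
  ph <- list(q = q, alpha_nu_t = theta$alpha_nu0)
  prev <- NA
  for (t in seq_len(n)) {
    ct <- choices[t]; rt <- rewards[t]
    ic <- if (ct == 1) 2L else 1L
    if (model %in% c("RL4p", "RLCF", "RLFQ3p")) {
      p_right[t] <- choice_prob(q[2] - q[1], prev, theta$beta,
                                if (model == "RLFQ3p") 0 else theta$phi)
      rpe[t] <- rt - q[ic]
      up <- rl_update(q, ct, rt, theta$alpha_pos, theta$alpha_neg, model)
      q <- up$q
    } else if (model == "RFLR") {
      p_right[t] <- choice_prob(D, prev, 1, theta$phi)
      D <- rflr_update(D, ct, rt, theta$alpha, theta$tau)
    } else if (model == "RL_meta") {
      p_right[t] <- choice_prob(meta$q[2] - meta$q[1], prev, theta$beta,
                                theta$phi)
      rpe[t] <- rt - meta$q[ic]
      meta <- meta_update(meta, ct, rt, theta)
    } else if (model == "PearceHall") {
      p_right[t] <- choice_prob(ph$q[2] - ph$q[1], prev, theta$beta,
                                theta$phi)
      rpe[t] <- rt - ph$q[ic]
      ph <- pearcehall_update(ph, ct, rt, theta)
    } else if (model == "BIfp") {
      p_right[t] <- choice_prob(bifp_value_diff(b), prev, theta$beta,
                                theta$phi)
      rpe[t] <- pseudo_rpe("BIfp", list(belief = b), ct, rt)
      b <- belief_update(b, ct, rt, rho1m, rho2m, theta$q)
    } else if (model %in% c("BRLfwr", "BRLfw")) {
      vb <- brl_value_and_weights(b, ct, rt, w1, w2, theta$alpha_w,
                                  if (model == "BRLfwr") "fwr" else "fw")
      p_right[t] <- choice_prob(vb$value_diff, prev, theta$beta, theta$phi)
      rpe[t] <- vb$delta
      w1 <- vb$w1; w2 <- vb$w2
      b <- belief_update(b, ct, rt, rho1m, rho2m, theta$q)
    } else {
      stop("no reference for model ", model)
    }
    prev <- ct
  }
  list(p_right = p_right, rpe = rpe,
       loglik = sum(log(ifelse(choices == 1, p_right, 1 - p_right))))
}

# small deterministic trial table built by hand
toy_trials <- function(choices, rewards, state = NULL,
                       subject = "m1", session = "s001") {
  tibble::tibble(
    subject_id = subject, session_id = session,
    trial = seq_along(choices) - 1L,
    choice = choices, reward = rewards,
    state = if (is.null(state)) NA_integer_ else state)
}

# representative parameters for quick simulations
rep_theta <- function(model) {
  r <- default_param_ranges()
  r <- r[r$model == model, ]
  stats::setNames((r$min + r$max) / 2, r$param)
}
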