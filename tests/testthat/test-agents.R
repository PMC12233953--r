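test_that("choice policy matches the logistic closed form", {
  expect_equal(choice_prob(0, NULL, beta = 1, phi = 0), 0.5)
  expect_equal(choice_prob(1, NULL, beta = 1, phi = 0), 0.7310586,
               tolerance = 1e-6)
  expect_equal(choice_prob(0, -1, beta = 0, phi = 2), 0.1192029,
               tolerance = 1e-6)
  # strictly increasing in the value difference for beta > 0
  d <- seq(-3, 3, by = 0.5)
  p <- vapply(d, choice_prob, 0, prev_choice = NULL, beta = 2, phi = 0.3)
  expect_true(all(diff(p) > 0))
})

test_that("Q-learning updates follow the delta rule and its variants", {
  up <- rl_update(c(0.2, 0.5), 1, 1, 0.8, 0.3, "RL4p")
  expect_equal(up$delta, 0.5)
  expect_equal(up$q[2], 0.9)
  expect_equal(up$q[1], 0.2) # unchosen untouched

  up <- rl_update(c(0.4, 0.5), 1, 1, 0.8, 0.3, "RLCF")
  expect_equal(up$q[1], 0.4 + 0.8 * ((1 - 1) - 0.4)) # 0.08

  # forgetting: zeta = 1 - (a+ + a-)/2 by default, (a+ + a-)/2 as the
  # alternative reading
  expect_equal(rlfq3p_zeta(0.8, 0.4), 0.4)
  expect_equal(rlfq3p_zeta(0.8, 0.4, "mean"), 0.6)
  up <- rl_update(c(0.5, 0.5), 1, 1, 0.8, 0.4, "RLFQ3p")
  expect_equal(up$q[1], 0.2)
})

test_that("RFLR value-difference recursion evaluates in closed form", {
  expect_equal(rflr_update(1, 1, 1, 0.5, 1), exp(-1) + 0.5, tolerance = 1e-7)
  expect_equal(rflr_update(1, 1, 0, 0.5, 1), exp(-1), tolerance = 1e-7)
  expect_equal(rflr_update(1, -1, 1, 0.5, 1), exp(-1) - 0.5, tolerance = 1e-7)
})

test_that("belief filter matches hand calculation and mixing limits", {
  expect_equal(belief_update(0.5, 1, 1, 0.75, 1e-4, 0.05), 0.94988,
               tolerance = 1e-4)
  expect_equal(belief_update(0.5, 1, 0, 0.75, 1e-4, 0.05), 0.2300144,
               tolerance = 1e-5)
  # maximal transition mixing erases all information
  for (b0 in c(0.1, 0.5, 0.9)) {
    expect_equal(belief_update(b0, 1, 1, 0.75, 1e-4, 0.5), 0.5)
  }
  # beliefs stay strictly inside (0, 1) along any sequence
  set.seed(42)
  b <- 0.5
  for (i in 1:200) {
    b <- belief_update(b, sample(c(-1, 1), 1), rbinom(1, 1, 0.5),
                       0.75, 1e-4, 0.02)
    expect_true(b > 0 && b < 1)
  }
})

test_that("belief recursion equals brute-force path enumeration", {
  # random subset of sequences at several lengths; exhaustive version runs
  # in the acceptance suite
  set.seed(1)
  for (rep in 1:25) {
    T_ <- sample(2:6, 1)
    ch <- sample(c(-1, 1), T_, replace = TRUE)
    rw <- rbinom(T_, 1, 0.5)
    q <- runif(1, 0.01, 0.3)
    b <- 0.5
    for (t in seq_len(T_)) b <- belief_update(b, ch[t], rw[t], 0.75, 1e-4, q)
    expect_equal(b, brute_force_belief(ch, rw, 0.75, 1e-4, q),
                 tolerance = 1e-10)
  }
})

test_that("belief-RL values, weight updates and BIfp mapping are exact", {
  vb <- brl_value_and_weights(0.8, 1, 1, 0.75, 1e-4, 0.1, "fwr")
  expect_equal(vb$q_right, 0.60002)
  expect_equal(vb$q_left, 0.15008)
  expect_equal(vb$value_diff, 0.44994)
  expect_equal(vb$delta, 0.39998)
  expect_equal(vb$w1, 0.75 + 0.1 * 0.39998 * 0.8)
  expect_equal(vb$w2, 1e-4) # fwr never updates w2
  vb2 <- brl_value_and_weights(0.8, 1, 1, 0.75, 1e-4, 0.1, "fw")
  expect_equal(vb2$w2, 1e-4 + 0.1 * 0.39998 * 0.2)

  expect_equal(bifp_value_diff(0.5), 0)
  expect_equal(bifp_value_diff(1), 1)
  expect_equal(bifp_value_diff(0.94988), 0.89976)
})

test_that("meta-learning update follows delta -> nu -> alpha -> omega", {
  th <- list(alpha_pos = 0.6, alpha_neg = 0.3, zeta = 0.8, alpha_nu = 0.2,
             psi = 0.5)
  st <- list(q = c(0.5, 0.5), alpha_neg_t = 0.3, omega = 0)
  out <- meta_update(st, 1, 0, th) # delta = -0.5
  expect_equal(out$nu, 0.5)
  expect_equal(out$alpha_neg_t, 0.5 * (0.5 + 0.3) + 0.5 * 0.3) # 0.55
  expect_equal(out$omega, 0.1)
  expect_equal(out$q[2], 0.5 + 0.55 * (-0.5))
  expect_equal(out$q[1], 0.5 * 0.8) # forgetting of the unchosen value

  # positive RPE leaves the adapted rate untouched
  out2 <- meta_update(st, 1, 1, th)
  expect_equal(out2$alpha_neg_t, 0.3)

  # psi = 0: the rate never adapts
  th0 <- modifyList(th, list(psi = 0))
  st0 <- st
  set.seed(2)
  for (i in 1:50) {
    st0 <- meta_update(st0, sample(c(-1, 1), 1), rbinom(1, 1, 0.5), th0)
    expect_equal(st0$alpha_neg_t, 0.3)
  }
})

test_that("Pearce-Hall associability and forgetting arithmetic", {
  th <- list(alpha_pos = 0.6, alpha_neg = 0.4, psi = 0.2, zeta = 0.5)
  st <- list(q = c(0.9, 0.0), alpha_nu_t = 0.5)
  out <- pearcehall_update(st, 1, 1, th) # |delta| = 1
  expect_equal(out$alpha_nu_t, 0.6)
  expect_equal(out$q[2], 0 + 0.6 * 0.6 * 1) # refreshed associability used
  expect_equal(out$q[1], 0.5 + 0.5 * (0.9 - 0.5)) # decay toward 0.5
})

test_that("pseudo-RPEs match expected-reward arithmetic and bounds", {
  expect_equal(pseudo_rpe("BIfp", list(belief = 0.8), 1, 1), 0.39998)
  expect_equal(pseudo_rpe("BIfp", list(belief = 0.8), 1, 0), -0.60002)
  expect_equal(pseudo_rpe("RL4p", list(q = c(0.2, 1)), 1, 1), 0)
  expect_error(pseudo_rpe("RFLR", list(), 1, 1), "RFLR")
  # bounded in [-1, 1] along simulated sessions, for every model with an RPE
  for (m in c("RL4p", "RLCF", "RLFQ3p", "RL_meta", "PearceHall", "BIfp",
              "BRLfwr")) {
    sim <- simulate_agent(m, rep_theta(m), task_config(n_trials = 300),
                          seed = 5)
    expect_true(all(sim$rpe >= -1 & sim$rpe <= 1), label = m)
  }
})

test_that("compiled forward pass agrees with the plain-R reference", {
  set.seed(9)
  ch <- sample(c(-1, 1), 60, replace = TRUE)
  rw <- rbinom(60, 1, 0.6)
  d <- toy_trials(ch, rw)
  thetas <- list(
    RL4p = c(alpha_pos = 0.7, alpha_neg = 0.4, beta = 2, phi = 0.5),
    RLCF = c(alpha_pos = 0.7, alpha_neg = 0.4, beta = 2, phi = 0.5),
    RFLR = c(alpha = 1.2, phi = 0.4, tau = 1.5),
    RLFQ3p = c(alpha_pos = 0.7, alpha_neg = 0.4, beta = 2),
    RL_meta = c(alpha_pos = 0.7, alpha_neg = 0.3, beta = 2, phi = 0.5,
                zeta = 0.7, alpha_nu = 0.25, psi = 0.4),
    PearceHall = c(alpha_pos = 0.7, alpha_neg = 0.4, phi = 0.5,
                   alpha_nu0 = 0.6, zeta = 0.7, psi = 0.3, beta = 2),
    BIfp = c(beta = 4, phi = 0.4, q = 0.05),
    BRLfwr = c(beta = 4, phi = 0.4, q = 0.05, alpha_w = 0.2),
    BRLfw = c(beta = 4, phi = 0.4, q = 0.05, alpha_w = 0.2)
  )
  for (m in names(thetas)) {
    run <- run_agent(d, m, thetas[[m]])
    ref <- r_reference_forward(m, thetas[[m]], ch, rw)
    expect_equal(run$p_right, ref$p_right, tolerance = 1e-10, label = m)
    if (m != "RFLR") {
      expect_equal(run$rpe, ref$rpe, tolerance = 1e-10, label = m)
    }
    expect_equal(-negative_log_likelihood(d, m, thetas[[m]]), ref$loglik,
                 tolerance = 1e-8, label = m)
  }
})

test_that("missed trials are skipped without touching the agent state", {
  ch <- c(1, 1, NA, -1, 1)
  rw <- c(1, 0, NA, 1, 0)
  d <- toy_trials(ch, rw)
  d2 <- toy_trials(ch[-3], rw[-3])
  th <- c(alpha_pos = 0.7, alpha_neg = 0.4, beta = 2, phi = 0.5)
  expect_equal(negative_log_likelihood(d, "RL4p", th),
               negative_log_likelihood(d2, "RL4p", th))
})
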