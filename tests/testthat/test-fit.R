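test_that("uniform policy likelihood equals n log 2 and bounds are enforced", {
  d <- toy_trials(sample(c(-1, 1), 40, replace = TRUE), rbinom(40, 1, 0.5))
  th <- c(alpha_pos = 0.5, alpha_neg = 0.5, beta = 0, phi = 0)
  expect_equal(negative_log_likelihood(d, "RL4p", th), 40 * log(2))
  expect_error(negative_log_likelihood(d, "RL4p",
                                       c(alpha_pos = 1.5, alpha_neg = 0.5,
                                         beta = 1, phi = 0)),
               "out of bounds")
})

test_that("likelihood prefers the generating switch rate", {
  worse <- 0
  for (s in 1:10) {
    sim <- simulate_agent("BIfp", c(beta = 5, phi = 0.3, q = 0.02),
                          task_config(n_trials = 1000), seed = 100 + s)
    nll_true <- negative_log_likelihood(sim, "BIfp",
                                        c(beta = 5, phi = 0.3, q = 0.02))
    nll_far <- negative_log_likelihood(sim, "BIfp",
                                       c(beta = 5, phi = 0.3, q = 0.3))
    worse <- worse + (nll_far > nll_true)
  }
  expect_gte(worse, 9) # perturbed q loses in (almost) every simulation
})

test_that("likelihood is additive over sessions (state resets per session)", {
  sim <- simulate_agent("RL4p", c(alpha_pos = 0.7, alpha_neg = 0.5,
                                  beta = 2, phi = 0.4),
                        task_config(n_trials = 200), sessions = 3, seed = 5)
  th <- c(alpha_pos = 0.6, alpha_neg = 0.4, beta = 1.5, phi = 0.2)
  full <- negative_log_likelihood(sim, "RL4p", th)
  per <- sum(vapply(split(sim, sim$session_id),
                    negative_log_likelihood, 0, model = "RL4p", theta = th))
  expect_equal(full, per, tolerance = 1e-10)
  # permuting session order leaves the total unchanged
  perm <- dplyr::arrange(sim, dplyr::desc(session_id), trial)
  expect_equal(negative_log_likelihood(perm, "RL4p", th), full,
               tolerance = 1e-10)
})

test_that("maximum-likelihood fitting is deterministic and start-monotone", {
  sim <- simulate_agent("BIfp", c(beta = 4, phi = 0.5, q = 0.03),
                        task_config(n_trials = 400), sessions = 2, seed = 8)
  f1 <- fit_agent(sim, "BIfp", n_starts = 3, seed = 2)
  f2 <- fit_agent(sim, "BIfp", n_starts = 3, seed = 2)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$loglik, f2$loglik)
  # AIC identity, exactly
  expect_identical(f1$aic, 2 * f1$k - 2 * f1$loglik)
  expect_lte(f1$loglik, 0)
  # nested starts: more starts can only improve the optimum
  f5 <- fit_agent(sim, "BIfp", n_starts = 5, seed = 2)
  expect_lte(-f5$loglik, -f1$loglik + 1e-9)
  expect_equal(f5$starts$nll[1:3], f1$starts$nll)
})

test_that("uninformative data drives the inverse temperature toward zero", {
  set.seed(31)
  d <- toy_trials(sample(c(-1, 1), 600, replace = TRUE), rbinom(600, 1, 0.5))
  f <- fit_agent(d, "RL4p", n_starts = 4, seed = 1)
  expect_lt(-f$loglik, 600 * log(2) * 1.01) # within 1% of coin-flip entropy
  expect_gt(-f$loglik, 600 * log(2) * 0.95)
})

test_that("AIC comparison zeroes the baseline and counts penalties", {
  sim <- simulate_agent("BIfp", c(beta = 4, phi = 0.5, q = 0.03),
                        task_config(n_trials = 300), sessions = 2, seed = 8)
  fits <- lapply(c("RL4p", "BIfp"), function(m) {
    fit_agent(sim, m, n_starts = 3, seed = 2)
  })
  tab <- aic_compare(fits, baseline = "RL4p")
  expect_equal(tab$delta_aic[tab$model == "RL4p"], 0)
  expect_equal(tab$delta_aic[tab$model == "BIfp"],
               tab$aic[tab$model == "BIfp"] - tab$aic[tab$model == "RL4p"])

  # equal log-likelihoods differing only in k: penalty arithmetic of 2 per
  # parameter
  fake <- function(model, k, ll) {
    structure(list(model = model, theta = c(a = 1), k = k, loglik = ll,
                   aic = 2 * k - 2 * ll, n_trials_used = 100, n_starts = 1,
                   best_start = 1, converged = TRUE, starts = NULL,
                   fingerprint = c(n = 1, sum_choice = 0, sum_reward = 0)),
              class = "bb_fit")
  }
  tab2 <- aic_compare(list(fake("RL4p", 4, -50), fake("RLFQ3p", 3, -50)),
                      baseline = "RL4p")
  expect_equal(tab2$delta_aic[tab2$model == "RLFQ3p"], -2)

  # refusing to compare fits on different data
  sim2 <- simulate_agent("BIfp", c(beta = 4, phi = 0.5, q = 0.03),
                         task_config(n_trials = 300), sessions = 2, seed = 9)
  f_other <- fit_agent(sim2, "RL4p", n_starts = 2, seed = 2)
  expect_error(aic_compare(list(fits[[2]], f_other)), "fingerprint")
})

test_that("around-switch likelihood counts the stated trials", {
  # constructed session: 3 blocks of 10 trials -> 2 switches... use 4 blocks
  n <- 40
  d <- toy_trials(rep(c(1, -1), each = 20)[1:n], rbinom(n, 1, 0.5))
  d$state <- rep(c(1, -1, 1, -1), each = 10)
  d$block_index <- rep(0:3, each = 10)
  th <- c(alpha_pos = 0.6, alpha_neg = 0.4, beta = 1, phi = 0.2)
  out <- around_switch_loglik(d, "RL4p", th, window = 5)
  expect_equal(out$n_trials, 15) # 3 switches x 5 trials
  expect_equal(out$aic, 2 * 4 - 2 * out$loglik)
  # a window covering everything after the first switch
  out_all <- around_switch_loglik(d, "RL4p", th, window = 1000)
  run <- run_agent(d, "RL4p", th)
  expect_equal(out_all$loglik, sum(run$loglik[11:n]), tolerance = 1e-10)
  expect_error(around_switch_loglik(d[1:10, ], "RL4p", th), "no block switches")
})

test_that("Holm step-down adjustment and the sign-flip p-value floor", {
  expect_equal(holm_bonferroni(0.03), 0.03)
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(c(1, 1, 1)), c(1, 1, 1))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")

  expect_equal(min_sign_permutation_p(5), 0.03125)
  expect_equal(min_sign_permutation_p(1), 0.5)
  expect_equal(min_sign_permutation_p(10), 0.0009765625)
  expect_error(min_sign_permutation_p(21), "refused")
})
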