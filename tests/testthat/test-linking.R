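sim_with_da <- function(model = "BIfp", theta = c(beta = 5, phi = 0.3,
                                                  q = 0.05),
                        n_trials = 600, seed = 2, noise_sd = 0.5) {
  sim <- simulate_agent(model, theta, task_config(n_trials = n_trials),
                        seed = seed)
  sim <- generate_event_times(sim, timing_config(), seed = seed)
  synthesize_da(sim, synth_da_config(noise_sd = noise_sd), seed = seed)
}

test_that("synthetic dopamine is linear in the RPE within each sign class", {
  sim <- sim_with_da(noise_sd = 1e-12)
  cfg <- synth_da_config(noise_sd = 1e-12)
  pos <- sim$rpe >= 0
  expect_equal(sim$da_pt[pos],
               cfg$gain_pos * sim$rpe[pos] + cfg$port_coef_pos *
                 sim$port_dur[pos], tolerance = 1e-6)
  # rewarded trials carry larger dopamine summaries than unrewarded ones
  expect_gt(mean(sim$da_pt[sim$reward == 1]),
            mean(sim$da_pt[sim$reward == 0]))
  expect_error(synthesize_da(toy_trials(c(1), c(1))), "rpe")
})

test_that("the RPE regression recovers generating coefficients", {
  sim <- sim_with_da(n_trials = 2000, noise_sd = 1e-9)
  des <- rpe_design(sim)
  out <- fit_rpe_regression(des, seed = 1)
  expect_equal(unname(out$coefficients["rpe_x_pos"]), 2, tolerance = 1e-3)
  expect_equal(unname(out$coefficients["rpe_x_neg"]), 1.5, tolerance = 1e-3)
  expect_equal(unname(out$coefficients["port_dur_x_pos"]), 0.1,
               tolerance = 1e-3)

  # destroying the response-covariate link lowers held-out likelihood
  sim2 <- sim_with_da(n_trials = 1000, noise_sd = 0.4)
  des2 <- rpe_design(sim2)
  set.seed(4)
  des_perm <- des2
  des_perm$da_pt <- sample(des_perm$da_pt)
  llk_true <- fit_rpe_regression(des2, seed = 9)$llk_test
  llk_perm <- fit_rpe_regression(des_perm, seed = 9)$llk_test
  expect_gt(llk_true, llk_perm)
})

test_that("cross-validated arbitration is baseline-consistent", {
  sim <- sim_with_da(n_trials = 800)
  sim$rpe_RL4p <- run_agent(sim, "RL4p",
                            c(alpha_pos = 0.8, alpha_neg = 0.7, beta = 2,
                              phi = 0.5))$rpe
  sim$rpe_BIfp <- sim$rpe
  only_base <- cv_llk_compare(sim, "RL4p")
  expect_equal(only_base$delta_llk_cv, 0)
  both <- cv_llk_compare(sim, c("RL4p", "BIfp"))
  # exact antisymmetry under baseline exchange on the same split
  swapped <- cv_llk_compare(sim, c("RL4p", "BIfp"), baseline = "BIfp")
  expect_equal(both$delta_llk_cv[both$model == "BIfp"],
               -swapped$delta_llk_cv[swapped$model == "RL4p"],
               tolerance = 1e-10)
  expect_error(cv_llk_compare(sim, c("RL4p", "nope")), "missing RPE")
})

test_that("lagged reward counts implement the partition identity", {
  # same port throughout: rewards at the chosen port only
  d <- toy_trials(rep(1, 5), c(1, 0, 1, 1, 1))
  d$da_pt <- rnorm(5)
  des <- build_lagged_design(d, n_lags = 4)
  expect_equal(nrow(des), 1L)
  expect_equal(des$R_chosen, 3)
  expect_equal(des$R_unchosen, 0)
  expect_equal(des$Stay, 1)

  d2 <- toy_trials(c(1, 1, -1, -1, 1), c(1, 1, 1, 0, 1))
  d2$da_pt <- rnorm(5)
  des2 <- build_lagged_design(d2, n_lags = 4)
  expect_equal(des2$R_chosen, 2)   # rewards at +1 among t-1..t-4
  expect_equal(des2$R_unchosen, 1) # reward at -1
  expect_equal(des2$Switch, 1)

  # partition identity on simulated data
  sim <- sim_with_da(n_trials = 400)
  des3 <- build_lagged_design(sim, n_lags = 4)
  key <- paste(sim$subject_id, sim$session_id)
  rw_sum <- rowSums(vapply(1:4, function(i) {
    beliefbandit:::lag_in_session(sim$reward, key, i)
  }, numeric(nrow(sim))))
  expect_true(all(des3$R_chosen + des3$R_unchosen <= 4))
  expect_equal(nrow(des3), sum(!is.na(rw_sum)))
  expect_equal(des3$R_chosen + des3$R_unchosen, rw_sum[!is.na(rw_sum)])
  expect_error(build_lagged_design(sim, n_lags = 0), "n_lags")
})

test_that("lagged regression recovers generator slope signs", {
  set.seed(8)
  sim <- simulate_agent("BIfp", c(beta = 5, phi = 0.3, q = 0.05),
                        task_config(n_trials = 5000), seed = 8)
  sim$da_pt <- 0 # placeholder; response rebuilt below
  des <- build_lagged_design(sim, n_lags = 4)
  des$response <- 0.5 * des$Reward - 0.1 * des$R_chosen * des$Switch +
    0.1 * des$R_unchosen * des$Switch + rnorm(nrow(des), 0, 0.3)
  est <- fit_lagged_model(des)
  get <- function(term) est$estimate[grepl(term, est$term)]
  expect_gt(min(get("Reward")), 0.3)
  expect_lt(get("Switch:R_chosen"), 0)
  expect_gt(get("Switch:R_unchosen"), 0)

  # zero noise: exact recovery
  des$response <- 0.5 * des$Reward - 0.1 * des$R_chosen * des$Switch +
    0.1 * des$R_unchosen * des$Switch
  est2 <- suppressWarnings(fit_lagged_model(des)) # zero-noise interpolation
  expect_equal(get2 <- est2$estimate[grepl("Switch:R_chosen", est2$term)],
               -0.1, tolerance = 1e-8)

  # hierarchical path needs more than one subject
  des$response <- des$response + rnorm(nrow(des), 0, 0.1)
  expect_warning(fit_lagged_model(des, hierarchical = TRUE),
                 "single subject")
})

test_that("history-binned dopamine orders codes by reward count and recency", {
  d <- toy_trials(rep(1, 40), rep(c(1, 0), 20))
  d$da_pt <- rep(1.5, 40)
  tab <- history_binned_da(d)
  expect_true(all(tab$mean_da == 1.5)) # uniform response -> equal bins
  # ordering: aaa first, AAA last, Aaa before aaA
  d2 <- toy_trials(rep(1, 2000), rbinom(2000, 1, 0.5))
  d2$da_pt <- rnorm(2000)
  tab2 <- history_binned_da(d2)
  expect_equal(tab2$code[1], "aaa")
  expect_equal(tab2$code[nrow(tab2)], "AAA")
  expect_lt(which(tab2$code == "Aaa"), which(tab2$code == "aaA"))
  expect_equal(nrow(tab2), 8L)
})
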