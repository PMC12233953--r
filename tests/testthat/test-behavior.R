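# ports: -1 = port 1, +1 = port 2 in the worked examples

test_that("three-trial history codes follow the reference-port rule", {
  # unrewarded port1, rewarded port2, unrewarded port2 -> "aBb"
  d <- toy_trials(c(-1, 1, 1, 1), c(0, 1, 0, 0))
  expect_equal(encode_history3(d)$hist3, c(NA, NA, NA, "aBb"))
  # same port three times, all rewarded -> "AAA"
  d2 <- toy_trials(c(1, 1, 1, 1), c(1, 1, 1, 0))
  expect_equal(encode_history3(d2)$hist3[4], "AAA")
  # port1 rewarded, port2 rewarded, port1 unrewarded -> "ABa"
  d3 <- toy_trials(c(-1, 1, -1, 1), c(1, 1, 0, 0))
  expect_equal(encode_history3(d3)$hist3[4], "ABa")
  # invariant to a global left/right relabeling
  flip <- function(d) { d$choice <- -d$choice; d }
  expect_equal(encode_history3(flip(d3))$hist3, encode_history3(d3)$hist3)
  # windows do not cross session boundaries
  d4 <- dplyr::bind_rows(toy_trials(c(1, 1), c(1, 1), session = "s001"),
                         toy_trials(c(1, 1, 1, 1), c(1, 1, 1, 1),
                                    session = "s002"))
  expect_equal(encode_history3(d4)$hist3, c(NA, NA, NA, NA, NA, "AAA"))
})

test_that("switch probability tables cover degenerate policies exactly", {
  stay <- toy_trials(rep(1, 30), rbinom(30, 1, 0.5))
  tab <- switch_probability_by_history(stay)
  expect_true(all(tab$p_switch == 0))
  expect_equal(sum(tab$n), 30 - 4 + 1) # trials with full history and a lag

  alt <- toy_trials(rep(c(1, -1), 15), rbinom(30, 1, 0.5))
  tab2 <- switch_probability_by_history(alt)
  expect_true(all(tab2$p_switch == 1))
})

test_that("two-outcome stay analysis isolates qualifying same-port trials", {
  # win-stay / lose-shift agent: switches iff last trial unrewarded
  set.seed(3)
  n <- 400
  ch <- numeric(n); rw <- numeric(n)
  ch[1] <- 1; rw[1] <- rbinom(1, 1, 0.6)
  for (t in 2:n) {
    ch[t] <- if (rw[t - 1] == 1) ch[t - 1] else -ch[t - 1]
    rw[t] <- rbinom(1, 1, 0.6)
  }
  tab <- stay_probability_by_2history(toy_trials(ch, rw))
  expect_equal(tab$p_stay[tab$history == "RR"], 1)
  expect_equal(tab$p_stay[tab$history == "RU"], 0)
  # under strict win-stay/lose-shift, an unrewarded t-2 forces a switch at
  # t-1, so UR and UU can never qualify as same-port histories
  expect_false(any(c("UR", "UU") %in% tab$history))

  # hand-constructed 6-trial table with exactly one qualifying RU trial,
  # where the animal stayed
  d <- toy_trials(c(1, 1, 1, 1, -1, -1), c(1, 1, 0, 0, 0, 1))
  tab2 <- stay_probability_by_2history(d)
  ru <- tab2[tab2$history == "RU", ]
  expect_equal(ru$n, 1L)
  expect_equal(ru$p_stay, 1)
})

test_that("block-aligned accuracy brackets omniscient and stale agents", {
  d <- toy_trials(rep(1, 30), rbinom(30, 1, 0.5))
  d$state <- rep(c(1, -1, 1), each = 10)
  d$block_index <- rep(0:2, each = 10)
  omni <- d; omni$choice <- omni$state
  acc <- block_switch_aligned_accuracy(omni, window = 4)
  expect_true(all(acc$p_correct == 1))
  # an agent frozen on the previous block's port is at 0 right after the
  # switch
  stale <- d
  stale$choice <- c(rep(1, 10), rep(1, 10), rep(-1, 10))
  acc2 <- block_switch_aligned_accuracy(stale, window = 3)
  expect_true(all(acc2$p_correct[acc2$offset >= 0] == 0))
})

test_that("trials-to-switch metrics implement the persistence rule", {
  blk <- function(correct) {
    d <- toy_trials(ifelse(correct, 1, -1), rep(0, length(correct)))
    d$state <- rep(1, length(correct))
    d$block_index <- rep(0L, length(correct))
    trials_to_switch_metrics(d)
  }
  m <- blk(c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(m$trial2sw, 3L); expect_equal(m$trial2asymp, 3L)
  m2 <- blk(c(TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(m2$trial2sw, 1L); expect_equal(m2$trial2asymp, 1L)
  m3 <- blk(c(TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(m3$trial2sw, 1L); expect_equal(m3$trial2asymp, 3L)
  m4 <- blk(c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(m4$trial2sw, 2L); expect_true(is.na(m4$trial2asymp))

  # asymptotic commitment can never precede the first correct choice
  sim <- simulate_agent("BIfp", c(beta = 5, phi = 0.3, q = 0.05),
                        task_config(n_trials = 1500), seed = 12)
  met <- trials_to_switch_metrics(sim)
  ok <- !is.na(met$trial2asymp)
  expect_true(all(met$trial2asymp[ok] >= met$trial2sw[ok]))
})

test_that("history logit designs have the documented columns and recover", {
  sim <- simulate_agent("RL4p", c(alpha_pos = 0.7, alpha_neg = 0.5,
                                  beta = 2, phi = 0.3),
                        task_config(n_trials = 300), seed = 2)
  des <- history_logit_design(sim, n_lags = 3, variant = "decay")
  expect_equal(ncol(des), 1 + 9) # response + 3 column families x 3 lags
  des_b <- history_logit_design(sim, n_lags = 3, variant = "blocking")
  expect_equal(ncol(des_b), 1 + 2 * 2 + 2 * 3)

  # with every past trial rewarded, the reward-omission-blocked columns
  # vanish identically
  allr <- toy_trials(sample(c(-1, 1), 50, replace = TRUE), rep(1, 50))
  des_r <- history_logit_design(allr, n_lags = 3, variant = "blocking")
  expect_true(all(des_r$cr2_r1blk == 0) && all(des_r$cr3_r1blk == 0))

  expect_error(history_logit_design(toy_trials(c(1, 1), c(1, 1)), 5),
               "history")

  # generative recovery: choices from a logistic model with decaying
  # choice-reward weights
  set.seed(14)
  n <- 10000
  w <- c(1.2, 0.6, 0.3)
  ch <- numeric(n); rw <- numeric(n)
  ch[1:3] <- sample(c(-1, 1), 3, replace = TRUE)
  rw[1:3] <- rbinom(3, 1, 0.5)
  for (t in 4:n) {
    eta <- sum(w * ch[t - (1:3)] * rw[t - (1:3)])
    ch[t] <- ifelse(runif(1) < stats::plogis(eta), 1, -1)
    rw[t] <- rbinom(1, 1, 0.5)
  }
  des_g <- history_logit_design(toy_trials(ch, rw), n_lags = 3, "decay")
  fit <- fit_history_logit(des_g)
  est <- coef(fit)[c("cr1", "cr2", "cr3")]
  se <- sqrt(diag(stats::vcov(fit)))[c("cr1", "cr2", "cr3")]
  expect_true(all(abs(est - w) < 4 * se))
})
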