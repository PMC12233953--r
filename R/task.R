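#' Task configuration for the two-armed bandit environment
#'
#' The environment delivers a reward with probability `rho1` when the
#' choice matches the hidden rewarded side and `rho2` otherwise. In
#' `"cumulative_rewards"` mode (the full-task design) the hidden side
#' flips once the animal has earned a per-block target number of rewards
#' drawn uniformly from `block_reward_min:block_reward_max`; in
#' `"per_trial"` mode it flips independently each trial with probability
#' `q_env`. Note the generative switch process of the cumulative mode
#' deliberately differs from the per-trial switch probability the belief
#' models assume, so model misspecification can be studied.
#'
#' @param rho1 Reward probability for a correct choice (default 0.75).
#' @param rho2 Reward probability for an incorrect choice (default 0; the
#'   belief models assume a small positive value instead, see
#'   [run_agent()]).
#' @param switch_mode `"cumulative_rewards"` or `"per_trial"`.
#' @param block_reward_min,block_reward_max Bounds of the uniform per-block
#'   reward target (defaults 7 and 23).
#' @param q_env Per-trial hidden-state switch probability (per-trial mode).
#' @param n_trials Trials per session.
#' @return A list of class `bb_task_config`.
#' @export
task_config <- function(rho1 = 0.75, rho2 = 0,
                        switch_mode = c("cumulative_rewards", "per_trial"),
                        block_reward_min = 7L, block_reward_max = 23L,
                        q_env = 0.05, n_trials = 500L) {
  switch_mode <- match.arg(switch_mode)
  stopifnot(rho2 >= 0, rho2 < rho1, rho1 <= 1,
            block_reward_min >= 1, block_reward_min <= block_reward_max,
            q_env >= 0, q_env <= 0.5, n_trials >= 1)
  structure(list(rho1 = rho1, rho2 = rho2, switch_mode = switch_mode,
                 block_reward_min = as.integer(block_reward_min),
                 block_reward_max = as.integer(block_reward_max),
                 q_env = q_env, n_trials = as.integer(n_trials)),
            class = "bb_task_config")
}

#' One environment step
#'
#' Samples the reward for a choice and advances the hidden state and
#' block bookkeeping.
#'
#' @param state Hidden state, -1 or +1.
#' @param choice Choice, -1 or +1.
#' @param cfg A [task_config()].
#' @param block_state List with `count` (rewards earned so far in the
#'   block), `target` (this block's reward target, cumulative mode) and
#'   `block_index`; use [init_block_state()] for a fresh block.
#' @return List with `reward`, `next_state`, and the updated
#'   `block_state`.
#' @export
step_environment <- function(state, choice, cfg, block_state) {
  if (!choice %in% c(-1, 1)) stop("choice must be -1 or +1", call. = FALSE)
  if (!state %in% c(-1, 1)) stop("state must be -1 or +1", call. = FALSE)
  p <- if (choice == state) cfg$rho1 else cfg$rho2
  reward <- as.integer(runif(1) < p)
  next_state <- state
  if (cfg$switch_mode == "cumulative_rewards") {
    if (reward == 1L) block_state$count <- block_state$count + 1L
    if (block_state$count >= block_state$target) {
      next_state <- -state
      block_state$block_index <- block_state$block_index + 1L
      block_state$count <- 0L
      block_state$target <- draw_block_target(cfg)
    }
  } else {
    if (runif(1) < cfg$q_env) {
      next_state <- -state
      block_state$block_index <- block_state$block_index + 1L
    }
  }
  list(reward = reward, next_state = next_state, block_state = block_state)
}

#' @rdname step_environment
#' @export
init_block_state <- function(cfg) {
  list(count = 0L, target = draw_block_target(cfg), block_index = 0L)
}

draw_block_target <- function(cfg) {
  if (cfg$switch_mode != "cumulative_rewards") return(NA_integer_)
  sample(cfg$block_reward_min:cfg$block_reward_max, 1L)
}

#' Simulate agent sessions in the bandit task
#'
#' Runs the agent in closed loop against the generative environment: on
#' each trial the agent emits a choice probability from its latents, a
#' choice is sampled, the environment returns a reward, and the agent
#' updates. Latents (`p_right`, `belief_right`, `q_left`, `q_right`,
#' `value_diff`, `rpe`) are recorded pre-update on every row. Each session
#' draws its own RNG substream from `(seed, session)` so sessions are
#' independently reproducible, and agent state resets at session
#' boundaries.
#'
#' @param model Model name; see [bb_models()].
#' @param theta Named parameter vector.
#' @param cfg A [task_config()].
#' @param sessions Number of sessions.
#' @param seed Integer seed; identical `(model, theta, cfg, sessions,
#'   seed)` give identical tables.
#' @param subject_id Subject label.
#' @param rho1_model,rho2_model Assumed reward probabilities of the belief
#'   models (model side, distinct from the environment's).
#' @param zeta_convention See [rlfq3p_zeta()].
#' @return A trial tibble; see [validate_trial_table()] for the column
#'   contract.
#' @export
#' @examples
#' sim <- simulate_agent("BIfp", c(beta = 5, phi = 0.3, q = 0.05),
#'                       task_config(n_trials = 200), sessions = 2, seed = 1)
#' dplyr::count(sim, session_id)
simulate_agent <- function(model, theta, cfg = task_config(), sessions = 1L,
                           seed = 1L, subject_id = "sim",
                           rho1_model = 0.75, rho2_model = 1e-4,
                           zeta_convention = "one_minus_mean") {
  theta <- check_theta(model, theta)
  mode_code <- if (cfg$switch_mode == "cumulative_rewards") 0L else 1L
  out <- purrr::map(seq_len(sessions), function(s) {
    set.seed(session_seed(seed, s))
    raw <- bb_simulate_cpp(model_code(model), unname(theta), cfg$n_trials,
                           cfg$rho1, cfg$rho2, mode_code,
                           cfg$block_reward_min, cfg$block_reward_max,
                           cfg$q_env, rho1_model, rho2_model,
                           zeta_conv_code(zeta_convention))
    tibble::tibble(
      subject_id = subject_id,
      session_id = sprintf("s%03d", s),
      trial = seq_len(cfg$n_trials) - 1L,
      choice = raw$choice, reward = raw$reward, state = raw$state,
      block_index = raw$block_index,
      rewards_earned_in_block = raw$rewards_earned_in_block,
      p_right = raw$p_right, belief_right = raw$belief_right,
      q_left = raw$q_left, q_right = raw$q_right,
      value_diff = raw$value_diff, rpe = raw$rpe
    )
  })
  dplyr::bind_rows(out)
}

# derive a per-session seed below 2^31 from (seed, session)
session_seed <- function(seed, s) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(s) %% 2000L
}

#' Timing configuration for synthetic event times
#'
#' Families and parameters of the sampling distributions for the
#' within-trial event chain CI -> CO -> SI -> O -> SO0 -> SO1 -> SOf.
#' Defaults are log-normal-ish durations placed so that typical trials
#' pass the analysis filters (center poke below 0.8 s, port occupancy
#' below 6 s, movement below 3 s, side-out bout latency below 1 s);
#' `outlier_frac` of trials get one duration pushed beyond its filter
#' threshold to exercise trial rejection. Rewarded trials draw longer
#' port durations than unrewarded ones (licking time).
#'
#' @param center_meanlog,center_sdlog Log-normal parameters of the center
#'   poke duration (s).
#' @param mvmt_meanlog,mvmt_sdlog Movement time CO -> SI (s).
#' @param port_meanlog_rew,port_meanlog_unrew,port_sdlog Port duration
#'   (outcome to first side-out), by reward.
#' @param so_lat_rate Exponential rate of the side-out bout latency.
#' @param iti_meanlog,iti_sdlog Side-out to next center-in gap.
#' @param outlier_frac Fraction of trials given an out-of-filter duration.
#' @return A list of class `bb_timing_config`.
#' @export
timing_config <- function(center_meanlog = log(0.35), center_sdlog = 0.3,
                          mvmt_meanlog = log(0.8), mvmt_sdlog = 0.35,
                          port_meanlog_rew = log(2.2),
                          port_meanlog_unrew = log(0.9), port_sdlog = 0.35,
                          so_lat_rate = 20,
                          iti_meanlog = log(1.0), iti_sdlog = 0.4,
                          outlier_frac = 0) {
  stopifnot(outlier_frac >= 0, outlier_frac <= 1)
  structure(list(center_meanlog = center_meanlog, center_sdlog = center_sdlog,
                 mvmt_meanlog = mvmt_meanlog, mvmt_sdlog = mvmt_sdlog,
                 port_meanlog_rew = port_meanlog_rew,
                 port_meanlog_unrew = port_meanlog_unrew,
                 port_sdlog = port_sdlog, so_lat_rate = so_lat_rate,
                 iti_meanlog = iti_meanlog, iti_sdlog = iti_sdlog,
                 outlier_frac = outlier_frac),
            class = "bb_timing_config")
}

#' Populate synthetic event times on a trial table
#'
#' Samples the event chain CI <= CO <= SI <= O <= SO0 <= SO1 <= SOf per
#' trial (seconds from session start) and computes the derived durations
#' `center_dur`, `MVMT`, `ITI`, `port_dur`, `SO_lat` (see
#' [compute_durations()] for the definitions). With `outlier_frac > 0`, a
#' random subset of trials has one duration inflated past its filter
#' threshold.
#'
#' @param data Trial tibble with `choice`/`reward` (and session columns).
#' @param tcfg A [timing_config()].
#' @param seed Integer seed.
#' @return `data` with event-time and duration columns appended.
#' @export
generate_event_times <- function(data, tcfg = timing_config(), seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(data)
  center <- stats::rlnorm(n, tcfg$center_meanlog, tcfg$center_sdlog)
  mv_exec <- stats::rlnorm(n, tcfg$mvmt_meanlog, tcfg$mvmt_sdlog)
  rew <- !is.na(data$reward) & data$reward == 1
  port <- stats::rlnorm(n, ifelse(rew, tcfg$port_meanlog_rew,
                                  tcfg$port_meanlog_unrew), tcfg$port_sdlog)
  so_lat <- stats::rexp(n, tcfg$so_lat_rate)
  iti_gap <- stats::rlnorm(n, tcfg$iti_meanlog, tcfg$iti_sdlog)

  if (tcfg$outlier_frac > 0) {
    out_rows <- which(runif(n) < tcfg$outlier_frac)
    which_rule <- sample(4, length(out_rows), replace = TRUE)
    center[out_rows[which_rule == 1]] <- 0.8 + stats::rexp(sum(which_rule == 1), 2)
    port[out_rows[which_rule == 2]] <- 6 + stats::rexp(sum(which_rule == 2), 0.5)
    iti_gap[out_rows[which_rule == 3]] <- 3 + stats::rexp(sum(which_rule == 3), 0.5)
    so_lat[out_rows[which_rule == 4]] <- 1 + stats::rexp(sum(which_rule == 4), 1)
  }

  starts <- session_starts(data)
  CI <- CO <- SI <- O <- SO0 <- SO1 <- SOf <- numeric(n)
  t_clock <- 0
  for (i in seq_len(n)) {
    if (starts[i]) t_clock <- 0
    CI[i] <- t_clock + iti_gap[i]
    CO[i] <- CI[i] + center[i]
    SI[i] <- CO[i] + mv_exec[i]
    O[i] <- SI[i] + 0.01 # outcome follows side-in at system latency
    SO0[i] <- O[i] + max(port[i] - so_lat[i], 0.01)
    SO1[i] <- SO0[i] + so_lat[i]
    SOf[i] <- SO1[i] + 0.05 * stats::rexp(1, 1)
    t_clock <- SOf[i]
  }
  data$CI <- CI; data$CO <- CO; data$SI <- SI; data$O <- O
  data$SO0 <- SO0; data$SO1 <- SO1; data$SOf <- SOf
  compute_durations(data)
}
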