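#' Parameter bounds used by the optimizer
#'
#' Box constraints for each model's free parameters: learning rates and
#' the other unit-interval rates in `[0, 1]`, inverse temperature in
#' `[0, 50]`, stickiness in `[0, 10]` (unconstrained in sign for `RFLR`,
#' where it lives in `[-10, 10]`), belief switch rate in `(0, 0.5]`,
#' decay timescale `tau` in `[0.05, 100]`.
#'
#' @param model Model name.
#' @return List with named `lower` and `upper` vectors.
#' @export
model_bounds <- function(model) {
  b <- switch(model,
    RL4p = , RLCF = list(lower = c(alpha_pos = 1e-5, alpha_neg = 1e-5,
                                   beta = 0, phi = 0),
                         upper = c(alpha_pos = 1, alpha_neg = 1,
                                   beta = 50, phi = 10)),
    RFLR = list(lower = c(alpha = 0, phi = -10, tau = 0.05),
                upper = c(alpha = 10, phi = 10, tau = 100)),
    RLFQ3p = list(lower = c(alpha_pos = 1e-5, alpha_neg = 1e-5, beta = 0),
                  upper = c(alpha_pos = 1, alpha_neg = 1, beta = 50)),
    RL_meta = list(lower = c(alpha_pos = 1e-5, alpha_neg = 1e-5, beta = 0,
                             phi = 0, zeta = 0, alpha_nu = 0, psi = 0),
                   upper = c(alpha_pos = 1, alpha_neg = 1, beta = 50,
                             phi = 10, zeta = 1, alpha_nu = 1, psi = 1)),
    PearceHall = list(lower = c(alpha_pos = 1e-5, alpha_neg = 1e-5, phi = 0,
                                alpha_nu0 = 0, zeta = 0, psi = 0, beta = 0),
                      upper = c(alpha_pos = 1, alpha_neg = 1, phi = 10,
                                alpha_nu0 = 1, zeta = 1, psi = 1, beta = 50)),
    BIfp = list(lower = c(beta = 0, phi = 0, q = 1e-5),
                upper = c(beta = 50, phi = 10, q = 0.5)),
    BRLfwr = , BRLfw = list(lower = c(beta = 0, phi = 0, q = 1e-5,
                                      alpha_w = 0),
                            upper = c(beta = 50, phi = 10, q = 0.5,
                                      alpha_w = 1)),
    BRLwrp = list(lower = c(beta = 0, phi = 0, q = 1e-5, alpha_w = 0,
                            rho1 = 0.5, rho2 = 1e-5),
                  upper = c(beta = 50, phi = 10, q = 0.5, alpha_w = 1,
                            rho1 = 1, rho2 = 0.5)),
    stop("unknown model '", model, "'", call. = FALSE)
  )
  b
}

# one random multi-start initialization, drawn from the fitting
# initialization distributions (uniform for rates, Gamma(2, 0.2) for
# stickiness, Exp(1) for inverse temperature and RFLR scales, N(0,1) for
# the RFLR stickiness, Unif(0, 0.05) for the belief switch rate), then
# clipped into the bounds
sample_init <- function(model) {
  draw <- function(p) {
    switch(p,
      alpha_pos = , alpha_neg = , zeta = , alpha_nu = , psi = ,
      alpha_nu0 = , alpha_w = runif(1),
      phi = if (model == "RFLR") rnorm(1) else rgamma(1, shape = 2, scale = 0.2),
      beta = rexp(1),
      alpha = rexp(1),
      tau = rexp(1),
      q = runif(1, 0, 0.05),
      rho1 = runif(1, 0.5, 1),
      rho2 = runif(1, 1e-5, 0.2),
      stop("no init distribution for parameter ", p)
    )
  }
  nm <- model_param_names(model)
  th <- vapply(nm, draw, numeric(1))
  b <- model_bounds(model)
  pmin(pmax(th, b$lower + 1e-6), b$upper - 1e-6)
}

#' Negative log-likelihood of observed choices under a model
#'
#' Runs the agent forward through all trials (state resetting at each
#' session boundary), accumulating \eqn{-\ln P(c_t)} of the observed
#' choices. Missed trials are skipped without a state update. Choice
#' probabilities are floored at 1e-12 before the log.
#'
#' @param data Trial tibble (one subject; sessions in chronological
#'   order).
#' @param model Model name.
#' @param theta Named parameter vector; must lie within [model_bounds()].
#' @param rho1_model,rho2_model Assumed reward probabilities of the
#'   belief models.
#' @param zeta_convention See [rlfq3p_zeta()].
#' @return The scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(data, model, theta, rho1_model = 0.75,
                                    rho2_model = 1e-4,
                                    zeta_convention = "one_minus_mean") {
  theta <- check_theta(model, theta)
  b <- model_bounds(model)
  if (any(theta < b$lower - 1e-12) || any(theta > b$upper + 1e-12)) {
    bad <- names(theta)[theta < b$lower - 1e-12 | theta > b$upper + 1e-12]
    stop("parameter out of bounds: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  fw <- bb_forward_cpp(model_code(model), unname(theta), choice_int(data),
                       reward_int(data), session_starts(data),
                       rho1_model, rho2_model,
                       zeta_conv_code(zeta_convention), FALSE)
  fw$nll
}

#' Maximum-likelihood fit of an agent to a trial table
#'
#' Multi-start bounded optimization (L-BFGS-B) of the choice
#' log-likelihood. Each start samples an initialization from the fitting
#' initialization distributions (see [model_bounds()] internals) with a
#' seed nested in `seed`, so increasing `n_starts` can only improve the
#' returned optimum.
#'
#' @param data Trial tibble.
#' @param model Model name.
#' @param n_starts Number of random starts (default 10).
#' @param seed Integer seed governing the starts.
#' @param rho1_model,rho2_model,zeta_convention Passed to
#'   [negative_log_likelihood()].
#' @param maxit L-BFGS-B iteration cap per start.
#' @return An object of class `bb_fit` with elements `model`, `theta`
#'   (named estimates), `k`, `loglik`, `aic`, `n_trials_used`,
#'   `n_starts`, `best_start`, `converged`, and a per-start diagnostics
#'   tibble `starts`. Supports [tidy()] and [glance()].
#' @export
#' @examples
#' sim <- simulate_agent("RL4p", c(alpha_pos = 0.8, alpha_neg = 0.6,
#'                                 beta = 2, phi = 0.5),
#'                       task_config(n_trials = 300), seed = 1)
#' fit <- fit_agent(sim, "RL4p", n_starts = 3, seed = 1)
#' glance(fit)
fit_agent <- function(data, model, n_starts = 10L, seed = 1L,
                      rho1_model = 0.75, rho2_model = 1e-4,
                      zeta_convention = "one_minus_mean", maxit = 300L) {
  stopifnot(n_starts >= 1)
  b <- model_bounds(model)
  zc <- zeta_conv_code(zeta_convention)
  ch <- choice_int(data)
  rw <- reward_int(data)
  ss <- session_starts(data)
  code <- model_code(model)
  obj <- function(th) {
    bb_forward_cpp(code, th, ch, rw, ss, rho1_model, rho2_model, zc, FALSE)$nll
  }

  starts <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    set.seed(start_seed(seed, i))
    th0 <- sample_init(model)
    opt <- tryCatch(
      optim(unname(th0), obj, method = "L-BFGS-B",
            lower = unname(b$lower), upper = unname(b$upper),
            control = list(maxit = maxit, factr = 1e7)),
      error = function(e) NULL)
    starts[[i]] <- if (is.null(opt)) {
      tibble::tibble(start = i, nll = Inf, convergence = NA_integer_,
                     theta = list(th0))
    } else {
      tibble::tibble(start = i, nll = opt$value,
                     convergence = opt$convergence,
                     theta = list(stats::setNames(opt$par, names(th0))))
    }
  }
  starts <- dplyr::bind_rows(starts)
  if (all(!is.finite(starts$nll))) {
    stop("all optimization starts failed for model ", model, call. = FALSE)
  }
  best <- which.min(starts$nll)
  theta_hat <- starts$theta[[best]]
  nll <- starts$nll[best]
  n_used <- bb_forward_cpp(code, unname(theta_hat), ch, rw, ss,
                           rho1_model, rho2_model, zc, FALSE)$n_used
  k <- model_k(model)
  structure(list(
    model = model, theta = theta_hat, k = k,
    loglik = -nll, aic = 2 * k + 2 * nll,
    n_trials_used = n_used, n_starts = n_starts,
    best_start = best, converged = isTRUE(starts$convergence[best] == 0),
    starts = starts,
    fingerprint = data_fingerprint(data),
    rho1_model = rho1_model, rho2_model = rho2_model,
    zeta_convention = zeta_convention
  ), class = "bb_fit")
}

start_seed <- function(seed, i) {
  (as.integer(seed) %% 100000L) * 10000L + as.integer(i) %% 10000L
}

data_fingerprint <- function(data) {
  c(n = nrow(data),
    sum_choice = sum(data$choice, na.rm = TRUE),
    sum_reward = sum(data$reward, na.rm = TRUE))
}

#' @export
print.bb_fit <- function(x, ...) {
  cat(sprintf("<bb_fit> %s: loglik %.2f, AIC %.2f (k = %d, %d trials, %d starts)\n",
              x$model, x$loglik, x$aic, x$k, x$n_trials_used, x$n_starts))
  print(round(x$theta, 4))
  invisible(x)
}

#' @method tidy bb_fit
#' @export
tidy.bb_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @method glance bb_fit
#' @export
glance.bb_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$aic, k = x$k,
                 nobs = x$n_trials_used, n_starts = x$n_starts,
                 converged = x$converged)
}

#' AIC model comparison relative to a baseline
#'
#' @param fits A (optionally named) list of `bb_fit` objects on identical
#'   data.
#' @param baseline Baseline model name (default `"RL4p"`); its row has
#'   `delta_aic` exactly 0 and lower values indicate a better fit than
#'   the baseline.
#' @return Tibble with `model`, `k`, `loglik`, `aic`, `delta_aic`,
#'   ordered by `delta_aic`.
#' @export
aic_compare <- function(fits, baseline = "RL4p") {
  tab <- dplyr::bind_rows(lapply(fits, glance))
  fps <- lapply(fits, `[[`, "fingerprint")
  if (length(unique(lapply(fps, unname))) != 1) {
    stop("fits were computed on different data (fingerprints differ)",
         call. = FALSE)
  }
  if (!baseline %in% tab$model) {
    stop("baseline model '", baseline, "' not among the fits", call. = FALSE)
  }
  base_aic <- tab$AIC[tab$model == baseline][1]
  out <- tibble::tibble(model = tab$model, k = tab$k, loglik = tab$logLik,
                        aic = tab$AIC, delta_aic = tab$AIC - base_aic)
  dplyr::arrange(out, .data$delta_aic)
}

#' Log-likelihood restricted to trials just after block switches
#'
#' The agent is run over the full sequence (latents evolve on every
#' trial) but the summed log-likelihood counts only the first `window`
#' trials of each post-switch block; the AIC uses the model's full
#' parameter count.
#'
#' @param data Trial tibble with a `block_index` column.
#' @param model,theta Model and (typically fitted on the full data)
#'   parameters.
#' @param window Number of trials after each switch (default 5).
#' @param ... Passed to [run_agent()].
#' @return List with `loglik`, `aic`, `n_trials` (number of summands).
#' @export
around_switch_loglik <- function(data, model, theta, window = 5L, ...) {
  if (!"block_index" %in% names(data)) {
    stop("data has no block_index column", call. = FALSE)
  }
  run <- run_agent(data, model, theta, ...)
  key <- paste(run$subject_id, run$session_id)
  switched <- c(FALSE, diff(run$block_index) != 0) &
    c(FALSE, key[-1] == key[-nrow(run)])
  if (!any(switched)) stop("no block switches in data", call. = FALSE)
  # position within the current block, 1-based from the first post-switch trial
  pos <- integer(nrow(run))
  p <- Inf
  for (i in seq_len(nrow(run))) {
    p <- if (switched[i]) 1 else p + 1
    pos[i] <- p
  }
  sel <- is.finite(pos) & pos <= window & !is.na(run$loglik)
  ll <- sum(run$loglik[sel])
  k <- model_k(model)
  list(loglik = ll, aic = 2 * k - 2 * ll, n_trials = sum(sel))
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1).
#' @export
holm_bonferroni <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "holm")
}

#' Minimum attainable one-sided p of an exact paired sign-flip test
#'
#' Enumerates all `2^n` sign assignments of a paired sign-flip
#' permutation test for a configuration in which all paired differences
#' share one sign and have distinct magnitudes, and returns the smallest
#' achievable one-sided p-value. With 5 subjects this floor is 1/32 =
#' 0.03125, the resolution limit of nonparametric pairwise tests at that
#' sample size.
#'
#' @param n Number of subjects (1-20; enumeration is refused above 20).
#' @return The minimum one-sided p-value, `1 / 2^n`.
#' @export
#' @examples
#' min_sign_permutation_p(5) # 0.03125
min_sign_permutation_p <- function(n) {
  stopifnot(n >= 1)
  if (n > 20) stop("enumeration refused for n > 20", call. = FALSE)
  n <- as.integer(n)
  mags <- seq_len(n) # distinct magnitudes, all positive
  m <- 2^n
  # all sign assignments via the binary representation of 0..2^n-1
  signs <- matrix(1, nrow = m, ncol = n)
  idx <- 0:(m - 1)
  for (j in seq_len(n)) {
    signs[bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0, j] <- -1
  }
  stat <- as.numeric(signs %*% mags)
  obs <- sum(mags)
  mean(stat >= obs)
}
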