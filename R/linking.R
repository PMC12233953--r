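#' Configuration of the synthetic dopamine generator
#'
#' @param gain_pos,gain_neg Scaling of positive / negative RPE into the
#'   per-trial dopamine summary.
#' @param port_coef_pos,port_coef_neg Port-duration modulation for
#'   positive / negative RPE trials.
#' @param noise_sd Gaussian noise SD (> 0).
#' @return List of class `bb_synth_da_config`.
#' @export
synth_da_config <- function(gain_pos = 2, gain_neg = 1.5,
                            port_coef_pos = 0.1, port_coef_neg = -0.1,
                            noise_sd = 0.5) {
  stopifnot(noise_sd > 0)
  structure(list(gain_pos = gain_pos, gain_neg = gain_neg,
                 port_coef_pos = port_coef_pos,
                 port_coef_neg = port_coef_neg, noise_sd = noise_sd),
            class = "bb_synth_da_config")
}

#' Synthesize per-trial dopamine summaries from model RPEs
#'
#' `da_pt = gain_pos * rpe` on positive-RPE trials and `gain_neg * rpe`
#' on negative ones, plus sign-specific port-duration terms (when a
#' `port_dur` column is present) and Gaussian noise — mirroring the
#' structure of the RPE regression used for arbitration.
#'
#' @param data Trial tibble with an `rpe` column from the generating
#'   model.
#' @param cfg A [synth_da_config()].
#' @param seed Integer seed.
#' @return `data` with a `da_pt` column appended.
#' @export
synthesize_da <- function(data, cfg = synth_da_config(), seed = 1L) {
  if (!"rpe" %in% names(data) || all(is.na(data$rpe))) {
    stop("data has no rpe column; run the generating model first",
         call. = FALSE)
  }
  set.seed(as.integer(seed))
  pos <- !is.na(data$rpe) & data$rpe >= 0
  pd <- if ("port_dur" %in% names(data)) data$port_dur else rep(0, nrow(data))
  pd[is.na(pd)] <- 0
  da <- ifelse(pos, cfg$gain_pos * data$rpe + cfg$port_coef_pos * pd,
               cfg$gain_neg * data$rpe + cfg$port_coef_neg * pd) +
    rnorm(nrow(data), 0, cfg$noise_sd)
  da[is.na(data$rpe)] <- NA_real_
  data$da_pt <- da
  data
}

#' Build the RPE regression design
#'
#' Featurized covariates for regressing the per-trial dopamine summary
#' on a model's RPE: the RPE split by sign (`rpe_x_pos`, `rpe_x_neg`),
#' port duration split the same way, egocentric action (choice
#' laterality, -1/+1), session number, and log movement and center-poke
#' durations (floored at 1 ms). Rows with any missing cell are dropped.
#'
#' @param data Trial tibble with `da_pt` and an RPE column.
#' @param rpe_col Name of the RPE column (default `"rpe"`).
#' @return Tibble with response `da_pt` and the predictor columns.
#' @export
rpe_design <- function(data, rpe_col = "rpe") {
  rpe <- data[[rpe_col]]
  if (is.null(rpe)) stop("no column '", rpe_col, "' in data", call. = FALSE)
  pos <- as.numeric(rpe >= 0)
  pd <- if ("port_dur" %in% names(data)) data$port_dur else rep(0, nrow(data))
  mv <- if ("MVMT" %in% names(data)) data$MVMT else rep(1, nrow(data))
  cd <- if ("center_dur" %in% names(data)) data$center_dur else rep(1, nrow(data))
  sess <- if ("session_id" %in% names(data)) {
    as.numeric(factor(data$session_id))
  } else rep(1, nrow(data))
  out <- tibble::tibble(
    da_pt = data$da_pt,
    rpe_x_pos = rpe * pos,
    rpe_x_neg = rpe * (1 - pos),
    port_dur_x_pos = pd * pos,
    port_dur_x_neg = pd * (1 - pos),
    ego_action = data$choice,
    session_num = sess,
    log_mvmt = log(pmax(mv, 1e-3)),
    log_center_dur = log(pmax(cd, 1e-3))
  )
  out[stats::complete.cases(out), ]
}

#' Fit the Gaussian RPE regression with a held-out evaluation
#'
#' Ordinary least squares (the Gaussian maximum-likelihood fit) on a
#' random train split, with summed per-trial Gaussian log-likelihood
#' reported on the held-out split (residual SD estimated on the train
#' split).
#'
#' @param design Output of [rpe_design()] (>= 50 rows).
#' @param split Training fraction (default 0.7).
#' @param seed Integer seed for the split.
#' @param train_idx Optional explicit training row indices (overrides
#'   `split`/`seed`), used to share one split across models.
#' @return List with `fit` (the `lm`), `coefficients`, `llk_train`,
#'   `llk_test`, `n_train`, `n_test`.
#' @export
fit_rpe_regression <- function(design, split = 0.7, seed = 1L,
                               train_idx = NULL) {
  n <- nrow(design)
  if (n < 50) stop("need at least 50 trials after filtering", call. = FALSE)
  keep <- vapply(design, function(x) var(x) > 0, logical(1))
  keep["da_pt"] <- TRUE
  design <- design[, keep]
  if (is.null(train_idx)) {
    set.seed(as.integer(seed))
    train_idx <- sample(n, floor(split * n))
  }
  if (n - length(train_idx) < 10) {
    stop("fewer than 10 held-out trials", call. = FALSE)
  }
  tr <- design[train_idx, ]
  te <- design[-train_idx, ]
  fit <- lm(da_pt ~ ., data = tr)
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  sigma <- sqrt(mean(stats::residuals(fit)^2)) # Gaussian MLE of the scale
  llk <- function(d) {
    sum(dnorm(d$da_pt - predict(fit, d), 0, sigma, log = TRUE))
  }
  list(fit = fit, coefficients = coef(fit),
       llk_train = llk(tr), llk_test = llk(te),
       n_train = nrow(tr), n_test = nrow(te))
}

#' Cross-validated log-likelihood model arbitration
#'
#' For each candidate model's RPE column, fits the RPE regression on a
#' shared 70-30 train/test split and reports the held-out summed
#' log-likelihood relative to the baseline model. The split is identical
#' across models so differences reflect the RPE covariates only.
#'
#' @param data Trial tibble with `da_pt` and one `rpe_<model>` column per
#'   candidate (see [add_model_rpes()]).
#' @param models Character vector of candidate model names.
#' @param baseline Baseline model (default `"RL4p"`).
#' @param split Training fraction.
#' @param seed Integer seed for the split.
#' @return Tibble with `model`, `llk_cv`, `delta_llk_cv` (model minus
#'   baseline; positive favours the model).
#' @export
cv_llk_compare <- function(data, models, baseline = "RL4p", split = 0.7,
                           seed = 1L) {
  cols <- paste0("rpe_", models)
  miss <- setdiff(cols, names(data))
  if (length(miss)) {
    stop("missing RPE columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!baseline %in% models) {
    stop("baseline must be among the candidate models", call. = FALSE)
  }
  # one shared split over the rows complete for every candidate
  designs <- lapply(cols, function(cl) rpe_design(data, rpe_col = cl))
  n <- unique(vapply(designs, nrow, integer(1)))
  if (length(n) != 1) {
    stop("candidate RPE columns cover different trial subsets", call. = FALSE)
  }
  set.seed(as.integer(seed))
  train_idx <- sample(n, floor(split * n))
  llks <- vapply(designs, function(d) {
    fit_rpe_regression(d, train_idx = train_idx)$llk_test
  }, numeric(1))
  names(llks) <- models
  tibble::tibble(model = models, llk_cv = unname(llks),
                 delta_llk_cv = unname(llks - llks[baseline]))
}

#' Append per-model RPE columns to a trial table
#'
#' Runs each fitted (or given) model over the observed choices/rewards
#' and stores its RPE trace as `rpe_<model>`.
#'
#' @param data Trial tibble.
#' @param thetas Named list of parameter vectors, one per model name.
#' @param ... Passed to [run_agent()].
#' @return `data` with one extra column per model.
#' @export
add_model_rpes <- function(data, thetas, ...) {
  for (m in names(thetas)) {
    run <- run_agent(data, m, thetas[[m]], ...)
    data[[paste0("rpe_", m)]] <- run$rpe
  }
  data
}

#' Lagged reward design for the past-reward regression
#'
#' For each trial with `n_lags` same-session predecessors: `Reward` is
#' the current reward, `R_chosen` counts rewarded past trials (t-1 ..
#' t-n_lags) at the currently chosen port, `R_unchosen` those at the
#' opposite port, and `Switch`/`Stay` indicate whether the current
#' choice differs from the previous one. Rows lacking history are
#' dropped.
#'
#' @param data Trial tibble; the response column (`da_pt` by default)
#'   must be present.
#' @param n_lags Number of past trials (default 4).
#' @param response Response column name.
#' @return Tibble with `response`, `Reward`, `R_chosen`, `R_unchosen`,
#'   `Switch`, `Stay`, `subject_id`.
#' @export
build_lagged_design <- function(data, n_lags = 4L, response = "da_pt") {
  if (n_lags < 1) stop("n_lags must be >= 1", call. = FALSE)
  if (!response %in% names(data)) {
    stop("no response column '", response, "'", call. = FALSE)
  }
  key <- paste(data$subject_id, data$session_id)
  ch <- lapply(seq_len(n_lags), function(i) lag_in_session(data$choice, key, i))
  rw <- lapply(seq_len(n_lags), function(i) lag_in_session(data$reward, key, i))
  r_ch <- r_un <- rep(0, nrow(data))
  complete <- !is.na(data$choice)
  for (i in seq_len(n_lags)) {
    complete <- complete & !is.na(ch[[i]]) & !is.na(rw[[i]])
    r_ch <- r_ch + as.numeric(rw[[i]] == 1 & ch[[i]] == data$choice)
    r_un <- r_un + as.numeric(rw[[i]] == 1 & ch[[i]] == -data$choice)
  }
  sw <- data$choice != ch[[1]]
  out <- tibble::tibble(
    response = data[[response]],
    Reward = data$reward, R_chosen = r_ch, R_unchosen = r_un,
    Switch = as.numeric(sw), Stay = as.numeric(!sw),
    subject_id = data$subject_id
  )[complete, ]
  out[!is.na(out$response), ]
}

#' Fit the lagged past-reward model
#'
#' Fixed-effects path: ordinary least squares of the response on
#' `Reward`, `R_chosen` and `R_unchosen`, each interacted with the
#' `Switch`/`Stay` indicators. Hierarchical path: the same fixed effects
#' with per-subject random intercept and `R_chosen`/`R_unchosen` slopes
#' via `lme4::lmer`; falls back to fixed effects with a warning when
#' only one subject is present.
#'
#' @param design Output of [build_lagged_design()].
#' @param hierarchical Use the mixed-model path.
#' @return Tibble of slope estimates with Wald 95% confidence bounds
#'   (`term`, `estimate`, `conf_low`, `conf_high`).
#' @export
fit_lagged_model <- function(design, hierarchical = FALSE) {
  fixed <- response ~ 0 + Switch + Stay + Reward:Switch + Reward:Stay +
    R_chosen:Switch + R_chosen:Stay + R_unchosen:Switch + R_unchosen:Stay
  if (hierarchical && length(unique(design$subject_id)) < 2) {
    warning("single subject: falling back to fixed effects")
    hierarchical <- FALSE
  }
  if (!hierarchical) {
    fit <- lm(fixed, data = design)
    est <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    f <- stats::update(fixed,
                       . ~ . + (1 + R_chosen + R_unchosen | subject_id))
    fit <- lme4::lmer(f, data = design,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  tibble::tibble(term = names(est), estimate = unname(est),
                 conf_low = unname(est - 1.96 * se),
                 conf_high = unname(est + 1.96 * se))
}

#' Mean dopamine by three-back same-port reward history
#'
#' Restricted to rewarded trials where the same port was chosen at `t`
#' and the three preceding trials, bins the per-trial dopamine summary
#' by the reward history code `aaa` .. `AAA` (uppercase rewarded),
#' ordered by increasing number then recency of past rewards.
#'
#' @param data Trial tibble with `da_pt`.
#' @return Tibble with `code`, `n`, `mean_da`.
#' @export
history_binned_da <- function(data) {
  stopifnot("da_pt" %in% names(data))
  key <- paste(data$subject_id, data$session_id)
  c0 <- data$choice
  c1 <- lag_in_session(data$choice, key, 1L)
  c2 <- lag_in_session(data$choice, key, 2L)
  c3 <- lag_in_session(data$choice, key, 3L)
  r1 <- lag_in_session(data$reward, key, 1L)
  r2 <- lag_in_session(data$reward, key, 2L)
  r3 <- lag_in_session(data$reward, key, 3L)
  ok <- !is.na(c0) & !is.na(c1) & !is.na(c2) & !is.na(c3) &
    c0 == c1 & c1 == c2 & c2 == c3 &
    !is.na(r1) & !is.na(r2) & !is.na(r3) &
    !is.na(data$reward) & data$reward == 1 & !is.na(data$da_pt)
  lett <- function(r) ifelse(r == 1, "A", "a")
  d <- tibble::tibble(code = paste0(lett(r3), lett(r2), lett(r1)),
                      da = data$da_pt)[ok, ]
  tab <- dplyr::summarise(dplyr::group_by(d, .data$code),
                          n = dplyr::n(), mean_da = mean(.data$da),
                          .groups = "drop")
  # order by (number of rewards, recency-weighted value)
  nr <- vapply(strsplit(tab$code, ""), function(x) sum(x == "A"), 0)
  rec <- vapply(strsplit(tab$code, ""), function(x) {
    sum((x == "A") * c(1, 2, 4))
  }, 0)
  tab[order(nr, rec), ]
}
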