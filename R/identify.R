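#' Default simulation parameter ranges
#'
#' Uniform ranges from which generating parameters are drawn for the
#' model-identification and parameter-recovery studies. The published
#' mouse fits are not deposited, so these defaults are plausible ranges
#' centred on the fitted values the study reports (standard-RL learning
#' rates near 0.7-0.9, stickiness well below the value weight, belief
#' switch rates bracketing the task's effective per-trial reversal rate
#' of roughly 0.04); treat them as free settings of the study.
#'
#' @return Tibble with columns `model`, `param`, `min`, `max`.
#' @export
default_param_ranges <- function() {
  rng <- function(model, ...) {
    v <- list(...)
    tibble::tibble(model = model, param = names(v),
                   min = vapply(v, `[`, numeric(1), 1),
                   max = vapply(v, `[`, numeric(1), 2))
  }
  dplyr::bind_rows(
    rng("RL4p", alpha_pos = c(0.5, 0.95), alpha_neg = c(0.5, 0.9),
        beta = c(1, 4), phi = c(0.1, 1.5)),
    rng("RLCF", alpha_pos = c(0.5, 0.95), alpha_neg = c(0.5, 0.9),
        beta = c(1, 4), phi = c(0.1, 1.5)),
    rng("RFLR", alpha = c(0.5, 2.5), phi = c(0.2, 1.5), tau = c(0.8, 3)),
    rng("RLFQ3p", alpha_pos = c(0.5, 0.95), alpha_neg = c(0.5, 0.9),
        beta = c(1, 4)),
    rng("RL_meta", alpha_pos = c(0.5, 0.95), alpha_neg = c(0.3, 0.8),
        beta = c(1, 4), phi = c(0.1, 1.5), zeta = c(0.3, 0.9),
        alpha_nu = c(0.1, 0.6), psi = c(0.1, 0.6)),
    rng("PearceHall", alpha_pos = c(0.5, 0.95), alpha_neg = c(0.3, 0.9),
        phi = c(0.1, 1.5), alpha_nu0 = c(0.3, 0.9), zeta = c(0.3, 0.9),
        psi = c(0.1, 0.6), beta = c(1, 5)),
    rng("BIfp", beta = c(2, 8), phi = c(0.1, 1.5), q = c(0.01, 0.08)),
    rng("BRLfwr", beta = c(2, 8), phi = c(0.1, 1.5), q = c(0.01, 0.08),
        alpha_w = c(0.01, 0.5))
  )
}

#' Draw generating parameters from a range table
#'
#' Each parameter is drawn independently and uniformly within its
#' `[min, max]` range.
#'
#' @param ranges Range tibble as returned by [default_param_ranges()].
#' @param model Model name.
#' @return Named parameter vector.
#' @export
sample_generating_params <- function(ranges, model) {
  r <- ranges[ranges$model == model, ]
  if (nrow(r) == 0) stop("no parameter ranges for model ", model, call. = FALSE)
  nm <- model_param_names(model)
  if (!setequal(r$param, nm)) {
    stop("ranges for ", model, " must cover exactly: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  r <- r[match(nm, r$param), ]
  stopifnot(all(r$min <= r$max))
  stats::setNames(runif(nrow(r), r$min, r$max), r$param)
}

#' Simulate / cross-fit / confusion-matrix model identification
#'
#' For each generating model and iteration: draw parameters from its
#' empirical range, simulate sessions, fit every candidate model by
#' maximum likelihood, and record the AIC winner. Ties are broken by
#' fewest parameters, then lexicographic model name. Row `i`, column `j`
#' of the resulting matrix estimates P(best-fit model j | data generated
#' by model i).
#'
#' @param models Character vector of model names (both generators and
#'   candidates).
#' @param ranges Parameter range tibble; see [default_param_ranges()].
#' @param n_iter Iterations per generating model.
#' @param cfg A [task_config()] for the simulated sessions.
#' @param sessions Sessions per iteration.
#' @param n_starts Optimizer starts per fit.
#' @param seed Integer seed.
#' @return An object of class `bb_confusion`: list with the row-stochastic
#'   `matrix`, the winner `counts`, and a `provenance` tibble (iteration,
#'   generating model, drawn parameters, per-candidate AICs, winner,
#'   seed).
#' @export
identification_study <- function(models, ranges = default_param_ranges(),
                                 n_iter = 100L, cfg = task_config(),
                                 sessions = 5L, n_starts = 3L, seed = 1L) {
  stopifnot(n_iter >= 1)
  prov <- list()
  counts <- matrix(0L, length(models), length(models),
                   dimnames = list(models, models))
  failed <- 0L
  it_seed <- 0L
  for (gi in seq_along(models)) {
    gen <- models[gi]
    for (it in seq_len(n_iter)) {
      it_seed <- it_seed + 1L
      set.seed(start_seed(seed, it_seed))
      theta <- sample_generating_params(ranges, gen)
      sim <- simulate_agent(gen, theta, cfg, sessions = sessions,
                            seed = start_seed(seed, it_seed))
      aics <- vapply(models, function(m) {
        f <- tryCatch(fit_agent(sim, m, n_starts = n_starts,
                                seed = start_seed(seed, it_seed)),
                      error = function(e) NULL)
        if (is.null(f)) NA_real_ else f$aic
      }, numeric(1))
      if (all(is.na(aics))) { failed <- failed + 1L; next }
      winner <- aic_winner(aics)
      counts[gen, winner] <- counts[gen, winner] + 1L
      prov[[length(prov) + 1L]] <- tibble::tibble(
        gen_model = gen, iter = it, seed = start_seed(seed, it_seed),
        theta = list(theta), aics = list(aics), winner = winner)
    }
  }
  rowsum_ <- rowSums(counts)
  mat <- sweep(counts, 1, pmax(rowsum_, 1), "/")
  structure(list(matrix = mat, counts = counts, n_iter = n_iter,
                 n_failed = failed,
                 provenance = dplyr::bind_rows(prov)),
            class = "bb_confusion")
}

# lowest AIC wins; ties broken by fewest parameters, then name
aic_winner <- function(aics) {
  ok <- !is.na(aics)
  cand <- names(aics)[ok]
  a <- aics[ok]
  best <- a <= min(a) + 1e-9
  cand <- cand[best]
  if (length(cand) > 1) {
    ks <- vapply(cand, model_k, integer(1))
    cand <- sort(cand[ks == min(ks)])
  }
  cand[1]
}

#' @export
print.bb_confusion <- function(x, ...) {
  cat(sprintf("<bb_confusion> %d generating models x %d iterations (%d failed)\n",
              nrow(x$matrix), x$n_iter, x$n_failed))
  print(round(x$matrix, 3))
  invisible(x)
}

#' @method tidy bb_confusion
#' @export
tidy.bb_confusion <- function(x, ...) {
  m <- x$matrix
  tibble::tibble(
    gen_model = rep(rownames(m), times = ncol(m)),
    fit_model = rep(colnames(m), each = nrow(m)),
    p = as.vector(m)
  )
}

#' Parameter-recovery study
#'
#' Draw generating parameters, simulate, refit the generating model, and
#' compare truth against estimate. Pairs whose estimate lies more than 6
#' standard deviations from the mean of the true values (per parameter)
#' are masked as outliers before the correlation is computed.
#'
#' @inheritParams identification_study
#' @param model Generating (and fitted) model name.
#' @return An object of class `bb_recovery`: list with the raw `pairs`
#'   tibble (`iter`, `param`, `truth`, `estimate`, `outlier`) and a
#'   `correlations` tibble (`param`, `r`, `n`).
#' @export
parameter_recovery <- function(model, ranges = default_param_ranges(),
                               n_iter = 100L, cfg = task_config(),
                               sessions = 5L, n_starts = 3L, seed = 1L) {
  stopifnot(n_iter >= 2)
  rows <- list()
  for (it in seq_len(n_iter)) {
    set.seed(start_seed(seed, it))
    theta <- sample_generating_params(ranges, model)
    sim <- simulate_agent(model, theta, cfg, sessions = sessions,
                          seed = start_seed(seed, it))
    fit <- tryCatch(fit_agent(sim, model, n_starts = n_starts,
                              seed = start_seed(seed, it)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      iter = it, param = names(theta), truth = unname(theta),
      estimate = unname(fit$theta[names(theta)]))
  }
  pairs <- dplyr::bind_rows(rows)
  pairs <- dplyr::group_by(pairs, .data$param)
  pairs <- dplyr::mutate(pairs,
                         outlier = outlier_mask_6sd(.data$truth, .data$estimate))
  pairs <- dplyr::ungroup(pairs)
  cors <- dplyr::summarise(
    dplyr::group_by(pairs, .data$param),
    r = {
      keep <- !.data$outlier
      tr <- .data$truth[keep]; es <- .data$estimate[keep]
      if (length(tr) < 3 || sd(tr) == 0 || sd(es) == 0) NA_real_
      else cor(tr, es)
    },
    n = sum(!.data$outlier), .groups = "drop")
  structure(list(model = model, pairs = pairs, correlations = cors),
            class = "bb_recovery")
}

#' Outlier mask: estimates beyond 6 SD of the mean true value
#'
#' @param truth,estimate Numeric vectors of equal length.
#' @return Logical vector, `TRUE` for masked pairs.
#' @export
outlier_mask_6sd <- function(truth, estimate) {
  m <- mean(truth)
  s <- sd(truth)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(truth)))
  abs(estimate - m) > 6 * s
}

#' @export
print.bb_recovery <- function(x, ...) {
  cat(sprintf("<bb_recovery> %s (%d iterations)\n", x$model,
              length(unique(x$pairs$iter))))
  print(x$correlations)
  invisible(x)
}
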