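#' @title Trial-history behavioural statistics
#' @description Encodings and summary statistics of choice behaviour as a
#'   function of recent outcome history, plus history logistic-regression
#'   design matrices. History windows never cross session boundaries.
#' @name behavior-metrics
NULL

# per-session lag that returns NA at session starts
lag_in_session <- function(x, key, n = 1L) {
  out <- dplyr::lag(x, n)
  same <- dplyr::lag(key, n) == key
  out[is.na(same) | !same] <- NA
  out
}

#' Encode three-trial outcome histories
#'
#' Encodes, for every trial `t`, the outcomes at `t-3`, `t-2`, `t-1` as a
#' three-letter code over `{A, a, B, b}`: the trial at `t-3` is the
#' reference and always `A`/`a`; later trials are `A`/`a` if the same
#' port as the reference was chosen and `B`/`b` otherwise; uppercase
#' means rewarded. For example, unrewarded at port 1, rewarded at port 2,
#' unrewarded at port 2 encodes as `"aBb"`. Trials lacking a complete
#' same-session history get `NA`.
#'
#' @param data Trial tibble.
#' @return `data` with a `hist3` character column appended.
#' @export
encode_history3 <- function(data) {
  key <- paste(data$subject_id, data$session_id)
  c1 <- lag_in_session(data$choice, key, 1L)
  c2 <- lag_in_session(data$choice, key, 2L)
  c3 <- lag_in_session(data$choice, key, 3L)
  r1 <- lag_in_session(data$reward, key, 1L)
  r2 <- lag_in_session(data$reward, key, 2L)
  r3 <- lag_in_session(data$reward, key, 3L)
  letter <- function(ch, rw, ref) {
    same <- ch == ref
    up <- rw == 1
    ifelse(same & up, "A", ifelse(same, "a", ifelse(up, "B", "b")))
  }
  code <- paste0(letter(c3, r3, c3), letter(c2, r2, c3), letter(c1, r1, c3))
  complete <- !is.na(c1) & !is.na(c2) & !is.na(c3) &
    !is.na(r1) & !is.na(r2) & !is.na(r3)
  code[!complete] <- NA_character_
  data$hist3 <- code
  data
}

#' Switch probability by three-trial outcome history
#'
#' For each observed history code, the fraction of trials on which the
#' choice at `t` differed from the choice at `t-1`.
#'
#' @param data Trial tibble ([encode_history3()] is applied if the
#'   `hist3` column is absent).
#' @return Tibble with `hist3`, `n`, `p_switch`.
#' @export
switch_probability_by_history <- function(data) {
  if (!"hist3" %in% names(data)) data <- encode_history3(data)
  key <- paste(data$subject_id, data$session_id)
  prev <- lag_in_session(data$choice, key, 1L)
  d <- tibble::tibble(hist3 = data$hist3,
                      sw = data$choice != prev)
  d <- dplyr::filter(d, !is.na(.data$hist3), !is.na(.data$sw))
  dplyr::summarise(dplyr::group_by(d, .data$hist3),
                   n = dplyr::n(), p_switch = mean(.data$sw),
                   .groups = "drop")
}

#' Stay probability after two same-port outcomes
#'
#' Restricted to trials where the animal chose the same port at `t-2`
#' and `t-1`, the two-outcome history is coded `RR`, `RU`, `UR` or `UU`
#' (outcome at `t-2` then `t-1`; `R` rewarded, `U` unrewarded), and the
#' stay probability is the fraction of trials where the choice at `t`
#' repeated the choice at `t-1`.
#'
#' @param data Trial tibble.
#' @return Tibble with `history`, `n`, `p_stay`.
#' @export
stay_probability_by_2history <- function(data) {
  key <- paste(data$subject_id, data$session_id)
  c1 <- lag_in_session(data$choice, key, 1L)
  c2 <- lag_in_session(data$choice, key, 2L)
  r1 <- lag_in_session(data$reward, key, 1L)
  r2 <- lag_in_session(data$reward, key, 2L)
  qual <- !is.na(c1) & !is.na(c2) & c1 == c2 &
    !is.na(r1) & !is.na(r2) & !is.na(data$choice)
  d <- tibble::tibble(
    history = paste0(ifelse(r2 == 1, "R", "U"), ifelse(r1 == 1, "R", "U")),
    stay = data$choice == c1
  )[qual, ]
  dplyr::summarise(dplyr::group_by(d, .data$history),
                   n = dplyr::n(), p_stay = mean(.data$stay),
                   .groups = "drop")
}

#' Choice accuracy aligned to block switches
#'
#' Probability of choosing the currently rewarded port as a function of
#' trial offset from a block switch; offset 0 is the first trial under
#' the new contingency.
#'
#' @param data Trial tibble with `state` and `block_index` columns.
#' @param window Offsets `-window .. +window` are tabulated.
#' @return Tibble with `offset`, `n`, `p_correct`.
#' @export
block_switch_aligned_accuracy <- function(data, window = 10L) {
  stopifnot(all(c("state", "block_index") %in% names(data)))
  key <- paste(data$subject_id, data$session_id)
  n <- nrow(data)
  switch_pos <- which(c(FALSE, diff(data$block_index) != 0) &
                        c(FALSE, key[-1] == key[-n]))
  correct <- as.numeric(data$choice == data$state)
  rows <- list()
  for (off in seq(-window, window)) {
    idx <- switch_pos + off
    ok <- idx >= 1 & idx <= n
    idx <- idx[ok]
    same <- key[idx] == key[switch_pos[ok]]
    vals <- correct[idx][same]
    vals <- vals[!is.na(vals)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      offset = off, n = length(vals),
      p_correct = if (length(vals)) mean(vals) else NA_real_)
  }
  dplyr::bind_rows(rows)
}

#' Trials to switch and to asymptotic choice within blocks
#'
#' For each block: `trial2sw` is the 1-based index (from block start) of
#' the first correct choice; `trial2asymp` is the first index from which
#' the correct port was chosen on that trial and the two following
#' trials. Both are `NA` if never achieved within the block.
#'
#' @param data Trial tibble with `state` and `block_index`.
#' @return Tibble with one row per (subject, session, block).
#' @export
trials_to_switch_metrics <- function(data) {
  stopifnot(all(c("state", "block_index") %in% names(data)))
  d <- dplyr::group_by(data, .data$subject_id, .data$session_id,
                       .data$block_index)
  dplyr::summarise(d,
    n_trials = dplyr::n(),
    trial2sw = {
      corr <- .data$choice == .data$state
      i <- which(corr)
      if (length(i)) i[1] else NA_integer_
    },
    trial2asymp = {
      corr <- !is.na(.data$choice == .data$state) & .data$choice == .data$state
      ok <- which(corr & dplyr::lead(corr, 1, default = FALSE) &
                    dplyr::lead(corr, 2, default = FALSE))
      if (length(ok)) ok[1] else NA_integer_
    },
    .groups = "drop")
}

#' History logistic-regression design matrix
#'
#' Builds the lagged design for regressing the current choice on outcome
#' history. With signed choices \eqn{\tilde C = \pm 1} and rewards
#' \eqn{R \in \{0,1\}}, the `"decay"` variant has, at each lag `i`,
#' the interaction \eqn{\tilde C_{t-i} R_{t-i}}, the reward main effect
#' \eqn{R_{t-i}} and the choice main effect \eqn{\tilde C_{t-i}} (3
#' column families). The `"blocking"` variant splits the interaction at
#' lags `i >= 2` by whether the trial at `t-1` was rewarded
#' (`cr<i>_r1blk` for \eqn{1[R_{t-1}=0]}, `cr<i>_r1` for
#' \eqn{1[R_{t-1}=1]}) while keeping both main-effect families at all
#' lags including lag 1. Rows with incomplete same-session history are
#' dropped; the response is the indicator of a rightward choice.
#'
#' @param data Trial tibble.
#' @param n_lags Number of lags (>= 1; >= 2 for the blocking variant).
#' @param variant `"decay"` or `"blocking"`.
#' @return Tibble with the response column `y` and predictor columns.
#' @export
history_logit_design <- function(data, n_lags = 5L,
                                 variant = c("decay", "blocking")) {
  variant <- match.arg(variant)
  stopifnot(n_lags >= 1)
  if (variant == "blocking" && n_lags < 2) {
    stop("blocking variant needs n_lags >= 2", call. = FALSE)
  }
  key <- paste(data$subject_id, data$session_id)
  ch <- lapply(seq_len(n_lags), function(i) lag_in_session(data$choice, key, i))
  rw <- lapply(seq_len(n_lags), function(i) lag_in_session(data$reward, key, i))
  out <- tibble::tibble(y = as.integer(data$choice == 1))
  if (variant == "decay") {
    for (i in seq_len(n_lags)) {
      out[[paste0("cr", i)]] <- ch[[i]] * rw[[i]]
      out[[paste0("r", i)]] <- rw[[i]]
      out[[paste0("c", i)]] <- ch[[i]]
    }
  } else {
    r1_unrew <- as.numeric(rw[[1]] == 0)
    for (i in 2:n_lags) {
      out[[paste0("cr", i, "_r1blk")]] <- ch[[i]] * rw[[i]] * r1_unrew
      out[[paste0("cr", i, "_r1")]] <- ch[[i]] * rw[[i]] * (1 - r1_unrew)
    }
    for (i in seq_len(n_lags)) {
      out[[paste0("r", i)]] <- rw[[i]]
      out[[paste0("c", i)]] <- ch[[i]]
    }
  }
  out <- out[stats::complete.cases(out), ]
  if (nrow(out) == 0) {
    stop("n_lags exceeds the available history", call. = FALSE)
  }
  out
}

#' Fit the history logistic regression
#'
#' @param design Output of [history_logit_design()].
#' @return A `glm` (binomial) fit of `y` on all design columns.
#' @export
fit_history_logit <- function(design) {
  glm(y ~ ., data = design, family = binomial())
}
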