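#' Adaptive iteratively reweighted penalized least-squares baseline
#'
#' Estimates a smooth baseline under sparse positive transients by
#' iterating weighted Whittaker smoothing (second-difference penalty
#' `lambda`) with weights that progressively ignore points above the
#' current baseline; iteration stops when the mass of negative residuals
#' falls below 0.1% of the total signal mass or after `max_iter`
#' passes.
#'
#' @param y Numeric series (finite, length >= 10).
#' @param lambda Smoothness penalty (default 1e8, suited to 20 Hz
#'   recordings with minutes-scale bleaching trends).
#' @param max_iter Maximum reweighting iterations.
#' @return The baseline series, same length as `y`.
#' @export
airpls_baseline <- function(y, lambda = 1e8, max_iter = 50L) {
  n <- length(y)
  if (n < 10) stop("series too short (need length >= 10)", call. = FALSE)
  if (any(!is.finite(y))) stop("series contains non-finite values", call. = FALSE)
  D <- Matrix::bandSparse(n - 2, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  total <- sum(abs(y))
  for (i in seq_len(max_iter)) {
    A <- DtD + Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(A, w * y))
    d <- y - z
    neg <- d < 0
    dssn <- abs(sum(d[neg]))
    if (dssn < 0.001 * total) break
    w[!neg] <- 0
    w[neg] <- exp(i * abs(d[neg]) / dssn)
    w[1] <- exp(i * max(d[neg]) / dssn)
    w[n] <- w[1]
  }
  z
}

#' Robust isosbestic artifact correction
#'
#' Robust (Huber-loss) linear regression from the detrended reference
#' channel to the detrended signal channel; the fitted artifact is
#' subtracted from the signal.
#'
#' @param signal_470 Detrended dopamine-sensitive channel.
#' @param reference_415 Detrended isosbestic reference channel.
#' @return The corrected signal series.
#' @export
isosbestic_correct <- function(signal_470, reference_415) {
  stopifnot(length(signal_470) == length(reference_415))
  if (sd(reference_415) < 1e-12) {
    warning("reference channel has zero variance; skipping regression")
    return(signal_470)
  }
  fit <- suppressWarnings(
    MASS::rlm(signal_470 ~ reference_415, maxit = 100))
  as.numeric(signal_470 - stats::fitted(fit))
}

#' Per-session z-scoring
#'
#' @param x Numeric series (length >= 2, nonzero SD).
#' @return `x` standardized to mean 0, SD 1 over the session.
#' @export
zscore_session <- function(x) {
  if (length(x) < 2) stop("series too short to z-score", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("zero standard deviation; cannot z-score", call. = FALSE)
  (x - mean(x)) / s
}

#' Full photometry preprocessing chain
#'
#' Channel-specific baselining ([airpls_baseline()]) of both channels,
#' robust isosbestic correction ([isosbestic_correct()]), then
#' per-session z-scoring ([zscore_session()]).
#'
#' @param signal_470,reference_415 Raw channel series.
#' @param lambda,max_iter Passed to [airpls_baseline()].
#' @return List with `zda` (the processed Z(DA) series), `corrected`,
#'   `baseline_470`, `baseline_415`.
#' @export
preprocess_photometry <- function(signal_470, reference_415,
                                  lambda = 1e8, max_iter = 50L) {
  b470 <- airpls_baseline(signal_470, lambda, max_iter)
  b415 <- airpls_baseline(reference_415, lambda, max_iter)
  corrected <- isosbestic_correct(signal_470 - b470, reference_415 - b415)
  list(zda = zscore_session(corrected), corrected = corrected,
       baseline_470 = b470, baseline_415 = b415)
}

#' Align a series to event times
#'
#' Linear interpolation of the series onto a fixed grid around each
#' event, at the native sample spacing. With `de_base = TRUE` the value
#' interpolated at the event time is subtracted from each row.
#'
#' @param series Numeric series.
#' @param timestamps Sample times in seconds (strictly increasing).
#' @param event_times Event times, one per trial; events outside the
#'   recording span give all-missing rows with a warning.
#' @param window `c(pre, post)` seconds around the event.
#' @param de_base Subtract the value at the event time.
#' @return Trial x time matrix with the relative-time grid in
#'   `attr(, "grid")`.
#' @export
align_to_event <- function(series, timestamps, event_times,
                           window = c(1, 2), de_base = FALSE) {
  stopifnot(length(series) == length(timestamps))
  dt <- stats::median(diff(timestamps))
  grid <- seq(-abs(window[1]), abs(window[2]), by = dt)
  out <- matrix(NA_real_, length(event_times), length(grid))
  oob <- 0L
  for (i in seq_along(event_times)) {
    ev <- event_times[i]
    if (is.na(ev)) next
    if (ev < timestamps[1] || ev > timestamps[length(timestamps)]) {
      oob <- oob + 1L
      next
    }
    out[i, ] <- approx(timestamps, series, xout = ev + grid, rule = 1)$y
    if (de_base) {
      out[i, ] <- out[i, ] - approx(timestamps, series, xout = ev, rule = 1)$y
    }
  }
  if (oob > 0) warning(oob, " event(s) outside the recording span")
  attr(out, "grid") <- grid
  out
}

#' Per-trial dopamine peak/trough summary
#'
#' Maximum of the aligned signal in the post-outcome window for rewarded
#' trials, minimum for unrewarded ones.
#'
#' @param aligned Trial x time matrix from [align_to_event()].
#' @param rewarded Logical (or 0/1) vector, one per trial.
#' @param window `c(from, to)` seconds after the event (default 0-1 s).
#' @return Numeric vector `da_pt`, `NA` where the window is all-missing.
#' @export
da_peak_trough <- function(aligned, rewarded, window = c(0, 1)) {
  grid <- attr(aligned, "grid")
  stopifnot(!is.null(grid), nrow(aligned) == length(rewarded))
  sel <- grid >= window[1] & grid <= window[2]
  apply_row <- function(i) {
    v <- aligned[i, sel]
    v <- v[!is.na(v)]
    if (!length(v) || is.na(rewarded[i])) return(NA_real_)
    if (rewarded[i] == 1) max(v) else min(v)
  }
  vapply(seq_len(nrow(aligned)), apply_row, numeric(1))
}

#' Derived trial durations from event times
#'
#' `MVMT = CI(t) - SOf(t-1)`, `ITI = CI(t) - SO1(t-1)` (previous trial of
#' the same session), `center_dur = CO - CI`, `port_dur = SO1 - O`,
#' `SO_lat = SO1 - SO0`.
#'
#' @param data Trial tibble with event-time columns.
#' @return `data` with duration columns appended/overwritten.
#' @export
compute_durations <- function(data) {
  key <- paste(data$subject_id, data$session_id)
  data$MVMT <- data$CI - lag_in_session(data$SOf, key, 1L)
  data$ITI <- data$CI - lag_in_session(data$SO1, key, 1L)
  data$center_dur <- data$CO - data$CI
  data$port_dur <- data$SO1 - data$O
  data$SO_lat <- data$SO1 - data$SO0
  data
}

#' Filter trials by movement-duration criteria
#'
#' Keeps trials with `center_dur <= 0.8`, `port_dur <= 6`, `MVMT <= 3`
#' and `SO_lat <= 1` (all thresholds inclusive and configurable). A
#' missing duration does not reject a trial (the first trial of a
#' session has no movement time).
#'
#' @param data Trial tibble with duration columns.
#' @param thresholds Named list of inclusive upper bounds.
#' @return List with `kept` (the surviving rows) and `report` (tibble of
#'   per-rule rejection counts plus totals).
#' @export
filter_trials <- function(data,
                          thresholds = list(center_dur = 0.8, port_dur = 6,
                                            MVMT = 3, SO_lat = 1)) {
  fails <- lapply(names(thresholds), function(col) {
    if (!col %in% names(data)) return(rep(FALSE, nrow(data)))
    v <- data[[col]]
    !is.na(v) & v > thresholds[[col]]
  })
  names(fails) <- names(thresholds)
  any_fail <- Reduce(`|`, fails, rep(FALSE, nrow(data)))
  report <- tibble::tibble(
    rule = names(thresholds),
    threshold = unlist(thresholds),
    n_rejected = unname(vapply(fails, function(f) sum(f), integer(1)))
  )
  list(kept = data[!any_fail, ], report = report,
       n_total = nrow(data), n_kept = sum(!any_fail))
}

#' Synthetic two-channel photometry session
#'
#' Generates dLight-like traces at a fixed sampling rate: a slow
#' exponential bleaching trend per channel, a shared motion artifact
#' (smoothed random walk) appearing in both channels, RPE-driven
#' transients at outcome times in the signal channel only (amplitude
#' proportional to the trial RPE, width scaled by the port duration),
#' and white noise. The pure transient trace is returned as ground truth
#' for recovery tests.
#'
#' @param data Trial tibble with outcome times `O`, rewards and an `rpe`
#'   column (e.g. from [run_agent()] or [simulate_agent()]); `port_dur`
#'   is used to scale transient width when present.
#' @param rate Sampling rate in Hz (default 20).
#' @param gain Scaling from RPE to fluorescence transient amplitude.
#' @param bleach_amp,bleach_tau Amplitude and timescale (s) of the
#'   bleaching trend.
#' @param artifact_sd Amplitude of the shared motion artifact.
#' @param noise_sd White-noise SD per channel.
#' @param seed Integer seed.
#' @return List with `time`, `signal_470`, `reference_415`,
#'   `truth` (noise-free transient trace) and the input `data`.
#' @export
simulate_photometry <- function(data, rate = 20, gain = 1,
                                bleach_amp = 5, bleach_tau = 600,
                                artifact_sd = 0.5, noise_sd = 0.1,
                                seed = 1L) {
  stopifnot(all(c("O", "rpe") %in% names(data)))
  set.seed(as.integer(seed))
  t_end <- max(data$SOf, data$O, na.rm = TRUE) + 5
  time <- seq(0, t_end, by = 1 / rate)
  n <- length(time)

  truth <- numeric(n)
  for (i in seq_len(nrow(data))) {
    if (is.na(data$O[i]) || is.na(data$rpe[i])) next
    width <- 0.3
    if ("port_dur" %in% names(data) && !is.na(data$port_dur[i])) {
      width <- 0.2 + 0.1 * pmin(data$port_dur[i], 4)
    }
    dt <- time - data$O[i]
    mask <- dt >= 0 & dt < 6 * width
    truth[mask] <- truth[mask] +
      gain * data$rpe[i] * (dt[mask] / width) * exp(1 - dt[mask] / width)
  }

  artifact <- as.numeric(stats::filter(rnorm(n, 0, artifact_sd),
                                       rep(1 / 20, 20), sides = 1))
  artifact[is.na(artifact)] <- 0
  bleach470 <- bleach_amp * exp(-time / bleach_tau) + 10
  bleach415 <- 0.8 * bleach_amp * exp(-time / (bleach_tau * 1.2)) + 8

  signal_470 <- bleach470 + artifact + truth + rnorm(n, 0, noise_sd)
  reference_415 <- bleach415 + 0.9 * artifact + rnorm(n, 0, noise_sd)
  list(time = time, signal_470 = signal_470, reference_415 = reference_415,
       truth = truth, data = data)
}
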