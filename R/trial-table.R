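#' @title Trial-table data model
#'
#' @description One row per bandit trial. Required columns: `subject_id`,
#' `session_id`, `trial` (0-based, strictly increasing within a session),
#' `choice` (-1 left / +1 right, `NA` for missed trials), `reward` (0/1).
#' Optional columns: hidden `state` (-1/+1), `block_index`,
#' `rewards_earned_in_block` (resets to 0 when the block increments),
#' event times in seconds (`CI`, `CO`, `SI`, `O`, `SO0`, `SO1`, `SOf`,
#' non-decreasing within a trial), derived durations (`MVMT`, `ITI`,
#' `center_dur`, `port_dur`, `SO_lat`), the per-trial dopamine summary
#' `da_pt`, and model latents (`p_right`, `belief_right`, `q_left`,
#' `q_right`, `value_diff`, `rpe`). Missed trials keep their row but all
#' outcome fields are missing.
#'
#' @name trial-table
NULL

bb_column_order <- c(
  "subject_id", "session_id", "trial", "choice", "reward", "state",
  "block_index", "rewards_earned_in_block",
  "CI", "CO", "SI", "O", "SO0", "SO1", "SOf",
  "MVMT", "ITI", "center_dur", "port_dur", "SO_lat",
  "da_pt", "p_right", "belief_right", "q_left", "q_right",
  "value_diff", "rpe"
)

bb_event_cols <- c("CI", "CO", "SI", "O", "SO0", "SO1", "SOf")

#' Validate a trial table
#'
#' Checks the domain and ordering invariants of the trial-table contract
#' (see [trial-table]) and fails with an informative error naming the
#' first offending row.
#'
#' @param data A trial tibble.
#' @return `data`, invisibly, if valid.
#' @export
validate_trial_table <- function(data) {
  need <- c("subject_id", "session_id", "trial", "choice", "reward")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(data$choice %in% c(-1, 1) | is.na(data$choice)))
  if (length(bad)) {
    stop(sprintf("invalid choice value %s at row %d (must be -1, +1 or NA)",
                 data$choice[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(!(data$reward %in% c(0, 1) | is.na(data$reward)))
  if (length(bad)) {
    stop(sprintf("invalid reward value %s at row %d (must be 0, 1 or NA)",
                 data$reward[bad[1]], bad[1]), call. = FALSE)
  }
  if ("state" %in% names(data)) {
    bad <- which(!(data$state %in% c(-1, 1) | is.na(data$state)))
    if (length(bad)) {
      stop(sprintf("invalid hidden state at row %d", bad[1]), call. = FALSE)
    }
  }
  bad <- which(is.na(data$choice) & !is.na(data$reward))
  if (length(bad)) {
    stop(sprintf("row %d has a reward but no choice (missed trials must have missing outcomes)",
                 bad[1]), call. = FALSE)
  }
  # trial index strictly increasing within each session
  key <- paste(data$subject_id, data$session_id)
  for (k in unique(key)) {
    tr <- data$trial[key == k]
    if (any(diff(tr) <= 0)) {
      stop("non-monotone trial index within session ", k, call. = FALSE)
    }
  }
  # event-order invariant CI <= CO <= SI <= O <= SO0 <= SO1 <= SOf
  ev_present <- intersect(bb_event_cols, names(data))
  if (length(ev_present) >= 2) {
    ev <- as.matrix(data[, ev_present])
    d <- ev[, -1, drop = FALSE] - ev[, -ncol(ev), drop = FALSE]
    bad <- which(apply(d < 0, 1, any, na.rm = TRUE))
    if (length(bad)) {
      i <- bad[1]
      j <- which(d[i, ] < 0)[1]
      stop(sprintf(
        "event-order invariant violated at row %d: %s > %s (events must be non-decreasing CI <= CO <= SI <= O <= SO0 <= SO1 <= SOf)",
        i, ev_present[j], ev_present[j + 1]), call. = FALSE)
    }
  }
  invisible(data)
}

#' Read a trial table from delimited text
#'
#' Reads a CSV/TSV session table, normalizes the choice coding to
#' -1/+1 (accepts 0/1 or L/R input), validates the trial-table contract
#' and sorts rows by (subject, session, trial).
#'
#' @param path File path.
#' @param dialect `"csv"` (default) or `"tsv"`.
#' @return A validated trial tibble.
#' @export
read_session_table <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  data <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(readr::problems(data))) {
    p <- readr::problems(data)
    stop(sprintf("malformed row at line %d of %s: %s", p$row[1], path,
                 p$expected[1]), call. = FALSE)
  }
  data$choice <- normalize_choice(data$choice)
  for (col in c("trial", "reward", "state", "block_index",
                "rewards_earned_in_block")) {
    if (col %in% names(data)) data[[col]] <- as.integer(data[[col]])
  }
  validate_trial_table(data)
  data <- dplyr::arrange(data, .data$subject_id, .data$session_id, .data$trial)
  tibble::as_tibble(data)
}

normalize_choice <- function(x) {
  if (is.character(x)) {
    up <- toupper(trimws(x))
    out <- dplyr::case_when(
      up %in% c("L", "LEFT") ~ -1,
      up %in% c("R", "RIGHT") ~ 1,
      up %in% c("NA", "") ~ NA_real_,
      TRUE ~ suppressWarnings(as.numeric(x))
    )
    x <- out
  }
  x <- as.numeric(x)
  if (all(x %in% c(0, 1) | is.na(x)) && any(x == 0, na.rm = TRUE)) {
    x <- 2 * x - 1 # 0/1 coding -> -1/+1
  }
  x
}

#' Write a trial table to delimited text
#'
#' Writes with a deterministic column order (the canonical trial-table
#' columns first, extras after, see [trial-table]) and floating-point
#' values rounded to 9 decimal places so a write/read round trip is
#' stable at that precision.
#'
#' @param data A valid trial tibble.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_session_table <- function(data, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_trial_table(data)
  ord <- c(intersect(bb_column_order, names(data)),
           setdiff(names(data), bb_column_order))
  data <- data[, ord]
  data <- dplyr::mutate(data, dplyr::across(dplyr::where(is.double),
                                            ~ round(.x, 9)))
  writer <- if (dialect == "csv") readr::write_csv else readr::write_tsv
  writer(data, path, progress = FALSE)
  invisible(path)
}
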