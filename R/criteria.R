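# Task-progression rules: FR1 acquisition, exclusion, FR5 fixed duration,
# PR breakpoint stabilization.

#' Task-progression criteria configuration
#'
#' Parameters of the standard progression rules:
#' \itemize{
#'   \item FR1 acquisition: an active:inactive discrimination ratio of at
#'     least `fr1_ratio_min` (default 3:1) and at least `fr1_rewards_min`
#'     reinforcements (default 20), on `consecutive_days` consecutive days
#'     (default 3). Mice not acquiring within `fr1_max_days` (default 17)
#'     are excluded.
#'   \item FR5: a fixed block of `fr5_days` sessions (default 3).
#'   \item PR stabilization: the breakpoint is considered stable when the
#'     daily reward counts over `consecutive_days` consecutive days agree to
#'     within ±`pr_rel_tol` (default 10%) of the window mean, or within
#'     `pr_abs_tol` (default 1) reward when the window mean is below
#'     `pr_small_threshold` (default 10).
#' }
#'
#' @param fr1_ratio_min,fr1_rewards_min,consecutive_days,fr1_max_days,fr5_days,pr_rel_tol,pr_abs_tol,pr_small_threshold
#'   See description; all must be positive.
#' @return An object of class `criteria_config`.
#' @export
criteria_config <- function(fr1_ratio_min = 3.0, fr1_rewards_min = 20,
                            consecutive_days = 3, fr1_max_days = 17,
                            fr5_days = 3, pr_rel_tol = 0.10, pr_abs_tol = 1,
                            pr_small_threshold = 10) {
  vals <- c(fr1_ratio_min, fr1_rewards_min, consecutive_days, fr1_max_days,
            fr5_days, pr_rel_tol, pr_abs_tol, pr_small_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all criteria parameters must be positive", call. = FALSE)
  structure(list(fr1_ratio_min = fr1_ratio_min,
                 fr1_rewards_min = fr1_rewards_min,
                 consecutive_days = as.integer(consecutive_days),
                 fr1_max_days = as.integer(fr1_max_days),
                 fr5_days = as.integer(fr5_days),
                 pr_rel_tol = pr_rel_tol, pr_abs_tol = pr_abs_tol,
                 pr_small_threshold = pr_small_threshold),
            class = "criteria_config")
}

#' Does a single FR1 session meet the daily acquisition criterion?
#'
#' True when the active:inactive ratio is at least `fr1_ratio_min` (an
#' infinite ratio — no inactive pokes at all — passes) and the session
#' delivered at least `fr1_rewards_min` reinforcements.
#'
#' @param summary A one-row session summary from [summarize_session()] (or
#'   anything with `active_inactive_ratio` and `rewards` fields).
#' @param cfg A [criteria_config()].
#' @return Logical scalar.
#' @export
fr1_day_passes <- function(summary, cfg = criteria_config()) {
  ratio <- summary$active_inactive_ratio
  if (is.na(ratio)) return(FALSE)
  ratio >= cfg$fr1_ratio_min && summary$rewards >= cfg$fr1_rewards_min
}

#' Day on which FR1 acquisition criteria are met
#'
#' Scans per-day session summaries (days contiguous from 1) for the first
#' run of `consecutive_days` consecutive passing days and returns the last
#' day of that run (passing on days 5, 6, 7 gives day 7). Returns `NA` if
#' no such run occurs within the supplied days; the mouse is excluded if it
#' has not acquired by day `fr1_max_days` (see [criteria_config()]).
#'
#' @param summaries A data frame of per-day FR1 summaries (rows ordered by
#'   `day`, days contiguous from 1), or a list of one-row summaries.
#' @param cfg A [criteria_config()].
#' @return Integer day of acquisition, or `NA_integer_` if the criteria were
#'   not met within the supplied days.
#' @export
fr1_acquisition_day <- function(summaries, cfg = criteria_config()) {
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, summaries)
  n <- nrow(summaries)
  if (n == 0L) return(NA_integer_)
  if (!is.null(summaries$day) && !identical(as.integer(summaries$day), seq_len(n)))
    stop("summaries must cover contiguous days starting at day 1", call. = FALSE)
  pass <- vapply(seq_len(n), function(i) fr1_day_passes(summaries[i, ], cfg),
                 logical(1))
  run <- 0L
  for (d in seq_len(n)) {
    run <- if (pass[d]) run + 1L else 0L
    if (run >= cfg$consecutive_days) return(d)
  }
  NA_integer_
}

#' Breakpoint stabilization over consecutive progressive-ratio days
#'
#' Scans windows of `consecutive_days` consecutive days of PR reward counts
#' for the earliest stabilizing window. A window stabilizes when every
#' day's count lies within `tol` of the window mean, where
#' `tol = max(pr_abs_tol, pr_rel_tol * mean)` for window means at or above
#' `pr_small_threshold`, and `tol = pr_abs_tol` below it (few rewards earn
#' an absolute, not relative, allowance). The stabilized breakpoint is the
#' window mean.
#'
#' @param rewards_by_day Numeric vector of daily PR reward counts, ordered
#'   by day.
#' @param cfg A [criteria_config()].
#' @return A list: `stabilized` (logical), `day` (last day of the earliest
#'   stabilizing window, or `NA`), `breakpoint` (window mean, or `NA`).
#' @examples
#' pr_stabilization(c(20, 21, 20))  # stabilized on day 3, breakpoint 20.33
#' pr_stabilization(c(10, 14, 10))  # not stabilized: 14 deviates too far
#' @export
pr_stabilization <- function(rewards_by_day, cfg = criteria_config()) {
  w <- cfg$consecutive_days
  n <- length(rewards_by_day)
  if (n >= w) {
    for (d in w:n) {
      win <- rewards_by_day[(d - w + 1L):d]
      m <- mean(win)
      tol <- if (m >= cfg$pr_small_threshold)
        max(cfg$pr_abs_tol, cfg$pr_rel_tol * m) else cfg$pr_abs_tol
      if (all(abs(win - m) <= tol))
        return(list(stabilized = TRUE, day = d, breakpoint = m))
    }
  }
  list(stabilized = FALSE, day = NA_integer_, breakpoint = NA_real_)
}
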