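# Session state machine: applies schedule, timeout and termination rules to
# a time-ordered poke stream and emits a complete event log.

#' Session configuration
#'
#' Bundles the reinforcement schedule with the session-level operating rules
#' of a nose-poke chamber: session length, reinforcement cap, post-response
#' timeout, and the reward delivered.
#'
#' Defaults follow standard practice for sucrose-reward nose-poke sessions:
#' 60-minute sessions, a 1-second timeout after each counted active-well
#' response, and a 10 uL drop of 20% sucrose per reinforcement. The
#' 50-reinforcement cap conventionally applies only to FR1 acquisition
#' sessions; later phases run the full session (`max_rewards = Inf`).
#'
#' @param schedule A `schedule_spec` ([fr_schedule()] / [pr_schedule()]).
#' @param max_duration_s Positive real, session length in seconds (default 3600).
#' @param max_rewards Positive integer or `Inf`: the session ends as soon as
#'   this many reinforcements have been delivered (default `Inf`).
#' @param timeout_s Non-negative real, the timeout opened by each counted
#'   active-well response (default 1).
#' @param reward_volume_ul Reward volume in microlitres (default 10).
#' @param sucrose_pct Sucrose concentration, percent w/v (default 20).
#' @return An object of class `session_config`.
#' @export
session_config <- function(schedule, max_duration_s = 3600, max_rewards = Inf,
                           timeout_s = 1, reward_volume_ul = 10,
                           sucrose_pct = 20) {
  schedule <- as_schedule(schedule)
  if (!is.numeric(max_duration_s) || max_duration_s <= 0)
    stop("`max_duration_s` must be positive", call. = FALSE)
  if (!(is.infinite(max_rewards) || (is.numeric(max_rewards) && max_rewards >= 1)))
    stop("`max_rewards` must be a positive count or Inf", call. = FALSE)
  if (!is.numeric(timeout_s) || timeout_s < 0)
    stop("`timeout_s` must be non-negative", call. = FALSE)
  structure(list(schedule = schedule,
                 max_duration_s = max_duration_s,
                 max_rewards = max_rewards,
                 timeout_s = timeout_s,
                 reward_volume_ul = reward_volume_ul,
                 sucrose_pct = sucrose_pct),
            class = "session_config")
}

#' Has a session reached a termination condition?
#'
#' A session terminates when either the time limit is reached or the
#' reinforcement cap (if finite) is hit, whichever comes first.
#'
#' @param n_rewards Reinforcements delivered so far.
#' @param t_s Session time in seconds.
#' @param config A `session_config`.
#' @return A list with `terminated` (logical) and `reason`
#'   (`"REWARD_CAP"`, `"TIME_LIMIT"`, or `NA` if still running).
#' @export
session_terminated <- function(n_rewards, t_s, config) {
  stopifnot(inherits(config, "session_config"))
  if (n_rewards >= config$max_rewards)
    return(list(terminated = TRUE, reason = "REWARD_CAP"))
  if (t_s >= config$max_duration_s)
    return(list(terminated = TRUE, reason = "TIME_LIMIT"))
  list(terminated = FALSE, reason = NA_character_)
}

new_event_log <- function(mouse_id, genotype, day, phase, config,
                          pokes, rewards, end_t_s, end_reason) {
  structure(list(mouse_id = mouse_id, genotype = genotype,
                 day = as.integer(day), phase = phase, config = config,
                 pokes = pokes, rewards = rewards,
                 end_t_s = end_t_s, end_reason = end_reason),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log: mouse %s (%s), day %d, phase %s>\n",
              x$mouse_id, x$genotype, x$day, x$phase))
  cat(sprintf("  %d pokes (%d in timeout), %d rewards, ended at %.1f s (%s)\n",
              nrow(x$pokes), sum(x$pokes$in_timeout), nrow(x$rewards),
              x$end_t_s, x$end_reason))
  invisible(x)
}

#' Run a session state machine over a poke stream
#'
#' Consumes a time-ordered stream of nose pokes and applies the schedule,
#' timeout and termination rules, producing a complete [event log][run_session].
#'
#' Rules, applied poke by poke in time order:
#' \itemize{
#'   \item A counted active-well poke advances progress toward the current
#'     response requirement ([requirement_for()]). When progress reaches the
#'     requirement, a reward is delivered at that poke's time, progress
#'     resets, and the requirement is recomputed.
#'   \item Every counted active poke (rewarded or not) opens a timeout window
#'     `(t, t + timeout_s]`. Any poke in either well falling inside an open
#'     window is logged with `in_timeout = TRUE`, is not counted, and does
#'     not extend the window.
#'   \item Counted inactive pokes are logged but never advance the schedule
#'     and never open a timeout.
#'   \item The session ends at `min(max_duration_s, time of reward number
#'     max_rewards)`; later pokes are discarded.
#' }
#'
#' Event times are recorded at millisecond resolution (the clock resolution
#' of typical chamber firmware); input times are rounded half-up to the
#' nearest millisecond on entry and all window/limit comparisons are done in
#' integer milliseconds, so replaying a logged stream reproduces the log
#' exactly. Equal-time pokes are processed in input order, the later one
#' treated as (infinitesimally) later — in particular it falls inside a
#' timeout window opened by the earlier one.
#'
#' @param config A [session_config()].
#' @param pokes A data frame with columns `t_s` (non-negative seconds from
#'   session start, non-decreasing) and `well` (`"active"` / `"inactive"`).
#' @param mouse_id,genotype,day,phase Metadata recorded in the log; `phase`
#'   is one of `"FR1"`, `"FR5"`, `"PR"`.
#' @return An object of class `event_log`: a list with fields `mouse_id`,
#'   `genotype`, `day`, `phase`, `config`, `pokes` (data frame `t_s`, `well`,
#'   `in_timeout`, `counted`), `rewards` (data frame `t_s`, `index`),
#'   `end_t_s` and `end_reason` (`"TIME_LIMIT"` or `"REWARD_CAP"`).
#' @examples
#' cfg <- session_config(fr_schedule(1), timeout_s = 1)
#' stream <- data.frame(t_s = c(0, 0.5, 2), well = c("active", "active", "active"))
#' log <- run_session(cfg, stream, phase = "FR1")
#' log$rewards  # rewards at t = 0 and t = 2; the poke at 0.5 was in timeout
#' @export
run_session <- function(config, pokes, mouse_id = "m1",
                        genotype = NA_character_, day = 1L,
                        phase = c("FR1", "FR5", "PR")) {
  stopifnot(inherits(config, "session_config"))
  phase <- match.arg(phase)
  if (is.null(pokes) || nrow(as.data.frame(pokes)) == 0L) {
    pokes <- data.frame(t_s = numeric(0), well = character(0))
  }
  pokes <- as.data.frame(pokes)
  if (!all(c("t_s", "well") %in% names(pokes)))
    stop("`pokes` must have columns `t_s` and `well`", call. = FALSE)
  t_s <- as.numeric(pokes$t_s)
  well <- as.character(pokes$well)
  if (any(is.na(t_s)) || any(t_s < 0))
    stop("poke times must be non-negative", call. = FALSE)
  if (is.unsorted(t_s))
    stop("poke stream must be sorted by time", call. = FALSE)
  if (!all(well %in% c("active", "inactive")))
    stop("`well` must be 'active' or 'inactive'", call. = FALSE)

  # integer-millisecond clock: deterministic window/limit comparisons
  t_ms <- round_half_up(t_s * 1000)
  timeout_ms <- round_half_up(config$timeout_s * 1000)
  dur_ms <- round_half_up(config$max_duration_s * 1000)
  max_rewards <- config$max_rewards
  sched <- config$schedule
  is_active <- well == "active"

  n <- length(t_ms)
  in_timeout <- logical(n)
  counted <- logical(n)
  reward_t <- numeric(0)
  progress <- 0L
  req <- requirement_for(sched, 0L)
  n_rewards <- 0L
  win_end <- -1           # end of the open timeout window, ms
  end_ms <- dur_ms
  end_reason <- "TIME_LIMIT"
  keep <- n               # pokes retained (those before session end)

  for (i in seq_len(n)) {
    ti <- t_ms[i]
    if (ti >= dur_ms) { keep <- i - 1L; break }
    if (timeout_ms > 0 && ti <= win_end) { in_timeout[i] <- TRUE; next }
    counted[i] <- TRUE
    if (is_active[i]) {
      win_end <- ti + timeout_ms
      progress <- progress + 1L
      if (progress >= req) {
        n_rewards <- n_rewards + 1L
        reward_t[n_rewards] <- ti
        progress <- 0L
        req <- requirement_for(sched, n_rewards)
        if (n_rewards >= max_rewards) {
          end_ms <- ti
          end_reason <- "REWARD_CAP"
          keep <- i
          break
        }
      }
    }
  }

  idx <- seq_len(keep)
  poke_df <- data.frame(t_s = t_ms[idx] / 1000,
                        well = well[idx],
                        in_timeout = in_timeout[idx],
                        counted = counted[idx],
                        stringsAsFactors = FALSE)
  reward_df <- data.frame(t_s = reward_t / 1000,
                          index = seq_along(reward_t))
  new_event_log(mouse_id = mouse_id, genotype = genotype, day = day,
                phase = phase, config = config,
                pokes = poke_df, rewards = reward_df,
                end_t_s = end_ms / 1000, end_reason = end_reason)
}
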