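# Canonical CSV event-log format and per-session summaries.
#
# One row per event, header fixed as:
#   mouse_id,genotype,day,phase,t_ms,event,well,in_timeout,counted
# Events: session_start, poke, reward, session_end. Times are integer
# milliseconds. For poke rows, in_timeout/counted are 0/1; for reward and
# boundary rows those fields are empty. The session_end row carries the end
# reason (TIME_LIMIT / REWARD_CAP) in the `well` column.

EVENT_LOG_HEADER <- "mouse_id,genotype,day,phase,t_ms,event,well,in_timeout,counted"

#' Write an event log to CSV
#'
#' Serialises an [event log][run_session] to the canonical plain-text format:
#' header `mouse_id,genotype,day,phase,t_ms,event,well,in_timeout,counted`,
#' one row per event (`session_start`, `poke`, `reward`, `session_end`),
#' sorted by time with a reward row immediately after the poke that earned
#' it. Times are integer milliseconds. The `session_end` row records the end
#' reason in its `well` column. The session configuration is not serialised;
#' supply it to [read_event_log()] if round-tripping it matters.
#'
#' @param log An `event_log`.
#' @param path File path or connection to write to.
#' @return `path`, invisibly.
#' @seealso [read_event_log()], [summarize_session()]
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "event_log"))
  np <- nrow(log$pokes)
  nr <- nrow(log$rewards)
  t_ms <- c(0,
            round_half_up(log$pokes$t_s * 1000),
            round_half_up(log$rewards$t_s * 1000),
            round_half_up(log$end_t_s * 1000))
  event <- c("session_start", rep("poke", np), rep("reward", nr), "session_end")
  well <- c("", log$pokes$well, rep("", nr), log$end_reason)
  in_to <- c("", as.character(as.integer(log$pokes$in_timeout)), rep("", nr), "")
  cnt <- c("", as.character(as.integer(log$pokes$counted)), rep("", nr), "")
  # stable sort: start first, rewards after the poke earning them, end last
  rank <- c(0L, rep(1L, np), rep(2L, nr), 3L)
  o <- order(t_ms, rank)
  gt <- if (is.na(log$genotype)) "" else log$genotype
  rows <- paste(log$mouse_id, gt, log$day, log$phase,
                t_ms[o], event[o], well[o], in_to[o], cnt[o], sep = ",")
  writeLines(c(EVENT_LOG_HEADER, rows), con = path)
  invisible(path)
}

#' Read an event log from CSV
#'
#' Parses and validates a file written by [write_event_log()]. Validation
#' errors (bad header, malformed rows, non-monotone times, a reward with no
#' preceding counted active poke, a poke flagged both counted and in
#' timeout) abort with the offending line number.
#'
#' @param path File path or connection.
#' @param config Optional [session_config()] to attach to the returned log
#'   (the CSV does not carry the configuration); defaults to `NULL`.
#' @return An `event_log`.
#' @export
read_event_log <- function(path, config = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1] != EVENT_LOG_HEADER)
    stop("not an event-log file: bad or missing header", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (length(body) < 2L)
    stop("event-log file must contain at least session_start and session_end",
         call. = FALSE)
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  # trailing empty fields are dropped by strsplit; pad to 9
  bad <- which(nfield < 6L | nfield > 9L)
  if (length(bad))
    stop(sprintf("malformed row at line %d: expected 9 fields", bad[1] + 1L),
         call. = FALSE)
  field <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "",
                              character(1))
  mouse_id <- field(1); genotype <- field(2); day <- field(3); phase <- field(4)
  t_ms <- suppressWarnings(as.numeric(field(5)))
  event <- field(6); well <- field(7); in_to <- field(8); cnt <- field(9)
  if (any(is.na(t_ms)))
    stop(sprintf("malformed t_ms at line %d", which(is.na(t_ms))[1] + 1L),
         call. = FALSE)
  if (is.unsorted(t_ms))
    stop("event times are not monotone non-decreasing", call. = FALSE)
  if (event[1] != "session_start" || event[length(event)] != "session_end")
    stop("event log must start with session_start and end with session_end",
         call. = FALSE)
  if (sum(event == "session_start") != 1L || sum(event == "session_end") != 1L)
    stop("event log must contain exactly one session_start and one session_end",
         call. = FALSE)

  is_poke <- event == "poke"
  is_reward <- event == "reward"
  unknown <- !(is_poke | is_reward | event %in% c("session_start", "session_end"))
  if (any(unknown))
    stop(sprintf("unknown event type '%s' at line %d",
                 event[unknown][1], which(unknown)[1] + 1L), call. = FALSE)
  if (any(is_poke & !(well %in% c("active", "inactive"))))
    stop("poke rows must have well 'active' or 'inactive'", call. = FALSE)
  if (any(is_poke & !(in_to %in% c("0", "1") & cnt %in% c("0", "1"))))
    stop("poke rows must have 0/1 in_timeout and counted flags", call. = FALSE)
  p_in_to <- in_to[is_poke] == "1"
  p_cnt <- cnt[is_poke] == "1"
  if (any(p_in_to & p_cnt))
    stop("a poke cannot be both counted and in timeout", call. = FALSE)

  # every reward must be preceded (or accompanied) by a counted active poke
  ca_cum <- cumsum(is_poke & well == "active" & cnt == "1")
  if (any(is_reward & ca_cum == 0))
    stop(sprintf("reward at line %d precedes any counted active poke",
                 which(is_reward & ca_cum == 0)[1] + 1L), call. = FALSE)

  end_reason <- well[event == "session_end"]
  if (!end_reason %in% c("TIME_LIMIT", "REWARD_CAP"))
    stop("session_end row must carry end reason TIME_LIMIT or REWARD_CAP",
         call. = FALSE)

  poke_df <- data.frame(t_s = t_ms[is_poke] / 1000,
                        well = well[is_poke],
                        in_timeout = p_in_to,
                        counted = p_cnt,
                        stringsAsFactors = FALSE)
  reward_df <- data.frame(t_s = t_ms[is_reward] / 1000,
                          index = seq_len(sum(is_reward)))
  gt <- genotype[1]
  new_event_log(mouse_id = mouse_id[1],
                genotype = if (nzchar(gt)) gt else NA_character_,
                day = as.integer(day[1]), phase = phase[1], config = config,
                pokes = poke_df, rewards = reward_df,
                end_t_s = t_ms[event == "session_end"] / 1000,
                end_reason = end_reason)
}

#' Summarise a session event log
#'
#' Reduces an [event log][run_session] to the per-session metrics used in
#' operant phenotyping: active, inactive and total poke counts (timeout
#' pokes are physical pokes and are included, as well as tallied
#' separately), reinforcement count, the active:inactive discrimination
#' ratio, and — for progressive-ratio sessions — the breakpoint (the final
#' reinforcement count).
#'
#' The active:inactive ratio is `Inf` when a mouse poked only the active
#' well (maximal discrimination) and `NA` when it made no pokes at all.
#'
#' @param log An `event_log`.
#' @return A one-row data frame with columns `mouse_id`, `genotype`, `day`,
#'   `phase`, `active_pokes`, `inactive_pokes`, `total_pokes`,
#'   `timeout_pokes`, `rewards`, `active_inactive_ratio`, `breakpoint`
#'   (`NA` unless phase is PR), `session_duration_s`, `end_reason`.
#' @export
summarize_session <- function(log) {
  stopifnot(inherits(log, "event_log"))
  active <- sum(log$pokes$well == "active")
  inactive <- sum(log$pokes$well == "inactive")
  rewards <- nrow(log$rewards)
  ratio <- if (active == 0 && inactive == 0) NA_real_
           else if (inactive == 0) Inf
           else active / inactive
  data.frame(mouse_id = log$mouse_id,
             genotype = log$genotype,
             day = log$day,
             phase = log$phase,
             active_pokes = active,
             inactive_pokes = inactive,
             total_pokes = active + inactive,
             timeout_pokes = sum(log$pokes$in_timeout),
             rewards = rewards,
             active_inactive_ratio = ratio,
             breakpoint = if (log$phase == "PR") rewards else NA_integer_,
             session_duration_s = log$end_t_s,
             end_reason = log$end_reason,
             stringsAsFactors = FALSE)
}

#' Summarise a list of event logs
#'
#' @param logs A list of `event_log` objects.
#' @return A tidy data frame, one row per session (see [summarize_session()]).
#' @export
summarize_sessions <- function(logs) {
  do.call(rbind, lapply(logs, summarize_session))
}
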