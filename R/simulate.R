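# Stochastic virtual-mouse simulator: poke streams across the FR1 -> FR5 ->
# PR protocol, with genotype-dependent parameters.

#' Protocol configuration for the FR1 -> FR5 -> PR pipeline
#'
#' Bundles the per-phase session configurations with the progression
#' criteria. The FR1 phase caps sessions at 50 reinforcements; FR5 and PR
#' sessions run the full 60 minutes.
#'
#' @param fr1,fr5,pr [session_config()]s for the three phases.
#' @param criteria A [criteria_config()].
#' @param pr_max_days Safety cap on PR days before a mouse is reported as
#'   never stabilizing (default 30).
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(fr1 = session_config(fr_schedule(1), max_rewards = 50),
                            fr5 = session_config(fr_schedule(5)),
                            pr = session_config(pr_schedule()),
                            criteria = criteria_config(),
                            pr_max_days = 30) {
  stopifnot(inherits(fr1, "session_config"), inherits(fr5, "session_config"),
            inherits(pr, "session_config"), inherits(criteria, "criteria_config"))
  structure(list(fr1 = fr1, fr5 = fr5, pr = pr, criteria = criteria,
                 pr_max_days = as.integer(pr_max_days)),
            class = "protocol_config")
}

#' @rdname protocol_config
#' @export
default_protocol <- function() protocol_config()

# homogeneous Poisson event times on [t0, t1)
poisson_times <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0))
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate one session of a virtual mouse
#'
#' Generates a poke stream from the agent model (see [agent_params()]) and
#' delegates it to [run_session()]. While engaged the agent pokes as a
#' Poisson process at `poke_rate_hz`, each poke hitting the active well with
#' the day's learning-curve probability. In progressive-ratio sessions,
#' after each earned reward the agent survives an engagement check with
#' probability `exp(-r/persistence)` (`r` the upcoming requirement); on the
#' first failure it permanently disengages for the rest of the session,
#' poking at `disengaged_rate_hz` with active-well probability
#' `disengaged_p_active`. Fixed-ratio sessions skip the engagement check.
#'
#' Uses the current RNG state; results are reproducible under `set.seed()`.
#'
#' @param agent An [agent_params()].
#' @param config A [session_config()].
#' @param day Positive integer; the global session-day counter driving the
#'   learning curve (accumulates across phases).
#' @param phase `"FR1"`, `"FR5"` or `"PR"`; if `NULL`, inferred from the
#'   schedule (PR for progressive ratio, FR1/FR5 by fixed ratio).
#' @param mouse_id,genotype Metadata for the log.
#' @return An `event_log` (see [run_session()]).
#' @export
simulate_session <- function(agent, config, day, phase = NULL,
                             mouse_id = "sim", genotype = NA_character_) {
  stopifnot(inherits(agent, "agent_params"), inherits(config, "session_config"))
  sched <- config$schedule
  if (is.null(phase)) {
    phase <- if (sched$kind == "PR") "PR"
             else if (sched$fixed_ratio == 1L) "FR1" else "FR5"
  }
  dur <- config$max_duration_s
  p_act <- p_active_on_day(agent, day)

  times <- poisson_times(agent$poke_rate_hz, 0, dur)
  wells <- ifelse(stats::runif(length(times)) < p_act, "active", "inactive")
  stream <- data.frame(t_s = times, well = wells, stringsAsFactors = FALSE)

  if (phase != "PR") {
    return(run_session(config, stream, mouse_id = mouse_id,
                       genotype = genotype, day = day, phase = phase))
  }

  # engagement coins, drawn up-front for determinism (with infinite
  # persistence every check passes and the draws are inert)
  u <- stats::runif(64L)
  first_pass <- run_session(config, stream, mouse_id = mouse_id,
                            genotype = genotype, day = day, phase = phase)
  k <- nrow(first_pass$rewards)
  if (k == 0L) return(first_pass)
  if (k > length(u)) u <- c(u, stats::runif(k - length(u)))
  surv <- exp(-requirement_for(sched, seq_len(k)) / agent$persistence)
  fail <- which(u[seq_len(k)] > surv)
  if (length(fail) == 0L) return(first_pass)

  k_dis <- fail[1L]
  # poke index that earned reward k_dis: the C(k_dis)-th counted active poke
  ca <- which(first_pass$pokes$counted & first_pass$pokes$well == "active")
  i_star <- ca[cumulative_pokes(sched, k_dis)]
  t_dis <- stream$t_s[i_star]
  dis_times <- poisson_times(agent$disengaged_rate_hz, t_dis, dur)
  dis_wells <- ifelse(stats::runif(length(dis_times)) < agent$disengaged_p_active,
                      "active", "inactive")
  stream2 <- rbind(stream[seq_len(i_star), , drop = FALSE],
                   data.frame(t_s = dis_times, well = dis_wells,
                              stringsAsFactors = FALSE))
  run_session(config, stream2, mouse_id = mouse_id, genotype = genotype,
              day = day, phase = phase)
}

#' Simulate a full behavioral protocol for one virtual mouse
#'
#' Runs daily FR1 sessions until the acquisition criteria are met (or the
#' mouse is excluded at the day cap), then the fixed FR5 block, then daily
#' PR sessions until breakpoint stabilization (or the PR safety cap). The
#' learning-curve day counter accumulates across phases.
#'
#' @param agent An [agent_params()].
#' @param protocol A [protocol_config()].
#' @param mouse_id,genotype Metadata for the logs.
#' @param phases Character subset of `c("FR1","FR5","PR")` to run, in
#'   protocol order (later phases are skipped if an earlier one excludes
#'   the mouse).
#' @param keep_logs Keep the full event logs (default `TRUE`); with
#'   `FALSE` only summaries and progress are returned.
#' @return A list with `logs` (list of `event_log`, or `NULL`), `summaries`
#'   (data frame, one row per session) and `progress` (one-row data frame:
#'   `mouse_id`, `genotype`, `excluded`, `fr1_days_to_criteria`,
#'   `pr_stabilization_day`, `breakpoint`).
#' @export
simulate_protocol <- function(agent, protocol = default_protocol(),
                              mouse_id = "sim", genotype = NA_character_,
                              phases = c("FR1", "FR5", "PR"),
                              keep_logs = TRUE) {
  stopifnot(inherits(protocol, "protocol_config"))
  phases <- match.arg(phases, several.ok = TRUE)
  crit <- protocol$criteria
  logs <- list()
  summaries <- list()
  day <- 0L
  excluded <- FALSE
  fr1_days <- NA_integer_
  pr_day <- NA_integer_
  breakpoint <- NA_real_

  add <- function(log) {
    s <- summarize_session(log)
    summaries[[length(summaries) + 1L]] <<- s
    if (keep_logs) logs[[length(logs) + 1L]] <<- log
    s
  }

  if ("FR1" %in% phases) {
    fr1_summ <- NULL
    for (d in seq_len(crit$fr1_max_days)) {
      day <- day + 1L
      log <- simulate_session(agent, protocol$fr1, day, phase = "FR1",
                              mouse_id = mouse_id, genotype = genotype)
      fr1_summ <- rbind(fr1_summ, add(log))
      fr1_days <- fr1_acquisition_day(fr1_summ, crit)
      if (!is.na(fr1_days)) break
    }
    excluded <- is.na(fr1_days)
  }

  if (!excluded && "FR5" %in% phases) {
    for (d in seq_len(crit$fr5_days)) {
      day <- day + 1L
      add(simulate_session(agent, protocol$fr5, day, phase = "FR5",
                           mouse_id = mouse_id, genotype = genotype))
    }
  }

  if (!excluded && "PR" %in% phases) {
    rewards_by_day <- integer(0)
    for (d in seq_len(protocol$pr_max_days)) {
      day <- day + 1L
      s <- add(simulate_session(agent, protocol$pr, day, phase = "PR",
                                mouse_id = mouse_id, genotype = genotype))
      rewards_by_day <- c(rewards_by_day, s$rewards)
      st <- pr_stabilization(rewards_by_day, crit)
      if (st$stabilized) {
        pr_day <- st$day
        breakpoint <- st$breakpoint
        break
      }
    }
  }

  list(logs = if (keep_logs) logs else NULL,
       summaries = do.call(rbind, summaries),
       progress = data.frame(mouse_id = mouse_id, genotype = genotype,
                             excluded = excluded,
                             fr1_days_to_criteria = fr1_days,
                             pr_stabilization_day = pr_day,
                             breakpoint = breakpoint,
                             stringsAsFactors = FALSE))
}

#' Specification of a simulated cohort
#'
#' @param n_per_genotype Integer vector of mice per genotype, recycled over
#'   `profiles` (default 12 each).
#' @param profiles List of [genotype_profile()]s (default
#'   [default_profiles()]); the first profile is the reference genotype in
#'   reports.
#' @param protocol A [protocol_config()].
#' @param seed Integer master seed; per-mouse RNG substreams are derived
#'   from it so that changing the cohort size does not perturb earlier mice.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_genotype = 12, profiles = default_profiles(),
                        protocol = default_protocol(), seed = 1L) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "genotype_profile")),
            inherits(protocol, "protocol_config"))
  n <- rep_len(as.integer(n_per_genotype), length(profiles))
  if (any(n < 1L)) stop("need at least one mouse per genotype", call. = FALSE)
  structure(list(n_per_genotype = n, profiles = profiles,
                 protocol = protocol, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of virtual mice
#'
#' Draws independent agents for each mouse from its genotype profile and
#' runs each through the full protocol. Each mouse consumes its own RNG
#' substream (L'Ecuyer-CMRG streams spawned from the master seed), so
#' results for mouse `i` do not depend on how many mice follow it. The
#' caller's RNG state is restored on exit.
#'
#' @param spec A [cohort_spec()].
#' @param keep_logs Keep full event logs for every session (default
#'   `FALSE`; summaries and per-mouse progress are always kept).
#' @param phases Phases to run, see [simulate_protocol()].
#' @return An object of class `operant_cohort`: a list with `spec`,
#'   `progress` (one row per mouse), `summaries` (one row per session) and
#'   `logs` (or `NULL`).
#' @seealso [cohort_report()] for the group statistics.
#' @export
simulate_cohort <- function(spec, keep_logs = FALSE,
                            phases = c("FR1", "FR5", "PR")) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = .GlobalEnv)
    else RNGkind("default", "default", "default")
  })

  set.seed(spec$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = .GlobalEnv)

  gnames <- names(spec$profiles)
  if (is.null(gnames)) gnames <- paste0("g", seq_along(spec$profiles))
  progress <- list()
  summaries <- list()
  logs <- list()
  for (g in seq_along(spec$profiles)) {
    profile <- spec$profiles[[g]]
    for (j in seq_len(spec$n_per_genotype[g])) {
      assign(".Random.seed", stream, envir = .GlobalEnv)
      agent <- sample_agent(profile)
      res <- simulate_protocol(agent, spec$protocol,
                               mouse_id = sprintf("%s_%02d", gnames[g], j),
                               genotype = profile$label,
                               phases = phases, keep_logs = keep_logs)
      progress[[length(progress) + 1L]] <- res$progress
      summaries[[length(summaries) + 1L]] <- res$summaries
      if (keep_logs) logs <- c(logs, res$logs)
      stream <- parallel::nextRNGStream(stream)
    }
  }
  structure(list(spec = spec,
                 progress = do.call(rbind, progress),
                 summaries = do.call(rbind, summaries),
                 logs = if (keep_logs) logs else NULL),
            class = "operant_cohort")
}

#' @export
print.operant_cohort <- function(x, ...) {
  tab <- table(x$progress$genotype)
  cat("<operant_cohort>\n  mice:",
      paste(sprintf("%s n=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  sessions: %d; excluded mice: %d; stabilized breakpoints: %d\n",
              nrow(x$summaries), sum(x$progress$excluded),
              sum(!is.na(x$progress$breakpoint))))
  invisible(x)
}

#' Fast per-day breakpoint sampler
#'
#' Draws daily progressive-ratio breakpoints directly from the agent model's
#' generative law without constructing poke streams: the day's breakpoint is
#' the smaller of (a) the first reward whose engagement check fails
#' (independent coins with survival `exp(-r/persistence)`) and (b) the
#' largest reward count affordable from a Poisson draw of counted active
#' pokes (engaged poke rate thinned by the active-well probability and the
#' post-response timeout dead time). Intended for large-scale power and
#' type-I-error studies where running the full event-level simulator for
#' thousands of cohorts would be wasteful; it agrees with the event-level
#' simulator up to the dead-time thinning approximation.
#'
#' @param agent An [agent_params()].
#' @param n_days Number of PR days to draw.
#' @param schedule A progressive-ratio [pr_schedule()].
#' @param max_duration_s Session length in seconds.
#' @param timeout_s Post-response timeout (dead time) in seconds.
#' @param day Learning-curve day at which the sessions are run (a
#'   post-acquisition day; default 15).
#' @return Integer vector of `n_days` daily breakpoints.
#' @export
simulate_breakpoints <- function(agent, n_days, schedule = pr_schedule(),
                                 max_duration_s = 3600, timeout_s = 1,
                                 day = 15) {
  stopifnot(inherits(agent, "agent_params"), schedule$kind == "PR")
  p <- p_active_on_day(agent, day)
  lam_a <- agent$poke_rate_hz * p
  lam_counted <- lam_a / (1 + lam_a * timeout_s)
  cum <- cumsum(requirement_for(schedule, 0:63))
  out <- integer(n_days)
  for (d in seq_len(n_days)) {
    a <- stats::rpois(1, lam_counted * max_duration_s)
    k_time <- sum(cum <= a)
    u <- stats::runif(64L)
    surv <- exp(-requirement_for(schedule, 1:64) / agent$persistence)
    fail <- which(u > surv)
    k_coin <- if (length(fail)) fail[1L] else 64L
    out[d] <- min(k_time, k_coin)
  }
  out
}
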