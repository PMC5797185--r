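# Independent brute-force oracles used by the property tests. These are
# deliberately written from scratch (different structure, own formulas) and
# must never call the implementation they check.

# requirement formula evaluated directly
oracle_requirement <- function(scale, rate, rewards_earned, fixed = NULL) {
  if (!is.null(fixed)) return(fixed)
  n <- rewards_earned + 1
  max(1, floor(scale * exp(n * rate) - scale + 0.5))
}

# step-by-step hand simulator: walks the poke stream keeping an explicit
# list of timeout windows opened so far, and a running requirement computed
# from the formula above
oracle_session <- function(config, pokes) {
  t_ms <- floor(as.numeric(pokes$t_s) * 1000 + 0.5)
  well <- as.character(pokes$well)
  to_ms <- floor(config$timeout_s * 1000 + 0.5)
  dur_ms <- floor(config$max_duration_s * 1000 + 0.5)
  sch <- config$schedule
  fixed <- if (sch$kind == "FR") sch$fixed_ratio else NULL

  windows <- matrix(numeric(0), ncol = 2)   # (start, end] pairs
  in_timeout <- logical(0)
  counted <- logical(0)
  reward_ms <- numeric(0)
  pokes_toward <- 0
  end_ms <- dur_ms
  end_reason <- "TIME_LIMIT"

  for (i in seq_along(t_ms)) {
    tp <- t_ms[i]
    if (tp >= dur_ms) break
    # inside any previously opened window? (equal-time pokes arrive "later",
    # so tp == start counts as inside when the window has positive length)
    inside <- FALSE
    if (to_ms > 0 && nrow(windows) > 0) {
      for (w in seq_len(nrow(windows)))
        if (tp >= windows[w, 1] && tp <= windows[w, 2]) inside <- TRUE
    }
    in_timeout <- c(in_timeout, inside)
    counted <- c(counted, !inside)
    if (inside) next
    if (well[i] == "active") {
      windows <- rbind(windows, c(tp, tp + to_ms))
      pokes_toward <- pokes_toward + 1
      need <- oracle_requirement(sch$pr_scale, sch$pr_rate,
                                 length(reward_ms), fixed = fixed)
      if (pokes_toward == need) {
        reward_ms <- c(reward_ms, tp)
        pokes_toward <- 0
        if (length(reward_ms) >= config$max_rewards) {
          end_ms <- tp
          end_reason <- "REWARD_CAP"
          break
        }
      }
    }
  }
  list(reward_ms = reward_ms,
       in_timeout = in_timeout, counted = counted,
       end_ms = end_ms, end_reason = end_reason)
}

# random short poke stream, occasionally with equal-time pokes
random_stream <- function(n_max = 20, mean_gap = 1) {
  n <- sample(0:n_max, 1)
  if (n == 0) return(data.frame(t_s = numeric(0), well = character(0)))
  gaps <- round(rexp(n, 1 / mean_gap), 3)
  if (n > 1 && runif(1) < 0.3) gaps[sample(2:n, 1)] <- 0  # tie
  data.frame(t_s = cumsum(gaps),
             well = sample(c("active", "inactive"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
             stringsAsFactors = FALSE)
}

random_config <- function() {
  sched <- if (runif(1) < 0.5) fr_schedule(sample(1:5, 1)) else pr_schedule()
  session_config(sched,
                 max_duration_s = sample(c(10, 30, 3600), 1),
                 max_rewards = sample(c(3, 10, Inf), 1),
                 timeout_s = sample(c(0, 0.5, 1), 1))
}
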