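test_that("FR1 timeout: a poke inside the 1-s window is flagged and uncounted", {
  cfg <- session_config(fr_schedule(1), timeout_s = 1)
  log <- run_session(cfg, data.frame(t_s = c(0, 0.5, 2), well = "active"),
                     phase = "FR1")
  expect_equal(log$rewards$t_s, c(0, 2))
  expect_equal(log$rewards$index, c(1L, 2L))
  expect_equal(log$pokes$in_timeout, c(FALSE, TRUE, FALSE))
  expect_equal(log$pokes$counted, c(TRUE, FALSE, TRUE))
})

test_that("FR5: five spaced active pokes earn a single reward at the fifth", {
  cfg <- session_config(fr_schedule(5), timeout_s = 1)
  log <- run_session(cfg, data.frame(t_s = c(2, 4, 6, 8, 10), well = "active"),
                     phase = "FR5")
  expect_equal(log$rewards$t_s, 10)
  expect_equal(nrow(log$rewards), 1L)
})

test_that("reward cap ends the session at the capping reward", {
  cfg <- session_config(fr_schedule(1), max_rewards = 50, timeout_s = 0)
  stream <- data.frame(t_s = seq(0, by = 2, length.out = 60), well = "active")
  log <- run_session(cfg, stream, phase = "FR1")
  expect_equal(nrow(log$rewards), 50L)
  expect_equal(log$end_reason, "REWARD_CAP")
  expect_equal(log$end_t_s, log$rewards$t_s[50])
  expect_equal(nrow(log$pokes), 50L)  # later pokes discarded
})

test_that("empty stream gives an empty time-limited log", {
  cfg <- session_config(fr_schedule(1))
  log <- run_session(cfg, NULL)
  expect_equal(nrow(log$pokes), 0L)
  expect_equal(nrow(log$rewards), 0L)
  expect_equal(log$end_reason, "TIME_LIMIT")
  expect_equal(log$end_t_s, 3600)
})

test_that("termination rule: time limit or reward cap, whichever first", {
  cfg <- session_config(fr_schedule(1), max_rewards = 50)
  expect_equal(session_terminated(50, 1200, cfg),
               list(terminated = TRUE, reason = "REWARD_CAP"))
  cfg2 <- session_config(fr_schedule(1))
  expect_equal(session_terminated(10, 3600, cfg2),
               list(terminated = TRUE, reason = "TIME_LIMIT"))
  expect_false(session_terminated(0, 0, cfg)$terminated)
})

test_that("inactive pokes never advance the schedule or open timeouts", {
  cfg <- session_config(fr_schedule(1), timeout_s = 1)
  log <- run_session(cfg, data.frame(
    t_s = c(0, 0.5, 1.0),
    well = c("inactive", "active", "inactive")), phase = "FR1")
  # inactive at 0 opens no window, so active at 0.5 is counted and rewarded;
  # inactive at 1.0 falls inside the active poke's window
  expect_equal(log$rewards$t_s, 0.5)
  expect_equal(log$pokes$counted, c(TRUE, TRUE, FALSE))
  expect_equal(log$pokes$in_timeout, c(FALSE, FALSE, TRUE))
})

test_that("invalid streams are rejected", {
  cfg <- session_config(fr_schedule(1))
  expect_error(run_session(cfg, data.frame(t_s = c(2, 1), well = "active")),
               "sorted")
  expect_error(run_session(cfg, data.frame(t_s = -1, well = "active")),
               "non-negative")
  expect_error(run_session(cfg, data.frame(t_s = 1, well = "left")), "well")
})

test_that("session state machine matches the brute-force hand simulator", {
  set.seed(42)
  for (rep in 1:300) {
    cfg <- random_config()
    stream <- random_stream(20)
    log <- run_session(cfg, stream)
    ref <- oracle_session(cfg, stream)
    expect_equal(round(log$rewards$t_s * 1000), ref$reward_ms)
    expect_equal(log$pokes$in_timeout, ref$in_timeout[seq_len(nrow(log$pokes))])
    expect_equal(log$pokes$counted, ref$counted[seq_len(nrow(log$pokes))])
    expect_equal(round(log$end_t_s * 1000), ref$end_ms)
    expect_equal(log$end_reason, ref$end_reason)
  }
})

test_that("conservation and replay invariants hold on random streams", {
  set.seed(7)
  for (rep in 1:100) {
    cfg <- random_config()
    log <- run_session(cfg, random_stream(20))
    # counted active pokes = sum of satisfied requirements + leftover progress
    n_rewards <- nrow(log$rewards)
    counted_active <- sum(log$pokes$counted & log$pokes$well == "active")
    spent <- if (n_rewards > 0) cumulative_pokes(cfg$schedule, n_rewards) else 0L
    leftover <- counted_active - spent
    expect_gte(leftover, 0)
    if (n_rewards > 0 || counted_active > 0)
      expect_lt(leftover, requirement_for(cfg$schedule, n_rewards))
    # replaying the logged stream reproduces the log
    replay <- run_session(cfg, log$pokes[, c("t_s", "well")],
                          mouse_id = log$mouse_id, genotype = log$genotype,
                          day = log$day, phase = log$phase)
    expect_equal(replay, log)
  }
})

test_that("rewards are monotone in the number of counted active pokes", {
  cfg <- session_config(pr_schedule(), timeout_s = 0)
  ks <- c(1, 5, 13, 22, 34, 60)
  rewards <- vapply(ks, function(k) {
    stream <- data.frame(t_s = seq_len(k), well = "active")
    nrow(run_session(cfg, stream, phase = "PR")$rewards)
  }, numeric(1))
  expect_true(all(diff(rewards) >= 0))
  expect_equal(rewards[ks == 34], 6)  # 34 pokes buy exactly 6 PR rewards
})
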