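zero_disp_profile <- function(persistence = 170) {
  genotype_profile("fixed", list(
    poke_rate_hz = 0.0759, p_active_floor = 0.5, p_active_ceiling = 0.88,
    learning_midpoint_day = 4.25, learning_slope_days = 1.0,
    persistence = persistence, disengaged_rate_hz = 0.01,
    disengaged_p_active = 0.5))
}

test_that("zero-dispersion profiles sample to their means, reproducibly", {
  prof <- zero_disp_profile()
  a <- sample_agent(prof)
  expect_equal(a$poke_rate_hz, 0.0759)
  expect_equal(a$persistence, 170)
  expect_equal(a$p_active_ceiling, 0.88)

  set.seed(123)
  b1 <- sample_agent(default_profiles()$wt)
  set.seed(123)
  b2 <- sample_agent(default_profiles()$wt)
  expect_identical(b1, b2)
})

test_that("lognormal between-mouse draws have the profile mean", {
  prof <- default_profiles()$wt
  set.seed(21)
  draws <- replicate(10000, {
    # isolate one lognormal parameter by drawing a full agent
    sample_agent(prof)$persistence
  })
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - prof$means$persistence), 3 * se)
})

test_that("the learning curve rises from floor to ceiling", {
  a <- sample_agent(zero_disp_profile())
  p <- p_active_on_day(a, c(1, 4.25, 30))
  expect_equal(p[2], (0.5 + 0.88) / 2)  # midpoint halfway
  expect_lt(p[1], 0.65)
  expect_equal(p[3], 0.88, tolerance = 1e-6)
  expect_true(all(diff(p_active_on_day(a, 1:30)) > 0))
})

test_that("an infinitely persistent agent never disengages in PR", {
  prof <- zero_disp_profile(persistence = Inf)
  a <- sample_agent(prof)
  set.seed(99)
  log <- simulate_session(a, session_config(pr_schedule()), day = 20)
  # with ~273 pokes/h at ceiling accuracy the time/poke budget allows ~12
  # rewards; an engaged agent should get close to that bound
  expect_gte(nrow(log$rewards), 10)
  s <- summarize_session(log)
  expect_equal(s$phase, "PR")
})

test_that("FR5 session throughput matches the Poisson poke-rate expectation", {
  a <- sample_agent(zero_disp_profile())
  set.seed(4)
  totals <- replicate(30, {
    log <- simulate_session(a, session_config(fr_schedule(5)), day = 15)
    summarize_session(log)$total_pokes
  })
  # expectation ~ 0.0759 * 3600 = 273.2; Poisson SE over 30 sessions ~ 3
  expect_lt(abs(mean(totals) - 273.2), 4 * sqrt(273.2 / 30))
})

test_that("simulated sessions are deterministic given the seed", {
  a <- sample_agent(zero_disp_profile(persistence = 60))
  set.seed(31); l1 <- simulate_session(a, session_config(pr_schedule()), day = 12)
  set.seed(31); l2 <- simulate_session(a, session_config(pr_schedule()), day = 12)
  expect_identical(l1, l2)
})

test_that("empirical disengagement survival matches exp(-r/persistence)", {
  m <- 30
  a <- sample_agent(zero_disp_profile(persistence = m))
  # fast PR sessions: high poke rate so the time budget is never binding;
  # silence post-disengagement poking so late stray pokes cannot earn
  # rewards and contaminate the survival estimate
  a$poke_rate_hz <- 0.5
  a$disengaged_rate_hz <- 0
  cfg <- session_config(pr_schedule(), max_duration_s = 600, timeout_s = 0.2)
  set.seed(17)
  n_sess <- 1000
  bp <- replicate(n_sess, nrow(simulate_session(a, cfg, day = 20)$rewards))
  # survival through the check after reward k has probability
  # exp(-r_{k+1}/m); estimate it from sessions that reached reward k
  for (k in c(1, 3, 5)) {
    at_risk <- sum(bp >= k)
    survived <- sum(bp >= k + 1)
    p_hat <- survived / at_risk
    p_true <- exp(-requirement_for(pr_schedule(), k) / m)
    se <- sqrt(p_true * (1 - p_true) / at_risk)
    expect_lt(abs(p_hat - p_true), 4 * se)
  }
})

test_that("expected breakpoint is non-decreasing in persistence", {
  prof <- zero_disp_profile()
  cfg <- session_config(pr_schedule())
  means <- vapply(c(30, 80, 200), function(m) {
    a <- sample_agent(zero_disp_profile(persistence = m))
    set.seed(55)  # paired seeds across persistence values
    mean(replicate(40, nrow(simulate_session(a, cfg, day = 15)$rewards)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("a low-ceiling agent is excluded at the FR1 day cap", {
  prof <- genotype_profile("poor", list(
    poke_rate_hz = 0.0759, p_active_floor = 0.5, p_active_ceiling = 0.70,
    learning_midpoint_day = 4.25, learning_slope_days = 1.0,
    persistence = 170, disengaged_rate_hz = 0.01, disengaged_p_active = 0.5))
  a <- sample_agent(prof)
  set.seed(2)
  res <- simulate_protocol(a, default_protocol(), keep_logs = FALSE)
  expect_true(res$progress$excluded)
  expect_true(is.na(res$progress$fr1_days_to_criteria))
  expect_equal(nrow(res$summaries), 17)  # ran all FR1 days, nothing after
})

test_that("a high-performing agent acquires FR1 in at least 3 days and completes the protocol", {
  a <- sample_agent(zero_disp_profile())
  set.seed(8)
  res <- simulate_protocol(a, default_protocol())
  p <- res$progress
  expect_false(p$excluded)
  expect_gte(p$fr1_days_to_criteria, 3)
  phases <- res$summaries$phase
  expect_equal(sum(phases == "FR5"), 3)
  if (!is.na(p$breakpoint)) {
    pr_rewards <- res$summaries$rewards[phases == "PR"]
    st <- pr_stabilization(pr_rewards[seq_len(p$pr_stabilization_day)])
    expect_equal(st$breakpoint, p$breakpoint)
  }
  # day counter accumulates across phases
  expect_equal(res$summaries$day, seq_len(nrow(res$summaries)))
})

test_that("protocol runs are reproducible and cohort substreams are stable", {
  a <- sample_agent(zero_disp_profile(persistence = 60))
  set.seed(14); r1 <- simulate_protocol(a, keep_logs = FALSE)$progress
  set.seed(14); r2 <- simulate_protocol(a, keep_logs = FALSE)$progress
  expect_identical(r1, r2)

  # adding mice must not perturb earlier mice (per-mouse substreams)
  sp_small <- cohort_spec(n_per_genotype = c(2, 1), seed = 77)
  sp_large <- cohort_spec(n_per_genotype = c(2, 2), seed = 77)
  c_small <- simulate_cohort(sp_small)
  c_large <- simulate_cohort(sp_large)
  expect_identical(c_small$progress,
                   c_large$progress[seq_len(nrow(c_small$progress)), ])
})

test_that("null cohorts with identical profiles show no systematic effect", {
  profs <- default_profiles()
  profs$mut <- genotype_profile("mutant", profs$wt$means, profs$wt$dispersions)
  reds <- vapply(1:4, function(r) {
    co <- simulate_cohort(cohort_spec(8, profs, seed = 400 + r))
    rep <- cohort_report(co)
    rep$pct_reduction[rep$metric == "breakpoint"]
  }, numeric(1))
  expect_lt(abs(mean(reds)), 20)  # centred on zero, sign varies by chance
})

test_that("single-genotype cohorts report means without comparisons", {
  co <- simulate_cohort(cohort_spec(3, default_profiles()["wt"], seed = 5))
  rep <- cohort_report(co)
  expect_true(all(is.na(rep$t)))
  expect_false(all(is.na(rep$mean_ref)))
  expect_true(all(is.na(rep$mean_cmp)))
})

test_that("fast breakpoint sampler agrees with the event-level simulator", {
  a <- sample_agent(zero_disp_profile(persistence = 60))
  cfg <- session_config(pr_schedule())
  set.seed(66)
  slow <- replicate(150, nrow(simulate_session(a, cfg, day = 15)$rewards))
  fast <- simulate_breakpoints(a, 1500, day = 15)
  se <- sqrt(var(slow) / 150 + var(fast) / 1500)
  expect_lt(abs(mean(slow) - mean(fast)), 4 * se)
})
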