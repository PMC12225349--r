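test_that("lognormal fit hits the target median and quartile ratio", {
  # degenerate IQR collapses to a point mass
  fit0 <- lognormal_from_median_iqr(100, 100, 100)
  expect_equal(fit0$sdlog, 0)
  expect_equal(stats::qlnorm(0.5, fit0$meanlog, fit0$sdlog), 100)

  fit <- lognormal_from_median_iqr(639, 593, 717)
  # closed-form quantile identities
  expect_equal(stats::qlnorm(0.5, fit$meanlog, fit$sdlog), 639)
  expect_equal(stats::qlnorm(0.75, fit$meanlog, fit$sdlog) /
                 stats::qlnorm(0.25, fit$meanlog, fit$sdlog), 717 / 593)
  # empirical median of 1e5 draws within 1% of the target
  set.seed(1234)
  draws <- stats::rlnorm(1e5, fit$meanlog, fit$sdlog)
  expect_lt(abs(stats::median(draws) - 639) / 639, 0.01)

  expect_error(lognormal_from_median_iqr(-1, 1, 2), "positive")
  expect_error(lognormal_from_median_iqr(5, 6, 7), "q1 <= median")
})

test_that("the 30:2 timeline follows deterministic arithmetic at zero variance", {
  # point-mass profile: breath 1.0 s + 1.0 s gap; compression 0.5 s at
  # 120/min; 1.0 s hand-off pause
  pr <- test_profile("T0", volume_median = 550, volume_iqr = c(550, 550),
                     time_median = 1, time_iqr = c(1, 1),
                     rate_median = 120, rate_iqr = c(120, 120),
                     depth_median = 55, depth_iqr = c(55, 55),
                     inter_breath_gap = 1, compression_pause = 1)
  des <- study_design()
  ev <- simulate_test(pr, des, seed = 1)
  # hand timeline: initial phase ends at 10 s; each cycle takes
  # 30*0.5 + 1 + 2*(1+1) = 20 s; breaths of cycle c fit while the second
  # breath starts at 10 + 20(c-1) + 16 + 2 <= 119; cycles 1..5 fit their
  # breaths (ending 10,30,..); cycle 6 compressions start at 110 and
  # only 20 fit before 120 s
  nv <- sum(ev$event_type == "ventilation")
  nc <- sum(ev$event_type == "compression")
  expect_equal(nv, 5 + 2 * 5)
  expect_equal(nc, 30 * 5 + 20)
  # all events fit inside the session
  ends <- ev$t_start_ms + ifelse(ev$event_type == "ventilation",
                                 ev$insufflation_ms,
                                 round(60000 / ev$rate_cpm))
  expect_true(all(ends <= 120000))
  # no overlap: events are emitted in order and each starts no earlier
  # than the previous one ends (1 ms slack for rounding)
  expect_true(all(diff(ev$t_start_ms) >= 0))
  expect_true(all(ev$t_start_ms[-1] >= ends[-nrow(ev)] - 1))
})

test_that("short sessions truncate to the initial breaths only", {
  pr <- test_profile("T0", volume_median = 550, volume_iqr = c(550, 550),
                     time_median = 1, time_iqr = c(1, 1),
                     rate_median = 120, rate_iqr = c(120, 120),
                     depth_median = 55, depth_iqr = c(55, 55),
                     inter_breath_gap = 1)
  des <- study_design(duration_s = 10)
  ev <- simulate_test(pr, des, seed = 2)
  expect_equal(sum(ev$event_type == "ventilation"), 5)
  expect_equal(sum(ev$event_type == "compression"), 0)
})

test_that("simulation is deterministic under a fixed seed", {
  pr <- default_profiles()$T1
  a <- simulate_test(pr, seed = 9); b <- simulate_test(pr, seed = 9)
  expect_identical(a, b)
  s1 <- simulate_study(seed = 17); s2 <- simulate_study(seed = 17)
  expect_identical(s1, s2)
  s3 <- simulate_study(seed = 18)
  expect_false(identical(s1, s3))
})

test_that("a default study has 5 pairs x 3 tests and valid timelines", {
  ev <- simulate_study(seed = 4)
  sess <- split_sessions(ev)
  expect_length(sess, 15)
  expect_error(simulate_study(profiles = default_profiles()[c("T0", "T1")]),
               "T2")
  # occupied time never exceeds the session
  for (s in sess) {
    vent <- s$event_type == "ventilation"
    occ <- sum(s$insufflation_ms[vent]) + sum(round(60000 / s$rate_cpm[!vent]))
    expect_lte(occ, 120000)
  }
  tr <- attr(ev, "truth")
  expect_equal(tr$seed, 4)
  expect_equal(tr$profiles$T0$volume_median, 639)
})

test_that("per-test distributions recover the profile targets", {
  ev <- simulate_study(seed = 31)
  cls <- classify_events(ev)
  eff <- cls$events
  pr <- default_profiles()
  for (tid in c("T0", "T1", "T2")) {
    sub <- eff[eff$test_id == tid, ]
    # medians of ~65-75 events per test sit near the profile medians
    expect_lt(abs(stats::median(sub$volume_ml) - pr[[tid]]$volume_median) /
                pr[[tid]]$volume_median, 0.15)
    expect_lt(abs(stats::median(sub$insufflation_ms / 1000) -
                    pr[[tid]]$time_median) / pr[[tid]]$time_median, 0.2)
  }
  # T0 mean insufflation time clusters near 0.48 s across sessions
  m <- summarize_sessions(ev)
  t0 <- m$mean_insufflation_time[m$test_id == "T0"]
  expect_true(all(abs(t0 - 0.48) < 0.15))
})

test_that("training profiles produce the dose-response green ordering", {
  ev <- simulate_study(seed = 6)
  counts <- classify_events(ev)$counts
  p_green <- counts[, "green"] / rowSums(counts)
  expect_lt(p_green["T0"], p_green["T2"])
  expect_lte(p_green["T0"], p_green["T1"])
})
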