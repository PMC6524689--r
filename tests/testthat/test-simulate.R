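test_that("staircase moves one step toward harder/easier and respects bounds", {
  d <- task_design()
  expect_equal(staircase_update(100, responded = TRUE, d), 50)
  expect_equal(staircase_update(100, responded = FALSE, d), 150)
  expect_equal(staircase_update(0, responded = TRUE, d), 0)    # floor clip
  expect_equal(staircase_update(900, responded = FALSE, d), 900)  # ceiling clip
  expect_error(staircase_update(-10, TRUE, d), "non-negative")
})

test_that("degenerate stop latencies decide the race deterministically", {
  never_stops <- race_params(ssrt_mean_ms = 1e9, ssrt_sd_ms = 1,
                             omission_rate = 0)
  always_stops <- race_params(ssrt_mean_ms = 1e-3, ssrt_sd_ms = 1e-4,
                              omission_rate = 0)
  set.seed(1)
  for (i in 1:20) {
    tr <- simulate_trial("stop", ssd_ms = 200, params = never_stops)
    expect_false(tr$response == "none")
    tr <- simulate_trial("stop", ssd_ms = 0, params = always_stops)
    expect_identical(tr$response, "none")
  }
  expect_error(simulate_trial("stop", ssd_ms = NA), "ssd_ms")
})

test_that("go responses hit the configured choice-error rate", {
  p <- race_params(choice_error_rate = 0.1, omission_rate = 0)
  s <- simulate_session(task_design(n_trials = 20000, n_choice_trials = 0),
                        p, seed = 11)
  go <- s$trials[s$trials$trial_type == "go" & s$trials$response != "none", ]
  frac <- mean(go$response != go$stimulus)
  se <- sqrt(0.1 * 0.9 / nrow(go))
  expect_lt(abs(frac - 0.1), 3 * se)
})

test_that("session layout matches the design and is seed-deterministic", {
  s <- simulate_session(seed = 5)
  ss <- s$trials[s$trials$block == "stopsignal", ]
  expect_equal(sum(ss$trial_type == "stop"), 72)
  expect_equal(sum(ss$trial_type == "go"), 216)
  expect_equal(sum(s$trials$block == "choice"), 48)
  # rt present iff responded; ssd present iff stop trial
  expect_true(all(xor(is.na(s$trials$rt_ms), s$trials$response != "none")))
  expect_true(all(is.na(s$trials$ssd_ms) == (s$trials$trial_type == "go")))
  # SSDs live on the staircase lattice within bounds
  ssd <- ss$ssd_ms[!is.na(ss$ssd_ms)]
  expect_true(all(ssd %% 50 == 0 & ssd >= 0 & ssd <= 900))
  expect_identical(s$trials, simulate_session(seed = 5)$trials)
  expect_false(identical(s$trials, simulate_session(seed = 6)$trials))
  expect_error(simulate_session(task_design(n_trials = 10, stop_fraction = 0.26)),
               "integer")
})

test_that("staircase tracking holds p(respond|signal) near one half", {
  s <- simulate_session(task_design(n_trials = 40000, n_choice_trials = 0),
                        race_params(), seed = 3)
  st <- s$trials[s$trials$trial_type == "stop", ]
  expect_gte(nrow(st), 1e4)
  p <- mean(st$response != "none")
  expect_gte(p, 0.45)
  expect_lte(p, 0.55)
})

test_that("slower stop runners never inhibit more often (same seed stream)", {
  means <- c(200, 250, 300, 400, 600)
  for (seed in 1:10) {
    fails <- vapply(means, function(m) {
      s <- simulate_session(params = race_params(ssrt_mean_ms = m), seed = seed)
      st <- s$trials[s$trials$trial_type == "stop", ]
      sum(st$response != "none")
    }, numeric(1))
    expect_true(all(diff(fails) >= 0))
  }
})

test_that("cohorts have one session per group x participant x effector", {
  spec <- default_cohort_spec()
  coh <- simulate_cohort(spec$groups, n_per_group = 3, design = small_design(),
                         seed = 7, between_sd = spec$between_sd)
  expect_length(coh, 12)  # 2 groups x 3 participants x 2 effectors
  meta <- data.frame(group = vapply(coh, `[[`, "", "group"),
                     eff = vapply(coh, `[[`, "", "effector"),
                     pid = vapply(coh, `[[`, "", "participant_id"))
  expect_equal(unname(table(meta$group, meta$eff)), matrix(3L, 2, 2))
  expect_equal(length(unique(meta$pid)), 6)
  expect_error(simulate_cohort(spec$groups, n_per_group = 1, seed = 1),
               "at least 2")
  expect_error(simulate_cohort(list(), n_per_group = 3, seed = 1), "group")
  # reproducible as a whole
  coh2 <- simulate_cohort(spec$groups, n_per_group = 3,
                          design = small_design(), seed = 7,
                          between_sd = spec$between_sd)
  expect_identical(trials_data_frame(coh), trials_data_frame(coh2))
})
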