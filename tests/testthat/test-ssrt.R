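test_that("rank index is the ceiling of basis count times response rate", {
  expect_identical(go_rt_rank_index(288, 0.6), 173L)
  expect_identical(go_rt_rank_index(100, 0.5), 50L)
  expect_identical(go_rt_rank_index(216, 0.55), 119L)
  expect_identical(go_rt_rank_index(288, 0), 1L)  # floored at 1
  expect_error(go_rt_rank_index(288, 1.2), "\\[0, 1\\]")
  expect_error(go_rt_rank_index(288, -0.1), "\\[0, 1\\]")
})

test_that("integration estimate matches hand enumeration", {
  # 10 go RTs 400..490; 4 stop trials, 2 responded (p = 0.5), mean SSD 200
  s <- manual_session(go_rts = seq(400, 490, by = 10),
                      ssds = c(150, 200, 200, 250),
                      stop_responded = c(TRUE, FALSE, TRUE, FALSE))
  est <- estimate_ssrt_integration(s, basis = "go_trials")
  expect_equal(est$p_respond_signal, 0.5)
  expect_equal(est$mean_ssd_ms, 200)
  expect_identical(est$rank_index, 5L)      # ceiling(10 * 0.5)
  expect_equal(est$nth_go_rt_ms, 440)
  expect_equal(est$ssrt_ms, 240)
})

test_that("boundary response rates select extreme ranks", {
  s <- manual_session(go_rts = seq(400, 490, by = 10),
                      ssds = c(150, 200, 200, 250),
                      stop_responded = rep(TRUE, 4))
  est <- estimate_ssrt_integration(s, basis = "total_trials")
  expect_equal(est$nth_go_rt_ms, 490)       # p = 1 -> max go RT
  expect_equal(est$ssrt_ms, 490 - 200)
  expect_false(est$low_p_warning)

  s0 <- manual_session(go_rts = seq(400, 490, by = 10),
                      ssds = c(150, 200, 200, 250),
                      stop_responded = rep(FALSE, 4))
  est0 <- estimate_ssrt_integration(s0)
  expect_identical(est0$rank_index, 1L)
  expect_true(est0$low_p_warning)

  no_stops <- manual_session(go_rts = c(400, 450), ssds = numeric(0),
                             stop_responded = logical(0),
                             design = task_design(n_trials = 2,
                                                  stop_fraction = 0.5))
  no_stops$trials <- no_stops$trials[no_stops$trials$trial_type != "stop", ]
  expect_error(estimate_ssrt_integration(no_stops), "no stop trials")
})

test_that("omissions rank as the slowest observed go RT", {
  s <- manual_session(go_rts = seq(400, 490, by = 10),
                      ssds = c(150, 200, 200, 250),
                      stop_responded = c(TRUE, FALSE, TRUE, FALSE))
  # make the two fastest go trials omissions: remaining sorted RTs start at 420
  go_rows <- which(s$trials$trial_type == "go" & s$trials$block == "stopsignal")
  s$trials$response[go_rows[1:2]] <- "none"
  s$trials$rt_ms[go_rows[1:2]] <- NA_real_
  est <- estimate_ssrt_integration(s, basis = "go_trials")
  # ranked list: 420..490 then 490, 490 -> 5th is 460
  expect_equal(est$nth_go_rt_ms, 460)
})

test_that("estimate is invariant to trial order and equivariant in SSD", {
  s <- simulate_session(design = small_design(), seed = 21)
  est <- estimate_ssrt_integration(s)
  shuffled <- s
  set.seed(1)
  shuffled$trials <- s$trials[sample(nrow(s$trials)), ]
  expect_equal(estimate_ssrt_integration(shuffled)$ssrt_ms, est$ssrt_ms)

  shifted <- s
  stop_rows <- shifted$trials$trial_type == "stop"
  shifted$trials$ssd_ms[stop_rows] <- shifted$trials$ssd_ms[stop_rows] + 30
  expect_equal(estimate_ssrt_integration(shifted)$ssrt_ms, est$ssrt_ms - 30)
})

test_that("integration method recovers the generative stop latency", {
  p <- race_params(ssrt_mean_ms = 250, ssrt_sd_ms = 20)
  est <- vapply(1:150, function(i) {
    estimate_ssrt_integration(simulate_session(params = p, seed = i),
                              basis = "go_trials")$ssrt_ms
  }, numeric(1))
  expect_lt(abs(mean(est) - 250), 10)
})

test_that("two-choice summary uses correct trials only", {
  block <- data.frame(trial_type = "go", stimulus = c("left", "left"),
                      response = c("left", "left"), rt_ms = c(400, 500))
  expect_equal(two_choice_rt(block)$mean_ms, 450)

  block2 <- data.frame(trial_type = "go", stimulus = c("left", "left"),
                       response = c("left", "right"), rt_ms = c(420, 300))
  tc <- two_choice_rt(block2)
  expect_equal(tc$mean_ms, 420)
  expect_equal(tc$accuracy, 0.5)

  s <- simulate_session(design = small_design(),
                        params = race_params(choice_error_rate = 0,
                                             omission_rate = 0), seed = 4)
  choice <- s$trials[s$trials$block == "choice", ]
  expect_equal(two_choice_rt(choice)$accuracy, 1)

  block3 <- data.frame(trial_type = "go", stimulus = "left",
                       response = "right", rt_ms = 300)
  expect_error(two_choice_rt(block3), "no correct responses")
  expect_error(two_choice_rt(data.frame(trial_type = "stop")), "go trials only")
})

test_that("slowing index is the ns-RT / 2-CRT ratio", {
  expect_equal(slowing_index(519.2, 400)$index, 1.298)
  expect_equal(slowing_index(400, 400)$index, 1)
  expect_equal(slowing_index(300, 400)$index, 0.75)  # speeding representable
  expect_error(slowing_index(-1, 400), "positive")
  expect_error(slowing_index(400, 0), "positive")
})

test_that("session summaries carry all per-participant measures", {
  spec <- default_cohort_spec()
  coh <- simulate_cohort(spec$groups, n_per_group = 2, design = small_design(),
                         seed = 31, between_sd = spec$between_sd)
  sm <- summarize_sessions(coh)
  expect_equal(nrow(sm), 8)
  expect_true(all(c("crt_mean", "ns_rt_mean", "slowing_index",
                    "p_respond_signal", "mean_ssd", "ssrt") %in% names(sm)))
  expect_true(all(is.finite(sm$ssrt)))
  expect_equal(sm$slowing_index, sm$ns_rt_mean / sm$crt_mean)
})
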