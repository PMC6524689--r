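make_long <- function(n_per_group = 10, seed = 1, group_shift = 0,
                      effector_shift = 0) {
  set.seed(seed)
  pid <- sprintf("p%02d", seq_len(2 * n_per_group))
  grp <- rep(c("expert", "control"), each = n_per_group)
  subj <- rnorm(2 * n_per_group, 0, 20)
  do.call(rbind, lapply(c("hands", "feet"), function(eff) {
    data.frame(participant_id = pid, group = grp, effector = eff,
               ssrt = 250 + subj + rnorm(2 * n_per_group, 0, 15) +
                 ifelse(grp == "control", group_shift, 0) +
                 ifelse(eff == "feet", effector_shift, 0))
  }))
}

test_that("pure additivity yields a zero interaction", {
  d <- make_long(seed = 3)
  # feet = hands + 10 plus subject noise centred within each group, so the
  # group-wise mean effector difference is exactly 10 for both groups
  set.seed(4)
  e <- rnorm(20, 0, 5)
  e <- e - ave(e, rep(c("expert", "control"), each = 10))
  d$ssrt[d$effector == "feet"] <- d$ssrt[d$effector == "hands"] + 10 + e
  res <- mixed_anova_2x2(d)
  expect_lt(res$F[res$effect == "group:effector"], 1e-12)
  expect_gt(res$F[res$effect == "effector"], 1)
})

test_that("between-group F equals the squared pooled t on subject means", {
  for (seed in 1:5) {
    d <- make_long(seed = seed, group_shift = 15)
    res <- mixed_anova_2x2(d)
    means <- aggregate(ssrt ~ participant_id + group, d, mean)
    g1 <- means$ssrt[means$group == "expert"]
    g2 <- means$ssrt[means$group == "control"]
    tt <- independent_t_test(mean(g1), sd(g1), length(g1),
                             mean(g2), sd(g2), length(g2))
    expect_equal(res$F[res$effect == "group"], tt$t^2, tolerance = 1e-8)
    expect_equal(res$df2[res$effect == "group"], tt$df)
  }
})

test_that("partial eta squared follows F/(F + df2) for single-df effects", {
  expect_lt(abs(partial_eta_from_f(7.89, 1, 58) - 0.120), 5e-4)
  d <- make_long(seed = 9, group_shift = 20, effector_shift = 12)
  res <- mixed_anova_2x2(d)
  expect_equal(res$partial_eta_sq, res$F / (res$F + res$df2), tolerance = 1e-10)
})

test_that("incomplete designs are rejected", {
  d <- make_long(n_per_group = 3)
  expect_error(mixed_anova_2x2(d[-1, ]), "every participant")
  expect_error(mixed_anova_2x2(d[, -4], value = "ssrt"), "columns")
})

test_that("per-effect type-I error is at the nominal level under the null", {
  n_sim <- 2000
  hits <- matrix(FALSE, n_sim, 3)
  for (i in seq_len(n_sim)) {
    res <- mixed_anova_2x2(make_long(n_per_group = 10, seed = 10000 + i))
    hits[i, ] <- res$p < 0.05
  }
  rates <- colMeans(hits)
  expect_true(all(abs(rates - 0.05) < 0.02))
})

test_that("design sample size is minimal for the target power", {
  res <- sample_size_mixed_anova(f = 0.33)
  expect_identical(res$N, 58L)
  expect_gte(res$power_achieved, 0.80)
  pwr_at <- function(N) {
    lambda <- 0.33^2 * N * 2 / (1 + 0.5)
    1 - pf(qf(0.95, 1, N - 2), 1, N - 2, ncp = lambda)
  }
  expect_lt(pwr_at(res$N - 2), 0.80)  # one group-size step below misses power

  expect_identical(sample_size_mixed_anova(f = 1000)$N, 4L)
  expect_error(sample_size_mixed_anova(f = 1e-4, n_max = 200), "not reachable")
})

test_that("analytic power matches a simulated mixed design", {
  res <- sample_size_mixed_anova(f = 0.33)
  n_per <- res$n_per_group
  delta <- 2 * 0.33  # two groups: f = |mu1 - mu2| / (2 sigma_total)
  set.seed(505)
  n_sim <- 2500
  sig <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    pid <- sprintf("p%02d", seq_len(2 * n_per))
    grp <- rep(c("a", "b"), each = n_per)
    subj <- rnorm(2 * n_per, 0, sqrt(0.5))             # rho = 0.5
    shift <- ifelse(grp == "b", delta, 0)
    d <- do.call(rbind, lapply(c("hands", "feet"), function(eff) {
      data.frame(participant_id = pid, group = grp, effector = eff,
                 ssrt = subj + shift + rnorm(2 * n_per, 0, sqrt(0.5)))
    }))
    res_i <- mixed_anova_2x2(d)
    sig[i] <- res_i$p[res_i$effect == "group"] < 0.05
  }
  expect_lt(abs(mean(sig) - res$power_achieved), 0.03)
})
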