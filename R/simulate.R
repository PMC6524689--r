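#' One staircase step for the stop-signal delay
#'
#' The tracking rule: after a successful inhibition (no response) the next SSD
#' gets one step longer (harder); after a failed inhibition (a response) it
#' gets one step shorter (easier). The result is clipped to the design bounds,
#' so long-run p(respond | signal) converges to about 0.5.
#'
#' @param ssd_ms Current stop-signal delay (ms), non-negative.
#' @param responded Logical; `TRUE` if the participant responded (failed to
#'   inhibit) on the stop trial.
#' @param design A [task_design()].
#' @return The next SSD (ms).
#' @examples
#' staircase_update(100, responded = TRUE, task_design())   # 50
#' staircase_update(100, responded = FALSE, task_design())  # 150
#' @export
staircase_update <- function(ssd_ms, responded, design = task_design()) {
  if (!is.numeric(ssd_ms) || length(ssd_ms) != 1L || is.na(ssd_ms) || ssd_ms < 0) {
    stop("ssd_ms must be a single non-negative number")
  }
  stopifnot(is.logical(responded), length(responded) == 1L, !is.na(responded))
  nxt <- ssd_ms + if (responded) -design$ssd_step_ms else design$ssd_step_ms
  min(max(nxt, design$ssd_min_ms), design$ssd_max_ms)
}

# Inverse-CDF samplers so every trial consumes a fixed number of uniform
# draws; keeps seed streams aligned when a single parameter is varied.
.sample_go_rt <- function(mu, sigma, tau, u1, u2) {
  max(1, stats::qnorm(u1, mean = mu, sd = sigma) + stats::qexp(u2, rate = 1 / tau))
}

.sample_stop_latency <- function(mean, sd, u) {
  p0 <- stats::pnorm(0, mean = mean, sd = sd)
  stats::qnorm(p0 + u * (1 - p0), mean = mean, sd = sd)
}

#' Simulate a single trial under the independent race model
#'
#' On a go trial the go process finishes with an ex-Gaussian latency (with
#' probability `omission_rate` it never finishes; with probability
#' `choice_error_rate` the response lands on the wrong side). On a stop trial
#' a response is emitted iff the go finishing time beats `ssd_ms` plus the
#' sampled stop latency — the horse race.
#'
#' Uses the current RNG state; seed at the session level for reproducibility.
#'
#' @param trial_type `"go"` or `"stop"`.
#' @param ssd_ms Stop-signal delay (ms); required iff `trial_type == "stop"`.
#' @param params A [race_params()].
#' @param block `"choice"` or `"stopsignal"`; the slowing factor applies in the
#'   stop-signal block only.
#' @param stimulus `"left"` or `"right"`; sampled uniformly if `NULL`.
#' @return A one-row data frame with columns `block`, `trial_type`, `stimulus`,
#'   `ssd_ms`, `response`, `rt_ms` (`NA` encodes absent).
#' @export
simulate_trial <- function(trial_type = c("go", "stop"), ssd_ms = NA_real_,
                           params = race_params(), block = "stopsignal",
                           stimulus = NULL) {
  trial_type <- match.arg(trial_type)
  if (trial_type == "stop" && (is.na(ssd_ms) || ssd_ms < 0)) {
    stop("stop trials need a non-negative ssd_ms")
  }
  if (trial_type == "go") ssd_ms <- NA_real_
  if (is.null(stimulus)) stimulus <- if (stats::runif(1) < 0.5) "left" else "right"

  mu <- params$go_mu_ms * if (block == "stopsignal") params$slowing_factor else 1
  u <- stats::runif(4)  # omission, choice error, go gaussian, go exponential
  omitted <- u[1] < params$omission_rate
  wrong <- u[2] < params$choice_error_rate
  go_rt <- if (omitted) Inf else
    .sample_go_rt(mu, params$go_sigma_ms, params$go_tau_ms, u[3], u[4])

  if (trial_type == "stop") {
    stop_lat <- .sample_stop_latency(params$ssrt_mean_ms, params$ssrt_sd_ms,
                                     stats::runif(1))
    if (go_rt >= ssd_ms + stop_lat) go_rt <- Inf  # stop runner wins
  }

  if (is.infinite(go_rt)) {
    response <- "none"; rt <- NA_real_
  } else {
    side <- if (wrong) setdiff(c("left", "right"), stimulus) else stimulus
    response <- side; rt <- go_rt
  }
  data.frame(block = block, trial_type = trial_type, stimulus = stimulus,
             ssd_ms = ssd_ms, response = response, rt_ms = rt,
             stringsAsFactors = FALSE)
}

#' Simulate one participant x effector session
#'
#' A two-choice block of pure go trials (no slowing), then a stop-signal block
#' with exactly `stop_fraction * n_trials` stop trials in uniformly random
#' positions, the SSD starting at `ssd_initial_ms` and driven by
#' [staircase_update()]. Identical `(design, params, seed)` give identical
#' sessions.
#'
#' @param design A [task_design()].
#' @param params A [race_params()].
#' @param seed Integer seed for this session.
#' @param participant_id,group,effector Metadata carried into the result.
#' @return An object of class `ssrt_session`: a list with the metadata,
#'   `design`, and a `trials` data frame (one row per trial, `trial_index`
#'   starting at 0 within each block).
#' @examples
#' s <- simulate_session(seed = 1)
#' table(s$trials$block, s$trials$trial_type)
#' @export
simulate_session <- function(design = task_design(), params = race_params(),
                             seed, participant_id = "p01", group = "control",
                             effector = "hands") {
  stopifnot(inherits(design, "task_design"), inherits(params, "race_params"))
  if (missing(seed)) stop("seed is required for simulation")
  set.seed(as.integer(seed))

  n_stop <- as.integer(round(design$n_trials * design$stop_fraction))
  stop_pos <- sort(sample.int(design$n_trials, n_stop))
  n_total <- design$n_choice_trials + design$n_trials

  # All randomness drawn up front (5 uniforms per trial plus the stimulus
  # side), so varying one race parameter leaves the stream aligned.
  stimulus <- ifelse(stats::runif(n_total) < 0.5, "left", "right")
  U <- matrix(stats::runif(n_total * 5L), ncol = 5L)
  block <- rep(c("choice", "stopsignal"),
               c(design$n_choice_trials, design$n_trials))
  mu <- ifelse(block == "stopsignal",
               params$go_mu_ms * params$slowing_factor, params$go_mu_ms)
  go_rt <- pmax(1, stats::qnorm(U[, 3]) * params$go_sigma_ms + mu +
                  stats::qexp(U[, 4]) * params$go_tau_ms)
  go_rt[U[, 1] < params$omission_rate] <- Inf
  wrong <- U[, 2] < params$choice_error_rate
  stop_lat <- .sample_stop_latency(params$ssrt_mean_ms, params$ssrt_sd_ms,
                                   U[, 5])

  trial_type <- rep("go", n_total)
  idx_stop <- design$n_choice_trials + stop_pos
  trial_type[idx_stop] <- "stop"
  ssd_vec <- rep(NA_real_, n_total)
  ssd <- design$ssd_initial_ms
  for (i in idx_stop) {  # only the staircase path is sequential
    ssd_vec[i] <- ssd
    responded <- go_rt[i] < ssd + stop_lat[i]
    if (!responded) go_rt[i] <- Inf  # stop runner won
    ssd <- staircase_update(ssd, responded, design)
  }

  answered <- is.finite(go_rt)
  other <- c(left = "right", right = "left")
  response <- ifelse(answered,
                     ifelse(wrong, other[stimulus], stimulus), "none")
  trials <- data.frame(
    trial_index = c(seq_len(design$n_choice_trials),
                    seq_len(design$n_trials)) - 1L,
    block = block, trial_type = trial_type, stimulus = stimulus,
    ssd_ms = ssd_vec,
    response = unname(response),
    rt_ms = ifelse(answered, go_rt, NA_real_),
    stringsAsFactors = FALSE)
  structure(list(participant_id = participant_id, group = group,
                 effector = effector, design = design, params = params,
                 seed = as.integer(seed), trials = trials),
            class = "ssrt_session")
}

#' @export
print.ssrt_session <- function(x, ...) {
  st <- x$trials[x$trials$block == "stopsignal", ]
  stops <- st[st$trial_type == "stop", ]
  cat(sprintf("Session %s (%s, %s): %d choice + %d stop-signal trials\n",
              x$participant_id, x$group, x$effector,
              sum(x$trials$block == "choice"), nrow(st)))
  if (nrow(stops)) {
    cat(sprintf("  p(respond|signal) = %.3f, mean SSD = %.1f ms\n",
                mean(stops$response != "none"), mean(stops$ssd_ms)))
  }
  invisible(x)
}

# Deterministic child-seed derivation; kept below 2^31.
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1000003) %% 2147483629)
}

#' Simulate a full two-group, two-effector cohort
#'
#' Generates `n_per_group` participants per group, each tested with both
#' effectors. Per-participant parameters are jittered around the group-level
#' [race_params()] with between-subject SDs shared across effectors (one draw
#' per participant), which induces the positive hands-feet correlation seen in
#' individual-differences data. Every session gets an independently derived
#' child seed, so cohorts are reproducible and insensitive to reordering.
#'
#' @param group_specs Named list mapping group name to either a single
#'   [race_params()] (used for both effectors) or a named list
#'   `list(hands = , feet = )` of [race_params()].
#' @param n_per_group Participants per group (>= 2).
#' @param design A [task_design()].
#' @param seed Master integer seed.
#' @param between_sd Named list of between-subject SDs applied additively to
#'   `go_mu_ms` and `ssrt_mean_ms`.
#' @return A list of `ssrt_session` objects, class `ssrt_cohort`.
#' @examples
#' coh <- simulate_cohort(n_per_group = 2, seed = 7,
#'                        design = task_design(n_trials = 48, n_choice_trials = 8))
#' length(coh)  # 2 groups x 2 participants x 2 effectors
#' @export
simulate_cohort <- function(group_specs = default_cohort_spec()$groups,
                            n_per_group = 30, design = task_design(), seed,
                            between_sd = list(go_mu_ms = 30, ssrt_mean_ms = 30)) {
  if (missing(seed)) stop("seed is required for simulation")
  if (length(group_specs) == 0) stop("group_specs must name at least one group")
  if (n_per_group < 2) stop("n_per_group must be at least 2")

  effectors_of <- function(sp) {
    if (inherits(sp, "race_params")) list(hands = sp, feet = sp) else sp
  }
  set.seed(as.integer(seed))
  sessions <- list()
  idx <- 0L
  for (g in names(group_specs)) {
    spec <- effectors_of(group_specs[[g]])
    for (i in seq_len(n_per_group)) {
      pid <- sprintf("%s_%02d", g, i)
      z_go <- stats::rnorm(1, 0, between_sd$go_mu_ms)
      z_stop <- stats::rnorm(1, 0, between_sd$ssrt_mean_ms)
      for (eff in names(spec)) {
        idx <- idx + 1L
        p <- spec[[eff]]
        pj <- p
        pj$go_mu_ms <- max(50, p$go_mu_ms + z_go)
        pj$ssrt_mean_ms <- max(50, p$ssrt_mean_ms + z_stop)
        sessions[[idx]] <- simulate_session(
          design, pj, seed = .child_seed(seed, idx),
          participant_id = pid, group = g, effector = eff)
      }
    }
  }
  structure(sessions, class = c("ssrt_cohort", "list"))
}

#' Reference cohort specification (elite vs recreational athletes)
#'
#' Generative parameters emulating a 30 + 30 cohort of elite handball players
#' ("expert") and recreational athletes ("control") tested with hands and feet:
#' group-level stop-latency means of 229 / 262 ms (hands) and 260 / 277 ms
#' (feet), two-choice RT means near 408 ms (hands) and 424 ms (feet), and
#' proactive slowing of go responses in the stop-signal block of roughly
#' 24-30% (slowing index about 1.30 for hands, 1.24 for feet).
#'
#' @return A list with elements `groups` (for [simulate_cohort()]),
#'   `n_per_group`, and `between_sd`.
#' @export
default_cohort_spec <- function() {
  # slowing factor s solves s*mu + tau = index * (mu + tau)
  slow <- function(index, mu, tau) (index * (mu + tau) - tau) / mu
  hands <- function(ssrt) race_params(go_mu_ms = 330, go_tau_ms = 78,
                                      ssrt_mean_ms = ssrt,
                                      slowing_factor = slow(1.298, 330, 78))
  feet <- function(ssrt) race_params(go_mu_ms = 346, go_tau_ms = 78,
                                     ssrt_mean_ms = ssrt,
                                     slowing_factor = slow(1.239, 346, 78))
  list(
    groups = list(
      expert = list(hands = hands(229.36), feet = feet(259.5)),
      control = list(hands = hands(261.52), feet = feet(276.74))
    ),
    n_per_group = 30,
    between_sd = list(go_mu_ms = 30, ssrt_mean_ms = 30)
  )
}
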