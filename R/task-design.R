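#' Stop-signal task design
#'
#' Defines the block structure of one session: a pure two-choice (go) block
#' followed by a stop-signal block in which a fixed fraction of trials carries
#' a stop signal whose delay (SSD) is driven by an adaptive staircase.
#'
#' Defaults describe the administered design this package models: a 48-trial
#' two-choice block, then 288 stop-signal trials of which 25% are stop trials,
#' with the SSD starting at 100 ms and moving in 50 ms steps.
#'
#' @param n_trials Number of trials in the stop-signal block.
#' @param stop_fraction Fraction of stop trials in the stop-signal block;
#'   `stop_fraction * n_trials` must be an integer.
#' @param n_choice_trials Number of go trials in the preceding two-choice block.
#' @param ssd_initial_ms Initial stop-signal delay (ms).
#' @param ssd_step_ms Staircase step size (ms).
#' @param ssd_min_ms,ssd_max_ms Bounds the staircase is clipped to (ms).
#' @return An object of class `task_design` (a validated list).
#' @examples
#' d <- task_design()
#' d$n_trials * d$stop_fraction  # 72 stop trials
#' @export
task_design <- function(n_trials = 288L, stop_fraction = 0.25,
                        n_choice_trials = 48L, ssd_initial_ms = 100,
                        ssd_step_ms = 50, ssd_min_ms = 0, ssd_max_ms = 900) {
  n_trials <- as.integer(n_trials)
  n_choice_trials <- as.integer(n_choice_trials)
  stopifnot(n_trials >= 1, n_choice_trials >= 0,
            stop_fraction > 0, stop_fraction < 1,
            ssd_step_ms > 0, ssd_min_ms >= 0)
  n_stop <- n_trials * stop_fraction
  if (abs(n_stop - round(n_stop)) > 1e-8) {
    stop("stop_fraction * n_trials must be an integer (got ", n_stop, ")")
  }
  if (!(ssd_min_ms <= ssd_initial_ms && ssd_initial_ms <= ssd_max_ms)) {
    stop("need ssd_min_ms <= ssd_initial_ms <= ssd_max_ms")
  }
  structure(list(
    n_trials = n_trials, stop_fraction = stop_fraction,
    n_choice_trials = n_choice_trials,
    ssd_initial_ms = ssd_initial_ms, ssd_step_ms = ssd_step_ms,
    ssd_min_ms = ssd_min_ms, ssd_max_ms = ssd_max_ms
  ), class = "task_design")
}

#' Generative parameters for the independent horse-race model
#'
#' Parameterises one simulated participant: an ex-Gaussian go-RT distribution
#' (the standard parametric RT model: Gaussian with mean `go_mu_ms` and SD
#' `go_sigma_ms` convolved with an exponential of mean `go_tau_ms`), a
#' truncated-normal stop-process latency, a multiplicative slowing of the go-RT
#' Gaussian location in the stop-signal block (proactive slowing while waiting
#' for possible stop signals), and lapse rates for choice errors and omissions.
#'
#' Under the race model a response is emitted on a stop trial iff the sampled
#' go finishing time is below SSD + the sampled stop latency; the staircase
#' then tracks the SSD at which this happens about half the time.
#'
#' @param go_mu_ms,go_sigma_ms,go_tau_ms Ex-Gaussian go-RT parameters (ms).
#' @param ssrt_mean_ms,ssrt_sd_ms Stop-latency mean and SD (ms); the latency is
#'   normal truncated at 0.
#' @param slowing_factor Multiplier (>= 1 typically) on `go_mu_ms` in the
#'   stop-signal block only.
#' @param choice_error_rate Probability a response lands on the wrong side.
#' @param omission_rate Probability the go process never finishes (no response
#'   on a go trial).
#' @return An object of class `race_params`.
#' @examples
#' race_params(ssrt_mean_ms = 230)
#' @export
race_params <- function(go_mu_ms = 330, go_sigma_ms = 40, go_tau_ms = 78,
                        ssrt_mean_ms = 260, ssrt_sd_ms = 30,
                        slowing_factor = 1.37,
                        choice_error_rate = 0.02, omission_rate = 0.005) {
  stopifnot(go_mu_ms > 0, go_sigma_ms > 0, go_tau_ms > 0,
            ssrt_mean_ms > 0, ssrt_sd_ms > 0, slowing_factor > 0,
            choice_error_rate >= 0, choice_error_rate < 1,
            omission_rate >= 0, omission_rate < 1)
  structure(list(
    go_mu_ms = go_mu_ms, go_sigma_ms = go_sigma_ms, go_tau_ms = go_tau_ms,
    ssrt_mean_ms = ssrt_mean_ms, ssrt_sd_ms = ssrt_sd_ms,
    slowing_factor = slowing_factor,
    choice_error_rate = choice_error_rate, omission_rate = omission_rate
  ), class = "race_params")
}

#' @export
print.task_design <- function(x, ...) {
  cat("Stop-signal task design\n")
  cat(sprintf("  choice block : %d go trials\n", x$n_choice_trials))
  cat(sprintf("  stop block   : %d trials (%d stop, %.0f%%)\n",
              x$n_trials, as.integer(x$n_trials * x$stop_fraction),
              100 * x$stop_fraction))
  cat(sprintf("  SSD staircase: start %g ms, step %g ms, range [%g, %g] ms\n",
              x$ssd_initial_ms, x$ssd_step_ms, x$ssd_min_ms, x$ssd_max_ms))
  invisible(x)
}

#' @export
print.race_params <- function(x, ...) {
  cat("Race-model parameters\n")
  cat(sprintf("  go RT  : exGauss(mu = %g, sigma = %g, tau = %g) ms, slowing x%g\n",
              x$go_mu_ms, x$go_sigma_ms, x$go_tau_ms, x$slowing_factor))
  cat(sprintf("  stop   : truncN(mean = %g, sd = %g) ms\n",
              x$ssrt_mean_ms, x$ssrt_sd_ms))
  cat(sprintf("  lapses : choice error %g, omission %g\n",
              x$choice_error_rate, x$omission_rate))
  invisible(x)
}
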