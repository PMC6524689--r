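#' Rank index for the integration method
#'
#' The integration method picks the nth fastest go RT, where n is the trial
#' basis count multiplied by p(respond | signal), rounded up (minimum 1). With
#' the 288-trial design and a response rate of 0.6 this selects the 173rd RT
#' (288 x 0.6 = 172.8).
#'
#' @param n_trials_basis Basis count (total block trials or go trials).
#' @param p_respond_signal Proportion of stop trials with a response, in
#'   \[0, 1\].
#' @return Integer rank (1-based).
#' @examples
#' go_rt_rank_index(288, 0.6)  # 173
#' @export
go_rt_rank_index <- function(n_trials_basis, p_respond_signal) {
  stopifnot(n_trials_basis >= 1)
  if (!is.numeric(p_respond_signal) || is.na(p_respond_signal) ||
      p_respond_signal < 0 || p_respond_signal > 1) {
    stop("p_respond_signal must be in [0, 1]")
  }
  max(1L, as.integer(ceiling(n_trials_basis * p_respond_signal - 1e-9)))
}

#' Integration-method SSRT estimate
#'
#' Estimates the stop-signal reaction time from one session: rank-order the
#' go RTs of the stop-signal block ascending (omitted go trials are assigned
#' the maximum observed go RT; choice errors are included by default), take
#' the RT at rank [go_rt_rank_index()] of the basis count times
#' p(respond | signal), and subtract the mean SSD over all stop trials.
#'
#' The `total_trials` basis uses the full stop-signal block length (288 by
#' default) as in the worked-design convention; `go_trials` uses only the go
#' trials (216) — the consensus-standard alternative. The rank is capped at
#' the number of rankable go RTs, so p = 1 selects the maximum go RT.
#'
#' @param session An `ssrt_session` (simulated or read from CSV).
#' @param basis `"total_trials"` (default) or `"go_trials"`.
#' @param include_choice_errors Include wrong-side go responses in the ranking
#'   (default `TRUE`).
#' @return An object of class `ssrt_estimate` with fields
#'   `p_respond_signal`, `mean_ssd_ms`, `rank_index`, `nth_go_rt_ms`,
#'   `ssrt_ms`, `n_trials_basis`, and a `low_p_warning` flag set when no stop
#'   trial drew a response.
#' @export
estimate_ssrt_integration <- function(session,
                                      basis = c("total_trials", "go_trials"),
                                      include_choice_errors = TRUE) {
  basis <- match.arg(basis)
  tr <- session$trials[session$trials$block == "stopsignal", ]
  stops <- tr[tr$trial_type == "stop", ]
  gos <- tr[tr$trial_type == "go", ]
  if (nrow(stops) == 0) stop("session has no stop trials; SSRT is undefined")
  if (nrow(gos) == 0) stop("session has no go trials in the stop-signal block")

  p <- mean(stops$response != "none")
  mean_ssd <- mean(stops$ssd_ms)

  if (!include_choice_errors) {
    keep <- gos$response == "none" | gos$response == gos$stimulus
    gos <- gos[keep, ]
  }
  rts <- gos$rt_ms
  if (all(is.na(rts))) stop("no go responses to rank")
  rts[is.na(rts)] <- max(rts, na.rm = TRUE)  # omissions get the max go RT
  rts <- sort(rts)

  n_basis <- if (basis == "total_trials") nrow(tr) else length(rts)
  rank <- min(go_rt_rank_index(n_basis, p), length(rts))
  nth <- rts[rank]
  structure(list(p_respond_signal = p, mean_ssd_ms = mean_ssd,
                 rank_index = rank, nth_go_rt_ms = nth,
                 ssrt_ms = nth - mean_ssd, n_trials_basis = n_basis,
                 low_p_warning = p == 0), class = "ssrt_estimate")
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf(
    "SSRT (integration): %.1f ms  [p(respond|signal) = %.3f, mean SSD = %.1f ms,\n  rank %d of basis %d -> nth go RT %.1f ms]%s\n",
    x$ssrt_ms, x$p_respond_signal, x$mean_ssd_ms, x$rank_index,
    x$n_trials_basis, x$nth_go_rt_ms,
    if (x$low_p_warning) "  (warning: p = 0, rank floored at 1)" else ""))
  invisible(x)
}

#' Two-choice RT summary of a go block
#'
#' Mean and SD over correct responses only (wrong-side responses and omissions
#' are excluded from the RT summary but count against accuracy).
#'
#' @param block Data frame of go trials (e.g. the `choice` block rows of a
#'   session's `trials`).
#' @return A list with `mean_ms`, `sd_ms`, `accuracy`, `n_correct`, `n_total`.
#' @export
two_choice_rt <- function(block) {
  if (any(block$trial_type != "go")) stop("two-choice block must contain go trials only")
  correct <- block$response != "none" & block$response == block$stimulus
  if (!any(correct)) stop("no correct responses in block; RT summary undefined")
  rts <- block$rt_ms[correct]
  list(mean_ms = mean(rts), sd_ms = stats::sd(rts),
       accuracy = mean(correct), n_correct = sum(correct), n_total = nrow(block))
}

#' Strategic slowing index
#'
#' Ratio of the mean no-signal RT in the stop-signal block (ns-RT) to the mean
#' two-choice RT from the pure go block (2-CRT). Values above 1 quantify how
#' much participants slow their go responses while anticipating stop signals;
#' values below 1 (speeding) are representable.
#'
#' @param ns_rt_ms Mean no-signal RT (ms), positive.
#' @param crt_ms Mean two-choice RT (ms), positive.
#' @return A list with `ns_rt_ms`, `crt_ms`, `index`.
#' @examples
#' slowing_index(519.2, 400)$index  # 1.298
#' @export
slowing_index <- function(ns_rt_ms, crt_ms) {
  if (!is.numeric(ns_rt_ms) || ns_rt_ms <= 0 || !is.numeric(crt_ms) || crt_ms <= 0) {
    stop("ns_rt_ms and crt_ms must be positive")
  }
  list(ns_rt_ms = ns_rt_ms, crt_ms = crt_ms, index = ns_rt_ms / crt_ms)
}

#' Per-participant summary of a cohort
#'
#' Applies [two_choice_rt()], [estimate_ssrt_integration()] and
#' [slowing_index()] to every session and returns the flat per-participant
#' table consumed by the inference layer.
#'
#' @param sessions A list of `ssrt_session` objects.
#' @param basis Passed to [estimate_ssrt_integration()].
#' @return A data frame with one row per session: `participant_id`, `group`,
#'   `effector`, `crt_mean`, `crt_sd`, `accuracy`, `ns_rt_mean`,
#'   `slowing_index`, `p_respond_signal`, `mean_ssd`, `ssrt`.
#' @export
summarize_sessions <- function(sessions, basis = "total_trials") {
  if (inherits(sessions, "ssrt_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    choice <- s$trials[s$trials$block == "choice", ]
    ss <- s$trials[s$trials$block == "stopsignal", ]
    ns <- ss[ss$trial_type == "go", ]
    crt <- two_choice_rt(choice)
    ns_correct <- ns$response != "none" & ns$response == ns$stimulus
    ns_rt <- mean(ns$rt_ms[ns_correct])
    est <- estimate_ssrt_integration(s, basis = basis)
    data.frame(participant_id = s$participant_id, group = s$group,
               effector = s$effector,
               crt_mean = crt$mean_ms, crt_sd = crt$sd_ms,
               accuracy = crt$accuracy, ns_rt_mean = ns_rt,
               slowing_index = slowing_index(ns_rt, crt$mean_ms)$index,
               p_respond_signal = est$p_respond_signal,
               mean_ssd = est$mean_ssd_ms, ssrt = est$ssrt_ms,
               stringsAsFactors = FALSE)
  }))
}

#' @rdname summarize_sessions
#' @param summary A data frame from `summarize_sessions()`.
#' @param path Output CSV path.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
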