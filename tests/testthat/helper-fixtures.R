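# Build an ssrt_session by hand from explicit go RTs and stop-trial outcomes,
# for worked examples where the estimate is enumerable on paper.
manual_session <- function(go_rts, ssds, stop_responded,
                           stop_rts = rep(350, sum(stop_responded)),
                           choice_rts = c(400, 500),
                           design = task_design(n_trials = length(go_rts) + length(ssds),
                                                stop_fraction = length(ssds) /
                                                  (length(go_rts) + length(ssds)),
                                                n_choice_trials = length(choice_rts))) {
  go <- data.frame(block = "stopsignal", trial_type = "go", stimulus = "left",
                   ssd_ms = NA_real_, response = "left", rt_ms = go_rts,
                   stringsAsFactors = FALSE)
  resp <- ifelse(stop_responded, "left", "none")
  rt <- rep(NA_real_, length(ssds))
  rt[stop_responded] <- stop_rts
  stop <- if (length(ssds)) {
    data.frame(block = "stopsignal", trial_type = "stop",
               stimulus = "left", ssd_ms = ssds, response = resp,
               rt_ms = rt, stringsAsFactors = FALSE)
  } else {
    go[0, ]
  }
  choice <- data.frame(block = "choice", trial_type = "go", stimulus = "left",
                       ssd_ms = NA_real_, response = "left", rt_ms = choice_rts,
                       stringsAsFactors = FALSE)
  trials <- rbind(choice, go, stop)
  trials$trial_index <- c(seq_along(choice_rts),
                          seq_len(nrow(go) + nrow(stop))) - 1L
  trials <- trials[, c("trial_index", "block", "trial_type", "stimulus",
                       "ssd_ms", "response", "rt_ms")]
  structure(list(participant_id = "manual", group = "control",
                 effector = "hands", design = design, trials = trials),
            class = "ssrt_session")
}

# Independent Monte-Carlo oracle for the Cauchy-prior t-test Bayes factor:
# draws from the (truncated) prior and averages the noncentral-t likelihood
# ratio. Deliberately shares no code with jzs_bayes_factor().
mc_bayes_factor <- function(t, n1, n2, location = 0, scale = 0.707,
                            side = "two_sided", ndraw = 1e6, seed = 101) {
  set.seed(seed)
  delta <- stats::rcauchy(ceiling(ndraw * 3), location, scale)
  delta <- switch(side,
                  two_sided = delta,
                  positive = delta[delta > 0],
                  negative = delta[delta < 0])[seq_len(ndraw)]
  ne <- sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  mean(suppressWarnings(stats::dt(t, df, ncp = delta * ne))) / stats::dt(t, df)
}

small_design <- function() task_design(n_trials = 48, n_choice_trials = 8)
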