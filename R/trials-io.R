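#' Write and read trial-level data as CSV
#'
#' The on-disk schema is one row per trial with columns `participant_id`,
#' `group`, `effector`, `block`, `trial_index`, `trial_type`, `stimulus`,
#' `ssd_ms`, `response`, `rt_ms`. Missing values (no SSD on go trials, no RT
#' on omissions/inhibitions) are written as empty fields. UTF-8, comma
#' separated, `.` decimal separator, header row.
#'
#' `read_trials_csv()` validates enum columns and numeric fields and reports
#' the offending row on failure; the round trip
#' `read_trials_csv(write_trials_csv(x))` reproduces the sessions' trials and
#' metadata exactly.
#'
#' @param sessions A list of `ssrt_session` objects (e.g. from
#'   [simulate_cohort()]) or a single session.
#' @param path File path to write to / read from.
#' @return `write_trials_csv()` returns `path` invisibly; `read_trials_csv()`
#'   returns an `ssrt_cohort` list of sessions (without generative params);
#'   `trials_data_frame()` returns the flat data frame.
#' @export
write_trials_csv <- function(sessions, path) {
  df <- trials_data_frame(sessions)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
trials_data_frame <- function(sessions) {
  if (inherits(sessions, "ssrt_session")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    cbind(data.frame(participant_id = s$participant_id, group = s$group,
                     effector = s$effector, stringsAsFactors = FALSE),
          s$trials)
  }))
}

.trial_cols <- c("participant_id", "group", "effector", "block", "trial_index",
                 "trial_type", "stimulus", "ssd_ms", "response", "rt_ms")

#' @rdname write_trials_csv
#' @param design The [task_design()] to attach to each session read back.
#' @export
read_trials_csv <- function(path, design = task_design()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(.trial_cols, names(df))
  if (length(missing_cols)) {
    stop("trial CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  as_num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("non-numeric %s '%s' in data row %d", col, df[[col]][bad[1]], bad[1]))
    }
    v
  }
  df$ssd_ms <- as_num("ssd_ms")
  df$rt_ms <- as_num("rt_ms")
  df$trial_index <- as.integer(as_num("trial_index"))
  check_enum <- function(col, levels, allow_na = FALSE) {
    v <- df[[col]]
    bad <- which(!(v %in% levels | (allow_na & is.na(v))))
    if (length(bad)) {
      stop(sprintf("invalid %s '%s' in data row %d", col, v[bad[1]], bad[1]))
    }
  }
  check_enum("block", c("choice", "stopsignal"))
  check_enum("trial_type", c("go", "stop"))
  check_enum("stimulus", c("left", "right"))
  check_enum("response", c("left", "right", "none"))
  bad_rt <- which(xor(is.na(df$rt_ms), df$response == "none"))
  if (length(bad_rt)) {
    stop("rt_ms must be present iff response != 'none' (data row ", bad_rt[1], ")")
  }
  bad_ssd <- which(xor(is.na(df$ssd_ms), df$trial_type == "go"))
  if (length(bad_ssd)) {
    stop("ssd_ms must be present iff trial_type == 'stop' (data row ", bad_ssd[1], ")")
  }

  key <- interaction(df$participant_id, df$effector, drop = TRUE)
  sessions <- lapply(split(df, key), function(d) {
    d <- d[order(match(d$block, c("choice", "stopsignal")), d$trial_index), ]
    trials <- d[, c("trial_index", "block", "trial_type", "stimulus",
                    "ssd_ms", "response", "rt_ms")]
    rownames(trials) <- NULL
    structure(list(participant_id = d$participant_id[1], group = d$group[1],
                   effector = d$effector[1], design = design, trials = trials),
              class = "ssrt_session")
  })
  # stable order: file appearance
  ord <- order(match(names(sessions), unique(as.character(key))))
  structure(unname(sessions[ord]), class = c("ssrt_cohort", "list"))
}
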