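#' Partial eta squared from an F ratio
#'
#' etap^2 = SS_effect / (SS_effect + SS_error) = (F df1) / (F df1 + df2).
#'
#' @param f F ratio (>= 0).
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in \[0, 1\].
#' @examples
#' partial_eta_from_f(7.89, 1, 58)  # 0.120
#' @export
partial_eta_from_f <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 >= 1, df2 >= 1)
  (f * df1) / (f * df1 + df2)
}

#' Published group-level summary statistics of the reference expertise study
#'
#' Group means and SDs (n = 30 per group) of integration-method SSRT for
#' elite handball players ("expert") versus recreational athletes ("control"),
#' by effector, as reported in the motor-expertise study whose design the
#' simulator emulates. These summaries are the inputs to the deterministic
#' recomputation layer ([reproduce_printed()]); they are data, not fitted
#' values.
#'
#' @return A data frame with columns `measure`, `effector`, `group`, `mean`,
#'   `sd`, `n`.
#' @export
published_group_summaries <- function() {
  data.frame(
    measure = "ssrt",
    effector = rep(c("hands", "feet"), each = 2),
    group = rep(c("expert", "control"), 2),
    mean = c(229.36, 261.52, 259.50, 276.74),
    sd = c(32.83, 39.00, 41.60, 38.40),
    n = 30L,
    stringsAsFactors = FALSE
  )
}

# Group contrast block shared by reproduce_printed() and analyze_summary():
# pooled t, d with noncentral-t CI, and the directed Bayes-factor pair.
.contrast_block <- function(m1, sd1, n1, m2, sd2, n2, conf_level = 0.95,
                            priors = list(c(location = 0, scale = 0.707),
                                          c(location = 0.5, scale = 0.5)),
                            side = "positive",
                            robustness_scales = c(0.5, 0.707, 1.0)) {
  tt <- independent_t_test(m1, sd1, n1, m2, sd2, n2, side = side)
  es <- pooled_cohens_d(m1, sd1, n1, m2, sd2, n2)
  ci <- smd_confidence_interval(es$d, n1, n2, conf_level)
  bfs <- lapply(priors, function(pr)
    jzs_bayes_factor(tt$t, n1, n2, prior_location = pr[["location"]],
                     prior_scale = pr[["scale"]], side = side))
  list(t = tt$t, df = tt$df, p = tt$p, d = es$d,
       ci_low = ci$ci_low, ci_high = ci$ci_high, conf_level = conf_level,
       bayes_factors = bfs,
       robustness = bf_robustness(tt$t, n1, n2, robustness_scales, side = side))
}

#' Recompute the reference study's printed statistics from its summaries
#'
#' The deterministic reproduction surface: starting only from the published
#' group means/SDs ([published_group_summaries()]) and printed F ratios, it
#' recomputes per effector the pooled t, Cohen's d with its noncentral-t 95%
#' CI, and the one-sided Bayes factors under the default Cauchy(0, 0.707) and
#' informed Cauchy(0.5, 0.5) priors with a robustness sweep; plus partial eta
#' squared for the printed ANOVA F ratios, the Fisher-z correlation bounds,
#' and the 2 x 2 design sample size at f = 0.33.
#'
#' @return A nested list (`hands`, `feet`, `anova_eta`, `correlations`,
#'   `sample_size`).
#' @export
reproduce_printed <- function() {
  gs <- published_group_summaries()
  blk <- function(eff) {
    e <- gs[gs$effector == eff & gs$group == "expert", ]
    c0 <- gs[gs$effector == eff & gs$group == "control", ]
    .contrast_block(e$mean, e$sd, e$n, c0$mean, c0$sd, c0$n)
  }
  list(
    hands = blk("hands"),
    feet = blk("feet"),
    anova_eta = data.frame(
      effect = c("effector", "group", "group:effector"),
      F = c(26.54, 7.89, 2.87), df1 = 1, df2 = 58,
      partial_eta_sq = partial_eta_from_f(c(26.54, 7.89, 2.87), 1, 58)),
    correlations = list(
      overall = pearson_ci(0.63, 60, sidedness = "one_sided"),
      expert = pearson_ci(0.67, 30),
      control = pearson_ci(0.54, 30),
      comparison = compare_independent_correlations(0.67, 30, 0.54, 30)),
    sample_size = sample_size_mixed_anova(f = 0.33)
  )
}

#' Analyze a per-participant summary table
#'
#' The full inferential layer on a cohort summary (from
#' [summarize_sessions()] or a summary CSV): mixed 2 x 2 ANOVA on SSRT with
#' partial eta squared, per-effector expert-vs-control contrasts (pooled t,
#' d with noncentral-t CI, directed Bayes factors under the default and
#' informed priors, robustness sweep), hands-feet SSRT correlations overall
#' and per group with their Fisher-z comparison, and the slowing-index group
#' comparison per effector.
#'
#' Contrasts are coded control minus expert, so positive t and d mean faster
#' stopping (shorter SSRT) in experts.
#'
#' @param summary Data frame with columns `participant_id`, `group`,
#'   `effector`, `ssrt`, `slowing_index` (as written by
#'   [summarize_sessions()]). Groups must be named `expert` and `control`.
#' @param conf_level Confidence level for intervals.
#' @param side Sidedness of the expert-superiority contrasts.
#' @return A nested list of class `ssrt_report`.
#' @export
analyze_summary <- function(summary, conf_level = 0.95, side = "positive") {
  stopifnot(all(c("expert", "control") %in% summary$group))
  grp <- function(eff, g, col = "ssrt") {
    x <- summary[[col]][summary$effector == eff & summary$group == g]
    list(mean = mean(x), sd = stats::sd(x), n = length(x), values = x)
  }
  effectors <- intersect(c("hands", "feet"), unique(summary$effector))

  contrasts <- lapply(effectors, function(eff) {
    e <- grp(eff, "expert"); c0 <- grp(eff, "control")
    c(list(effector = eff,
           expert_mean = e$mean, expert_sd = e$sd,
           control_mean = c0$mean, control_sd = c0$sd),
      .contrast_block(e$mean, e$sd, e$n, c0$mean, c0$sd, c0$n,
                      conf_level = conf_level, side = side))
  })
  names(contrasts) <- effectors

  anova_res <- mixed_anova_2x2(summary, value = "ssrt")

  correlations <- NULL
  if (length(effectors) == 2) {
    wide <- merge(
      summary[summary$effector == effectors[1],
              c("participant_id", "group", "ssrt")],
      summary[summary$effector == effectors[2], c("participant_id", "ssrt")],
      by = "participant_id", suffixes = c("_1", "_2"))
    r_all <- stats::cor(wide$ssrt_1, wide$ssrt_2)
    by_group <- lapply(split(wide, wide$group), function(w)
      pearson_ci(stats::cor(w$ssrt_1, w$ssrt_2), nrow(w),
                 conf_level = conf_level))
    re <- by_group[["expert"]]; rc <- by_group[["control"]]
    correlations <- list(
      overall = pearson_ci(r_all, nrow(wide), conf_level, "one_sided"),
      by_group = by_group,
      comparison = compare_independent_correlations(re$r, re$n, rc$r, rc$n))
  }

  slowing <- lapply(effectors, function(eff) {
    e <- grp(eff, "expert", "slowing_index")
    c0 <- grp(eff, "control", "slowing_index")
    bf <- jzs_bayes_factor(
      independent_t_test(e$mean, e$sd, e$n, c0$mean, c0$sd, c0$n)$t,
      e$n, c0$n, prior_location = 0, prior_scale = 0.707, side = "two_sided")
    list(effector = eff, expert_mean = e$mean, control_mean = c0$mean,
         bf01 = bf$bf01)
  })
  names(slowing) <- effectors

  structure(list(anova = anova_res, contrasts = contrasts,
                 correlations = correlations, slowing = slowing,
                 conf_level = conf_level, side = side),
            class = "ssrt_report")
}

#' @export
print.ssrt_report <- function(x, ...) {
  print(x$anova)
  for (ct in x$contrasts) {
    cat(sprintf(
      "%s: expert %.1f ms vs control %.1f ms, t(%d) = %.2f, p = %.3g, d = %.2f [%.3f, %.3f]\n",
      ct$effector, ct$expert_mean, ct$control_mean, ct$df, ct$t, ct$p, ct$d,
      ct$ci_low, ct$ci_high))
    cat(sprintf("  BF10 = %.2f (Cauchy 0/0.707), %.2f (Cauchy 0.5/0.5)\n",
                ct$bayes_factors[[1]]$bf10, ct$bayes_factors[[2]]$bf10))
  }
  if (!is.null(x$correlations)) {
    cat(sprintf("hands-feet r = %.2f, one-sided lower bound %.2f\n",
                x$correlations$overall$r, x$correlations$overall$ci_low))
  }
  invisible(x)
}

#' Default pipeline configuration
#'
#' The simulate -> estimate -> analyze configuration at the reference study's
#' conditions: 30 participants per group, both effectors, the 48 + 288 trial
#' design, and the generative parameters of [default_cohort_spec()].
#'
#' @param seed Master seed (mandatory for simulation).
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(seed) {
  spec <- default_cohort_spec()
  structure(list(seed = as.integer(seed), design = task_design(),
                 groups = spec$groups, n_per_group = spec$n_per_group,
                 between_sd = spec$between_sd,
                 analysis = list(conf_level = 0.95, side = "positive")),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Fields mirror [default_pipeline_config()]: `seed`, optional `design`
#' (passed to [task_design()]), optional `groups` (group -> effector ->
#' [race_params()] fields), `n_per_group`, `between_sd`, `analysis`. Omitted
#' fields fall back to the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) stop("config must set a seed")
  cfg <- default_pipeline_config(raw$seed)
  if (!is.null(raw$design)) cfg$design <- do.call(task_design, raw$design)
  if (!is.null(raw$groups)) {
    cfg$groups <- lapply(raw$groups, function(g) {
      if (!is.null(g$go_mu_ms) || is.null(names(g))) do.call(race_params, g)
      else lapply(g, function(eff) do.call(race_params, eff))
    })
  }
  if (!is.null(raw$n_per_group)) cfg$n_per_group <- raw$n_per_group
  if (!is.null(raw$between_sd)) cfg$between_sd <- raw$between_sd
  if (!is.null(raw$analysis)) cfg$analysis <- utils::modifyList(cfg$analysis, raw$analysis)
  cfg
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full simulate -> estimate -> analyze pipeline
#'
#' Simulates the cohort, writes the trial-level CSV, summarises every session
#' (two-choice RT, slowing index, integration-method SSRT), writes the
#' per-participant summary CSV, runs [analyze_summary()], and writes the
#' report as JSON and markdown. Rerunning with the same config and seed
#' reproduces every output byte for byte.
#'
#' @param config A `pipeline_config` (from [default_pipeline_config()] or
#'   [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The report list, invisibly; side effects: `trials.csv`,
#'   `summary.csv`, `report.json`, `report.md` in `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  .log_stage("simulate", "seed %d, %d per group, %d + %d trials",
             config$seed, config$n_per_group, config$design$n_choice_trials,
             config$design$n_trials)
  cohort <- simulate_cohort(config$groups, config$n_per_group, config$design,
                            seed = config$seed, between_sd = config$between_sd)
  trials_path <- file.path(out_dir, "trials.csv")
  write_trials_csv(cohort, trials_path)
  .log_stage("simulate", "%d sessions -> %s", length(cohort), trials_path)

  summary <- summarize_sessions(cohort)
  summary_path <- file.path(out_dir, "summary.csv")
  write_summary_csv(summary, summary_path)
  .log_stage("estimate", "%d rows -> %s", nrow(summary), summary_path)

  report <- analyze_summary(summary,
                            conf_level = config$analysis$conf_level,
                            side = config$analysis$side)
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(.report_to_list(report), json_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  writeLines(.report_markdown(report), file.path(out_dir, "report.md"))
  .log_stage("analyze", "report -> %s", json_path)
  invisible(report)
}

.report_to_list <- function(report) {
  list(
    anova = as.list(as.data.frame(report$anova)),
    contrasts = lapply(report$contrasts, function(ct) {
      ct$bayes_factors <- lapply(ct$bayes_factors, unclass)
      ct
    }),
    correlations = report$correlations,
    slowing = report$slowing,
    conf_level = report$conf_level, side = report$side)
}

.report_markdown <- function(report) {
  a <- report$anova
  lines <- c("# Stop-signal expertise report", "", "## Mixed 2 x 2 ANOVA (SSRT)", "",
             "| effect | df | F | p | partial eta sq |", "|---|---|---|---|---|",
             sprintf("| %s | (%d, %d) | %.2f | %.3g | %.3f |",
                     a$effect, a$df1, a$df2, a$F, a$p, a$partial_eta_sq),
             "", "## Group contrasts (control - expert)", "")
  for (ct in report$contrasts) {
    lines <- c(lines, sprintf(
      "- **%s**: t(%d) = %.2f, p = %.3g, d = %.2f, %d%% CI [%.3f, %.3f]; BF10 = %.2f (Cauchy 0/0.707), %.2f (Cauchy 0.5/0.5)",
      ct$effector, ct$df, ct$t, ct$p, ct$d, round(100 * ct$conf_level),
      ct$ci_low, ct$ci_high,
      ct$bayes_factors[[1]]$bf10, ct$bayes_factors[[2]]$bf10))
  }
  if (!is.null(report$correlations)) {
    lines <- c(lines, "", sprintf(
      "Hands-feet SSRT correlation r = %.2f (one-sided lower bound %.2f); group comparison p = %.3f.",
      report$correlations$overall$r, report$correlations$overall$ci_low,
      report$correlations$comparison$p))
  }
  lines
}

#' Generate a tiny reproducible fixture cohort
#'
#' A reduced design (8 choice + 48 stop-signal trials, 25% stop) with 2
#' participants per group and both effectors — 448 data rows — written as a
#' trial CSV. Used by the unit tests and as a fast worked example.
#'
#' @param seed Integer seed.
#' @param dir Directory for `fixture_trials.csv`.
#' @return Path to the written CSV, invisibly.
#' @export
make_fixtures <- function(seed, dir = tempdir()) {
  design <- task_design(n_trials = 48, n_choice_trials = 8)
  spec <- default_cohort_spec()
  cohort <- simulate_cohort(spec$groups, n_per_group = 2, design = design,
                            seed = seed, between_sd = spec$between_sd)
  path <- file.path(dir, "fixture_trials.csv")
  write_trials_csv(cohort, path)
  invisible(path)
}
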