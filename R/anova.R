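#' Mixed (split-plot) 2 x 2 ANOVA with partial eta squared
#'
#' Classical between-within ANOVA for one between-subject factor (group) and
#' one within-subject factor (effector), fitted with [stats::aov()] using an
#' `Error(participant)` stratum: the group effect is tested against the
#' subject-within-group mean square, effector and the interaction against the
#' effector x subject mean square. Partial eta squared is
#' SS_effect / (SS_effect + SS_error) — for df1 = 1 this equals F / (F + df2).
#'
#' @param data Data frame with columns `participant_id`, `group`, `effector`
#'   and the response named by `value`; every participant must have one value
#'   per effector.
#' @param value Name of the response column (default `"ssrt"`).
#' @return A data frame of class `mixed_anova` with one row per effect
#'   (`group`, `effector`, `group:effector`): `df1`, `df2`, `F`, `p`,
#'   `partial_eta_sq`.
#' @examples
#' d <- expand.grid(participant_id = sprintf("p%02d", 1:8),
#'                  effector = c("hands", "feet"))
#' d$group <- rep(rep(c("a", "b"), each = 4), 2)
#' set.seed(1); d$ssrt <- rnorm(nrow(d), 250, 30)
#' mixed_anova_2x2(d)
#' @export
mixed_anova_2x2 <- function(data, value = "ssrt") {
  req <- c("participant_id", "group", "effector", value)
  if (!all(req %in% names(data))) {
    stop("data must have columns ", paste(req, collapse = ", "))
  }
  tab <- table(data$participant_id, data$effector)
  if (any(tab != 1)) stop("every participant needs exactly one value per effector")
  if (any(table(unique(data[, c("participant_id", "group")])$group) < 2)) {
    stop("need at least 2 participants per group")
  }
  d <- data.frame(participant_id = factor(data$participant_id),
                  group = factor(data$group),
                  effector = factor(data$effector),
                  y = data[[value]])
  fit <- stats::aov(y ~ group * effector + Error(participant_id), data = d)
  sm <- summary(fit)
  between <- sm[["Error: participant_id"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(strat, name) {
    i <- match(name, trimws(rownames(strat)))
    er <- match("Residuals", trimws(rownames(strat)))
    ss_e <- strat[er, "Sum Sq"]
    data.frame(effect = name, df1 = strat[i, "Df"], df2 = strat[er, "Df"],
               F = strat[i, "F value"], p = strat[i, "Pr(>F)"],
               partial_eta_sq = strat[i, "Sum Sq"] / (strat[i, "Sum Sq"] + ss_e),
               stringsAsFactors = FALSE)
  }
  out <- rbind(pick(between, "group"),
               pick(within, "effector"),
               pick(within, "group:effector"))
  rownames(out) <- NULL
  class(out) <- c("mixed_anova", "data.frame")
  out
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed 2 x 2 ANOVA (between: group, within: effector)\n")
  y <- x
  y$F <- round(y$F, 2)
  y$p <- ifelse(y$p < 0.001, "< 0.001", sprintf("%.3f", y$p))
  y$partial_eta_sq <- round(y$partial_eta_sq, 3)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' A-priori sample size for the between factor of a within-between design
#'
#' Smallest balanced total N whose between-groups test reaches the target
#' power, under the noncentral-F approximation for a repeated-measures design
#' with m measurements per subject and repeated-measures correlation rho:
#' noncentrality lambda = f^2 * N * m / (1 + (m - 1) rho), with df1 =
#' n_groups - 1 and df2 = N - n_groups. rho and the targeted effect are
#' explicit parameters; rho = 0.5 is the conventional planning default.
#'
#' @param f Cohen's f for the between effect (> 0).
#' @param alpha Type-I error rate.
#' @param power Target power.
#' @param n_groups Number of between-subject groups.
#' @param n_measures Number of repeated measurements per subject.
#' @param rho Assumed correlation among repeated measurements.
#' @param n_max Search ceiling for total N.
#' @return A list with `N` (total), `n_per_group`, `power_achieved`, and the
#'   inputs.
#' @examples
#' sample_size_mixed_anova(f = 0.33)  # N = 58 in the 2 x 2 design
#' @export
sample_size_mixed_anova <- function(f, alpha = 0.05, power = 0.80,
                                    n_groups = 2, n_measures = 2, rho = 0.5,
                                    n_max = 100000) {
  stopifnot(f > 0, alpha > 0, alpha < 1, power > 0, power < 1,
            n_groups >= 2, n_measures >= 1, rho > -1, rho < 1)
  pwr <- function(N) {
    lambda <- f^2 * N * n_measures / (1 + (n_measures - 1) * rho)
    df2 <- N - n_groups
    crit <- stats::qf(1 - alpha, n_groups - 1, df2)
    1 - stats::pf(crit, n_groups - 1, df2, ncp = lambda)
  }
  for (N in seq(2 * n_groups, n_max, by = n_groups)) {
    if (pwr(N) >= power) {
      return(list(N = as.integer(N), n_per_group = as.integer(N / n_groups),
                  power_achieved = pwr(N),
                  f = f, alpha = alpha, power_target = power,
                  n_groups = n_groups, n_measures = n_measures, rho = rho))
    }
  }
  stop("target power not reachable with N <= ", n_max)
}
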