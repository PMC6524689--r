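#' Pooled-SD standardized mean difference (Cohen's d) from summaries
#'
#' d = (m2 - m1) / s_p with the pooled SD
#' s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)). The sign
#' convention is second group minus first, so passing (expert, control)
#' summaries yields a positive d when controls are slower.
#'
#' @param m1,sd1,n1 Mean, SD and size of the first group.
#' @param m2,sd2,n2 Mean, SD and size of the second group.
#' @return A list with `d`, `pooled_sd`, `n1`, `n2`.
#' @examples
#' pooled_cohens_d(229.36, 32.83, 30, 261.52, 39.00, 30)$d  # ~0.89
#' @export
pooled_cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(sd1 > 0 || sd2 > 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  if (sp == 0) stop("pooled SD is zero; d is undefined")
  list(d = (m2 - m1) / sp, pooled_sd = sp, n1 = n1, n2 = n2)
}

#' Independent-samples Student t test from summaries
#'
#' Pooled-variance (Student) t with df = n1 + n2 - 2, matching the classical
#' two-sample test on which the pooled d and its noncentral-t interval rest.
#' Sign convention follows [pooled_cohens_d()]: second group minus first.
#'
#' @inheritParams pooled_cohens_d
#' @param side `"two_sided"`, `"positive"` (H1: m2 > m1) or `"negative"`.
#' @return A list with `t`, `df`, `p`, `side`.
#' @examples
#' independent_t_test(229.36, 32.83, 30, 261.52, 39.00, 30, side = "positive")
#' @export
independent_t_test <- function(m1, sd1, n1, m2, sd2, n2,
                               side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  es <- pooled_cohens_d(m1, sd1, n1, m2, sd2, n2)
  se <- es$pooled_sd * sqrt(1 / n1 + 1 / n2)
  tval <- (m2 - m1) / se
  df <- n1 + n2 - 2
  p <- switch(side,
              two_sided = 2 * stats::pt(-abs(tval), df),
              positive = stats::pt(tval, df, lower.tail = FALSE),
              negative = stats::pt(tval, df))
  list(t = tval, df = df, p = p, side = side)
}

#' Noncentral-t confidence interval for a standardized mean difference
#'
#' Inverts the noncentral-t distribution of the observed statistic
#' t = d * sqrt(n1 n2 / (n1 + n2)): the interval bounds are the
#' noncentrality parameters at which the observed t sits at the upper and
#' lower (1 - conf) / 2 tail, divided back to the d scale. This is the exact
#' pivot interval (as implemented in the MBESS tradition), not the
#' normal-approximation d +/- z * SE.
#'
#' @param d Observed standardized mean difference.
#' @param n1,n2 Group sizes.
#' @param conf_level Confidence level in (0, 1), default 0.95.
#' @return A list with `d`, `ci_low`, `ci_high`, `conf_level`, `n1`, `n2`.
#' @examples
#' smd_confidence_interval(0.89, 30, 30)
#' @export
smd_confidence_interval <- function(d, n1, n2, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1, n1 >= 2, n2 >= 2)
  scale <- sqrt(n1 * n2 / (n1 + n2))
  tobs <- d * scale
  df <- n1 + n2 - 2
  alpha <- (1 - conf_level) / 2
  # ncp at which the observed t has tail probability q
  ncp_at <- function(q) {
    f <- function(ncp) suppressWarnings(stats::pt(tobs, df, ncp)) - q
    lo <- tobs - 12 - 6 * abs(tobs)
    hi <- tobs + 12 + 6 * abs(tobs)
    out <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-9), error = function(e) e)
    if (inherits(out, "error")) {
      stop("noncentrality root finding failed (t = ", signif(tobs, 4),
           ", df = ", df, "): ", conditionMessage(out))
    }
    out$root
  }
  list(d = d, ci_low = ncp_at(1 - alpha) / scale, ci_high = ncp_at(alpha) / scale,
       conf_level = conf_level, n1 = n1, n2 = n2)
}
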