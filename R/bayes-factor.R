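#' Bayes factor for an independent-samples t test under a Cauchy prior
#'
#' Computes BF10 for the two-sample design from the t statistic: the marginal
#' likelihood of t under a Cauchy(location, scale) prior on the standardized
#' effect size delta — optionally truncated to one side and renormalized —
#' divided by the likelihood under the point null delta = 0. Given delta, the
#' t statistic has a noncentral-t distribution with noncentrality
#' delta * sqrt(n1 n2 / (n1 + n2)) and df = n1 + n2 - 2, so
#'
#'   BF10 = integral dt(t; df, delta * ne) pi(delta) d delta / dt(t; df, 0).
#'
#' `location = 0, scale = 0.707` is the default (JZS-style) prior;
#' `location = 0.5, scale = 0.5` is the informed prior used for directed
#' expertise hypotheses. `side = "positive"` restricts the prior to delta > 0
#' (e.g. superiority of experts when t is coded control minus expert).
#'
#' The integral is evaluated by adaptive quadrature ([stats::integrate()])
#' with the reported absolute error propagated into `numerical_error`.
#'
#' @param t Observed t statistic.
#' @param n1,n2 Group sizes.
#' @param prior_location Cauchy prior location on the delta scale.
#' @param prior_scale Cauchy prior scale (r); 0.707 is the conventional
#'   default width.
#' @param side `"two_sided"`, `"positive"` or `"negative"` prior truncation.
#' @return An object of class `bf_result`: `bf10`, `bf01`, `prior_location`,
#'   `prior_scale`, `side`, `numerical_error` (absolute, on the BF10 scale).
#' @examples
#' jzs_bayes_factor(3.46, 30, 30, side = "positive")
#' @export
jzs_bayes_factor <- function(t, n1, n2, prior_location = 0,
                             prior_scale = 0.707,
                             side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  stopifnot(prior_scale > 0, n1 >= 2, n2 >= 2)
  ne <- sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2

  dens <- function(delta) {
    suppressWarnings(stats::dt(t, df, ncp = delta * ne)) *
      stats::dcauchy(delta, prior_location, prior_scale)
  }
  bounds <- switch(side,
                   two_sided = c(-Inf, Inf),
                   positive = c(0, Inf),
                   negative = c(-Inf, 0))
  mass <- switch(side,
                 two_sided = 1,
                 positive = 1 - stats::pcauchy(0, prior_location, prior_scale),
                 negative = stats::pcauchy(0, prior_location, prior_scale))
  quad <- tryCatch(
    stats::integrate(Vectorize(dens), bounds[1], bounds[2],
                     rel.tol = 1e-10, abs.tol = 1e-12, subdivisions = 500L),
    error = function(e) stop("Bayes factor quadrature failed: ",
                             conditionMessage(e)))
  null_dens <- stats::dt(t, df)
  bf10 <- quad$value / mass / null_dens
  structure(list(bf10 = bf10, bf01 = 1 / bf10,
                 prior_location = prior_location, prior_scale = prior_scale,
                 side = side,
                 numerical_error = quad$abs.error / mass / null_dens),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (BF01 = %.4g)  Cauchy(%g, %g), %s  [quad err %.2g]\n",
              x$bf10, x$bf01, x$prior_location, x$prior_scale, x$side,
              x$numerical_error))
  invisible(x)
}

#' Bayes factor robustness over prior widths
#'
#' Recomputes [jzs_bayes_factor()] for a sweep of Cauchy scales at location 0,
#' the standard check that the grade of evidence does not hinge on the prior
#' width.
#'
#' @inheritParams jzs_bayes_factor
#' @param scales Numeric vector of Cauchy scales to sweep.
#' @return A data frame with columns `prior_scale`, `bf10`, `bf01`.
#' @export
bf_robustness <- function(t, n1, n2, scales = c(0.5, 0.707, 1.0),
                          side = c("two_sided", "positive", "negative")) {
  side <- match.arg(side)
  if (!length(scales)) stop("scales must be non-empty")
  res <- lapply(scales, function(s)
    jzs_bayes_factor(t, n1, n2, prior_location = 0, prior_scale = s, side = side))
  data.frame(prior_scale = scales,
             bf10 = vapply(res, `[[`, numeric(1), "bf10"),
             bf01 = vapply(res, `[[`, numeric(1), "bf01"))
}
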