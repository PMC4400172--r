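#' Quadratic long-term trend of a rate channel
#'
#' Ordinary least squares of the per-bin count on standardized linear
#' and quadratic time: attention that rises from the event onset and
#' falls toward its end appears as a positive linear and a negative
#' quadratic coefficient.  Time is centred before squaring and both
#' predictors (and the response) are z-scored, which tames the `t`/`t^2`
#' collinearity and puts the betas on the standardized scale.
#'
#' The result also carries the decay-only check of
#' [second_half_decay_test()], which asks whether the falling limb of
#' the quadratic is present in the second half of the event on its own.
#'
#' @param series A [rate_series()].
#' @param channel Channel label (default `"total"`).
#' @return An object of class `trend_fit`: `beta_linear`,
#'   `beta_quadratic`, `t_linear`, `t_quadratic`, `p_linear`,
#'   `p_quadratic`, `r2`, `second_half` (list `beta`, `t`, `p`),
#'   `n_obs`, and the `lm` object in `$model`.
#' @export
fit_quadratic_trend <- function(series, channel = "total") {
  stopifnot(inherits(series, "rate_series"))
  if (!channel %in% names(series$channels))
    stop("unknown channel: ", channel)
  y <- as.numeric(series$channels[[channel]])
  if (length(y) < 3L) stop("need at least 3 bins to fit a quadratic")
  t <- bin_times(series)
  tc <- t - mean(t)
  x1 <- zscore(tc)
  x2 <- zscore(tc^2)
  yz <- zscore(y)
  fit <- stats::lm(yz ~ x1 + x2)
  sm <- stats::coef(summary(fit))
  structure(list(
    beta_linear = sm["x1", "Estimate"],
    beta_quadratic = sm["x2", "Estimate"],
    t_linear = sm["x1", "t value"],
    t_quadratic = sm["x2", "t value"],
    p_linear = sm["x1", "Pr(>|t|)"],
    p_quadratic = sm["x2", "Pr(>|t|)"],
    r2 = summary(fit)$r.squared,
    second_half = second_half_decay_test(series, channel),
    n_obs = length(y),
    model = fit), class = "trend_fit")
}

#' Decay-only test on the second half of an event
#'
#' Restricted to bins in the second half of the series — where an
#' inverted-U trend has only its falling limb — the count is regressed
#' on the centred quadratic term alone (centred about the full-series
#' midpoint, with an intercept).  A significantly negative coefficient
#' indicates that the late decay is present independently of the early
#' rise.
#'
#' @param series A [rate_series()].
#' @param channel Channel label.
#' @return List with standardized `beta`, `t`, `p` and `n_obs`.
#' @export
second_half_decay_test <- function(series, channel = "total") {
  stopifnot(inherits(series, "rate_series"))
  if (!channel %in% names(series$channels))
    stop("unknown channel: ", channel)
  if (series$n_bins < 4L) stop("need at least 4 bins")
  t <- bin_times(series)
  mid <- series$t0_s + series$n_bins * series$bin_width_s / 2
  sel <- t >= mid
  y <- as.numeric(series$channels[[channel]][sel])
  q <- (t[sel] - mean(t))^2
  fit <- stats::lm(zscore(y) ~ zscore(q))
  sm <- stats::coef(summary(fit))
  list(beta = sm[2L, "Estimate"], t = sm[2L, "t value"],
       p = sm[2L, "Pr(>|t|)"], n_obs = sum(sel))
}

#' @method print trend_fit
#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Quadratic long-term trend (n = %d bins)\n", x$n_obs))
  cat(sprintf("  linear:    beta = %+.3f, t = %+.2f, p = %.3g\n",
              x$beta_linear, x$t_linear, x$p_linear))
  cat(sprintf("  quadratic: beta = %+.3f, t = %+.2f, p = %.3g\n",
              x$beta_quadratic, x$t_quadratic, x$p_quadratic))
  cat(sprintf("  R2 = %.3f\n", x$r2))
  cat(sprintf("  second-half decay alone: beta = %+.3f, t = %+.2f, p = %.3g\n",
              x$second_half$beta, x$second_half$t, x$second_half$p))
  invisible(x)
}

#' @export
coef.trend_fit <- function(object, ...) {
  c(linear = object$beta_linear, quadratic = object$beta_quadratic)
}
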