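#' Novelty decay component of the salient-event model
#'
#' `N(t) = exp(-lambda t)`: the falling salience of a remark after its
#' onset.
#'
#' @param t Seconds since event onset (vectorised).
#' @param lambda Decay rate, 1/s (>= 0).
#' @return Dimensionless values in (0, 1].
#' @export
novelty <- function(t, lambda) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda < 0)
    stop("lambda must be a single nonnegative number")
  exp(-lambda * t)
}

#' Adoption sigmoid component of the salient-event model
#'
#' `M(t) = 1 / (1 + exp(-m (t - s)))`: the self-sustaining uptake of a
#' remark as a meme.  `s` is the time (seconds) at which the rate is
#' increasing maximally and `m` the slope of that rise.  Computed via
#' the logistic CDF, which is numerically stable for large `|m(t-s)|`.
#'
#' @param t Seconds since event onset (vectorised).
#' @param m Sigmoid slope, 1/s.
#' @param s Sigmoid midpoint, seconds.
#' @return Values in (0, 1).
#' @export
meme_sigmoid <- function(t, m, s) {
  stats::plogis(m * (t - s))
}

#' Salient-event model parameters
#'
#' @param lambda Novelty decay rate, 1/s (>= 0).
#' @param m Sigmoid slope, 1/s (>= 0).
#' @param s Sigmoid midpoint, seconds.
#' @param b Base rate, in the units of the fitted series.
#' @return An object of class `meme_params`.
#' @export
meme_params <- function(lambda, m, s, b) {
  if (lambda < 0 || m < 0) stop("lambda and m must be nonnegative")
  structure(list(lambda = lambda, m = m, s = s, b = b),
            class = "meme_params")
}

#' Composite salient-event (meme) model
#'
#' `M(t) [N(t) - b]`, the product of the adoption sigmoid and the
#' novelty decay net of the base rate `b`.  As written the model tends
#' to `-b` as `t` grows; since the model is fitted by maximising a
#' Pearson correlation, which is invariant to positive affine maps,
#' this offset is immaterial to fitting.
#'
#' @param t Seconds since event onset (vectorised).
#' @param params A [meme_params()].
#' @return Model values (same length as `t`).
#' @export
meme_composite <- function(t, params) {
  stopifnot(inherits(params, "meme_params"))
  meme_sigmoid(t, params$m, params$s) *
    (novelty(t, params$lambda) - params$b)
}

#' Base rate from the tail of a series
#'
#' The stable sustained rate after the initial burst has decayed: the
#' mean of the final `tail_s` seconds of a channel.
#'
#' @param series A [rate_series()].
#' @param channel Channel label.
#' @param tail_s Length of the tail in seconds (default 100).
#' @return Mean rate over the tail, in counts per bin.
#' @export
estimate_base_rate <- function(series, channel, tail_s = 100) {
  stopifnot(inherits(series, "rate_series"))
  if (!channel %in% names(series$channels))
    stop("unknown channel: ", channel)
  n_tail <- as.integer(round(tail_s / series$bin_width_s))
  if (n_tail < 1L || n_tail > series$n_bins)
    stop("series shorter than the requested tail of ", tail_s, " s")
  mean(utils::tail(series$channels[[channel]], n_tail))
}

#' Parameter grid for the salient-event fit
#'
#' The defaults span "reasonable ranges" for events whose burst decays
#' over minutes: decay rates between 1e-4 and 0.1 /s (half-lives of
#' about two hours down to seven seconds, log-spaced), sigmoid slopes
#' between 0.01 and 1 /s (log-spaced), and midpoints between 0 and
#' 300 s (5-s steps).
#'
#' @param lambda,m,s Numeric vectors of candidate values.
#' @return An object of class `meme_grid`.
#' @export
meme_grid <- function(lambda = 10^seq(-4, -1, length.out = 25),
                      m = 10^seq(-2, 0, length.out = 25),
                      s = seq(0, 300, length.out = 61)) {
  if (any(lambda < 0) || any(m < 0)) stop("lambda and m must be nonnegative")
  structure(list(lambda = sort(lambda), m = sort(m), s = sort(s)),
            class = "meme_grid")
}

cor_with_centered <- function(comp, yc, ss_y) {
  n <- length(yc)
  num <- as.vector(crossprod(comp, yc))
  css <- colSums(comp^2) - n * colMeans(comp)^2
  r <- num / sqrt(css * ss_y)
  r[!is.finite(r)] <- -Inf
  r
}

#' Fit the salient-event model by correlation-maximising search
#'
#' Evaluates the Pearson correlation between the composite model
#' [meme_composite()] and the observed channel over an exhaustive
#' `lambda x m x s` grid and returns the maximiser, optionally followed
#' by a local Nelder–Mead refinement started at the grid optimum (kept
#' only if it strictly improves the correlation).  Exact ties on the
#' grid are broken toward the smallest `lambda`, then the smallest `s`,
#' then the smallest `m`.
#'
#' Because the objective is a correlation, the fit is invariant to
#' positive affine transformations of the observed series; in
#' particular max-scaled and raw counts give identical fits.
#'
#' @param series A [rate_series()] whose time base is seconds from the
#'   salient-event onset (e.g. from [event_locked_window()]).
#' @param channel Channel label to fit.
#' @param grid A [meme_grid()].
#' @param b Base rate; estimated from the final 100 s of the series via
#'   [estimate_base_rate()] when `NULL`.
#' @param window_s Fit window: only bins with centre time in
#'   `[0, window_s)` enter the objective (default 600 s, the span over
#'   which such bursts typically fade).
#' @param refine Run the local refinement after the grid search?
#' @return An object of class `meme_fit`: `params` ([meme_params()]),
#'   `r`, `r2`, `grid`, `n_evaluations`, `n_obs`, `refined`,
#'   `window_s`.
#' @export
fit_meme <- function(series, channel, grid = meme_grid(), b = NULL,
                     window_s = 600, refine = TRUE) {
  stopifnot(inherits(series, "rate_series"), inherits(grid, "meme_grid"))
  if (!channel %in% names(series$channels))
    stop("unknown channel: ", channel)
  if (is.null(b)) b <- estimate_base_rate(series, channel)
  t_all <- bin_times(series)
  sel <- t_all >= 0 & t_all < window_s
  t <- t_all[sel]
  y <- as.numeric(series$channels[[channel]][sel])
  if (length(y) < 3L) stop("fewer than 3 bins in the fit window")
  if (stats::sd(y) == 0)
    stop("constant observed series: correlation is undefined")
  yc <- y - mean(y)
  ss_y <- sum(yc^2)

  ns <- length(grid$s); nm <- length(grid$m)
  sm <- expand.grid(s = grid$s, m = grid$m)  # s varies fastest
  M <- stats::plogis(outer(t, sm$s, "-") *
                       rep(sm$m, each = length(t)))
  best <- list(r = -Inf, lambda = NA, m = NA, s = NA)
  for (lam in grid$lambda) {
    nb <- exp(-lam * t) - b
    comp <- M * nb  # recycles nb down each column
    r <- cor_with_centered(comp, yc, ss_y)
    rmax <- max(r)
    if (rmax > best$r) {
      cand <- which(r == rmax)
      # ties: smallest s, then smallest m (lambda fixed in this pass;
      # across passes the first/smallest lambda reaching rmax wins)
      ord <- cand[order(sm$s[cand], sm$m[cand])][1L]
      best <- list(r = rmax, lambda = lam, m = sm$m[ord], s = sm$s[ord])
    }
  }
  if (!is.finite(best$r))
    stop("no grid point produced a non-constant model")
  refined <- FALSE
  if (refine) {
    obj <- function(p) {
      lam <- exp(p[1L]); mm <- exp(p[2L]); ss <- p[3L]
      comp <- stats::plogis(mm * (t - ss)) * (exp(-lam * t) - b)
      cs <- sum((comp - mean(comp))^2)
      if (!is.finite(cs) || cs == 0) return(1e10)
      -sum(comp * yc) / sqrt(cs * ss_y)
    }
    start <- c(log(max(best$lambda, 1e-12)), log(max(best$m, 1e-12)), best$s)
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (-opt$value > best$r) {
      best <- list(r = -opt$value, lambda = exp(opt$par[1L]),
                   m = exp(opt$par[2L]), s = opt$par[3L])
      refined <- TRUE
    }
  }
  structure(list(params = meme_params(best$lambda, best$m, best$s, b),
                 r = best$r, r2 = best$r^2, grid = grid,
                 n_evaluations = length(grid$lambda) * nm * ns,
                 n_obs = length(y), window_s = window_s,
                 refined = refined),
            class = "meme_fit")
}

#' @method print meme_fit
#' @export
print.meme_fit <- function(x, ...) {
  p <- x$params
  cat("Salient-event (decay x sigmoid) fit\n")
  cat(sprintf("  lambda = %.4g /s, m = %.4g /s, s = %.4g s, b = %.4g\n",
              p$lambda, p$m, p$s, p$b))
  cat(sprintf("  r = %.4f (R2 = %.4f) on %d bins; %d grid evaluations%s\n",
              x$r, x$r2, x$n_obs, x$n_evaluations,
              if (x$refined) " + local refinement" else ""))
  invisible(x)
}

#' @export
coef.meme_fit <- function(object, ...) {
  with(object$params, c(lambda = lambda, m = m, s = s, b = b))
}

#' @export
predict.meme_fit <- function(object, t, ...) {
  meme_composite(t, object$params)
}

#' @export
plot.meme_fit <- function(x, series, channel, ...) {
  t <- bin_times(series)
  sel <- t >= 0 & t < x$window_s
  y <- series$channels[[channel]][sel]
  graphics::plot(t[sel], y, type = "h", col = "grey70",
                 xlab = "time from event onset (s)",
                 ylab = "messages / bin", ...)
  mod <- predict(x, t[sel])
  # display on the data scale via the affine map implied by the fit
  fitd <- stats::lm.fit(cbind(1, mod), y)$fitted.values
  graphics::lines(t[sel], fitd, col = "red", lwd = 2)
  invisible(x)
}
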