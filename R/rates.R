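#' Per-second rate series aligned to an event
#'
#' A `rate_series` holds integer message counts per time bin for one or
#' more channels (one per target term, plus a `"total"` channel that
#' counts each message once however many terms it matches).  Bins are
#' half-open intervals `[k, k+1) * bin_width_s` seconds from the
#' alignment origin `t0_s`.
#'
#' @param channels Named list of equal-length non-negative integer
#'   count vectors.
#' @param t0_s Time of the left edge of the first bin, seconds relative
#'   to the alignment origin (0 for a series aligned to event onset).
#' @param bin_width_s Bin width in seconds.
#' @param n_dropped Number of messages that fell outside the event
#'   window and were dropped during binning.
#' @return An object of class `rate_series`.
#' @export
rate_series <- function(channels, t0_s = 0, bin_width_s = 1, n_dropped = 0L) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  lens <- vapply(channels, length, integer(1L))
  if (length(unique(lens)) != 1L)
    stop("all channels must have the same number of bins")
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  channels <- lapply(channels, function(x) {
    if (any(x < 0 | !is.finite(x))) stop("counts must be finite and >= 0")
    x
  })
  structure(list(t0_s = as.numeric(t0_s),
                 bin_width_s = as.numeric(bin_width_s),
                 n_bins = unname(lens[1L]),
                 channels = channels,
                 n_dropped = as.integer(n_dropped)),
            class = "rate_series")
}

#' @method print rate_series
#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("Rate series: %d bins of %g s from t0 = %g s\n",
              x$n_bins, x$bin_width_s, x$t0_s))
  for (ch in names(x$channels))
    cat(sprintf("  %-12s sum %g, peak %g\n", ch,
                sum(x$channels[[ch]]), max(x$channels[[ch]])))
  if (x$n_dropped > 0)
    cat(sprintf("  (%d out-of-window messages dropped)\n", x$n_dropped))
  invisible(x)
}

#' Bin-center times of a rate series
#'
#' @param series A [rate_series()].
#' @return Numeric vector of bin-center times in seconds.
#' @export
bin_times <- function(series) {
  series$t0_s + (seq_len(series$n_bins) - 0.5) * series$bin_width_s
}

#' @export
as.data.frame.rate_series <- function(x, ...) {
  t_s <- x$t0_s + (seq_len(x$n_bins) - 1L) * x$bin_width_s
  do.call(rbind, lapply(names(x$channels), function(ch)
    data.frame(t_s = t_s, channel = ch, count = x$channels[[ch]])))
}

#' @export
plot.rate_series <- function(x, channels = names(x$channels), ...) {
  t_s <- bin_times(x)
  ymax <- max(vapply(x$channels[channels], max, numeric(1L)))
  graphics::plot(NA, xlim = range(t_s), ylim = c(0, ymax),
                 xlab = "time from onset (s)", ylab = "messages / bin", ...)
  for (i in seq_along(channels))
    graphics::lines(t_s, x$channels[[channels[i]]], col = i)
  graphics::legend("topright", legend = channels, col = seq_along(channels),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Align filtered messages to event onset and bin into per-second counts
#'
#' A message at absolute time `tau` lands in bin
#' `floor((tau - onset_timestamp) / bin_width_s)` (half-open bins,
#' 0-based from onset).  Messages outside `[0, duration_s)` are dropped
#' and counted in the series' drop log.  The `"total"` channel is the
#' union of the per-term matches, counted once per message.
#'
#' @param filtered Named list of per-term message data frames as
#'   returned by [filter_messages()].
#' @param annotation A [debate_annotation()] supplying the onset
#'   timestamp and duration.
#' @param bin_width_s Bin width in seconds (default 1).
#' @return A [rate_series()] with one channel per term plus `"total"`.
#' @export
align_and_bin <- function(filtered, annotation, bin_width_s = 1) {
  stopifnot(inherits(annotation, "debate_annotation"))
  if (bin_width_s <= 0) stop("bin_width_s must be positive")
  if (annotation$duration_s <= 0) stop("annotation duration must be positive")
  n_bins <- as.integer(ceiling(annotation$duration_s / bin_width_s))
  bin_of <- function(ts) {
    off <- ts - annotation$onset_timestamp
    b <- floor(off / bin_width_s) + 1L
    b[off < 0 | off >= annotation$duration_s] <- NA_integer_
    b
  }
  channels <- lapply(filtered, function(df) {
    b <- bin_of(df$timestamp)
    tabulate(b[!is.na(b)], nbins = n_bins)
  })
  # total: each distinct message once, however many term channels matched
  all_rows <- do.call(rbind, lapply(filtered, function(df)
    df[c(".idx", "timestamp")]))
  if (is.null(all_rows) || !nrow(all_rows)) {
    channels$total <- integer(n_bins)
    n_dropped <- 0L
  } else {
    uniq <- all_rows[!duplicated(all_rows$.idx), , drop = FALSE]
    b <- bin_of(uniq$timestamp)
    channels$total <- tabulate(b[!is.na(b)], nbins = n_bins)
    n_dropped <- sum(is.na(b))
  }
  rate_series(channels, t0_s = 0, bin_width_s = bin_width_s,
              n_dropped = n_dropped)
}

#' Per-bin proportion of mentions of one term relative to two terms
#'
#' The share of attention one principal receives: per bin,
#' `a / (a + b)` after optional moving-average smoothing of both
#' channels.  Bins where `a + b = 0` (after smoothing) are `NA`; missing
#' values are propagated, never zero-filled.
#'
#' @param series A [rate_series()].
#' @param term_a,term_b Channel labels.
#' @param smooth_bins Width of a centred moving average applied to both
#'   channels before the ratio (0 or 1 = no smoothing).
#' @return Numeric vector of length `n_bins` with values in \[0, 1\] or
#'   `NA`.
#' @export
mention_proportion <- function(series, term_a, term_b, smooth_bins = 0L) {
  stopifnot(inherits(series, "rate_series"))
  for (ch in c(term_a, term_b))
    if (!ch %in% names(series$channels)) stop("unknown channel: ", ch)
  a <- as.numeric(series$channels[[term_a]])
  b <- as.numeric(series$channels[[term_b]])
  if (smooth_bins > 1L) {
    k <- rep(1 / smooth_bins, smooth_bins)
    a <- as.numeric(stats::filter(a, k, sides = 2))
    b <- as.numeric(stats::filter(b, k, sides = 2))
  }
  denom <- a + b
  out <- a / denom
  out[!is.na(denom) & denom == 0] <- NA_real_
  out
}

#' Extract an event-locked window from a rate series
#'
#' Re-origins the series at a salient-event onset, keeping
#' `[onset - pre_s, onset + post_s)`.  With `max_scale` each channel is
#' divided by its in-window maximum, giving unit-peak profiles that can
#' be compared across events of very different raw magnitude.
#'
#' @param series A [rate_series()].
#' @param onset_s Event onset, seconds on the series' time base.
#' @param pre_s,post_s Seconds to keep before/after the onset.
#' @param max_scale Divide each channel by its window maximum?
#' @return A [rate_series()] with `t0_s = -pre_s` relative to the
#'   onset (counts become numeric when `max_scale`).
#' @export
event_locked_window <- function(series, onset_s, pre_s = 0, post_s = 600,
                                max_scale = FALSE) {
  stopifnot(inherits(series, "rate_series"))
  bw <- series$bin_width_s
  from <- floor((onset_s - series$t0_s - pre_s) / bw) + 1L
  to <- ceiling((onset_s - series$t0_s + post_s) / bw)
  if (from < 1L || to > series$n_bins) {
    warning("window clipped to series extent")
    from <- max(from, 1L); to <- min(to, series$n_bins)
  }
  if (to < from) stop("empty event-locked window")
  channels <- lapply(series$channels, function(x) x[from:to])
  if (max_scale) {
    channels <- lapply(names(channels), function(ch) {
      m <- max(channels[[ch]])
      if (m == 0) stop("cannot max-scale channel with all-zero window: ", ch)
      channels[[ch]] / m
    })
    names(channels) <- names(series$channels)
  }
  rate_series(channels,
              t0_s = series$t0_s + (from - 1L) * bw - onset_s,
              bin_width_s = bw)
}

#' Latency from a salient-event onset to the first matching message
#'
#' @param messages A per-term message data frame (an element of the
#'   list from [filter_messages()]) or a named list of them.
#' @param annotation A [debate_annotation()] supplying the onset
#'   timestamp.
#' @param onset_s Salient-event onset, seconds from event onset.
#' @return Seconds from `onset_s` to the earliest matching message at
#'   or after it (`NA` if none); a named vector if `messages` is a
#'   list.
#' @export
first_latency <- function(messages, annotation, onset_s) {
  if (is.data.frame(messages)) {
    off <- messages$timestamp - annotation$onset_timestamp - onset_s
    off <- off[off >= 0]
    return(if (length(off)) min(off) else NA_real_)
  }
  vapply(messages, first_latency, numeric(1L),
         annotation = annotation, onset_s = onset_s)
}

#' Latency to peak rate within a series
#'
#' Bin-center time of the first bin attaining the channel maximum
#' (earliest bin wins ties).
#'
#' @param series A [rate_series()] (typically an event-locked window).
#' @param channel Channel label.
#' @return Bin-center time in seconds on the series' time base, or
#'   `NA` for an all-zero channel.
#' @export
peak_latency <- function(series, channel) {
  stopifnot(inherits(series, "rate_series"))
  if (!channel %in% names(series$channels))
    stop("unknown channel: ", channel)
  x <- series$channels[[channel]]
  if (!length(x)) stop("empty channel: ", channel)
  if (all(x == 0)) return(NA_real_)
  bin_times(series)[which.max(x)]
}

#' Write a rate series as a tidy CSV
#'
#' Long format with columns `t_s` (bin left edge), `channel`, `count`.
#'
#' @param series A [rate_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rates <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}
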