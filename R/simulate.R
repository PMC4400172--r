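#' Configuration for a synthetic debate timeline
#'
#' Defaults emulate a televised 90-minute two-candidate debate with a
#' moderator: about 200 turns of mean length 25 s with a heavy-tailed
#' (log-normal) duration distribution, roughly half of them initiated
#' as interruptions.
#'
#' @param duration_s Event duration in seconds.
#' @param mean_turn_s Mean turn duration in seconds.
#' @param turn_sd_log Log-scale SD of the log-normal turn duration.
#' @param p_interrupt Probability a turn starts as an interruption
#'   (overlapping the previous turn by up to 2 s).
#' @param p_moderator Probability a turn belongs to the moderator.
#' @param speakers Labels of the two principals.
#' @param moderator Moderator label.
#' @param seed Integer RNG seed; the generated timeline is a
#'   deterministic function of the config.
#' @return An object of class `debate_config`.
#' @export
debate_config <- function(duration_s = 5400, mean_turn_s = 25,
                          turn_sd_log = 0.9, p_interrupt = 0.54,
                          p_moderator = 0.25,
                          speakers = c("candidate_a", "candidate_b"),
                          moderator = "moderator", seed = 1L) {
  stopifnot(duration_s > 0, mean_turn_s > 0, turn_sd_log >= 0,
            p_interrupt >= 0, p_interrupt <= 1,
            p_moderator >= 0, p_moderator <= 1,
            length(speakers) == 2L)
  structure(list(duration_s = duration_s, mean_turn_s = mean_turn_s,
                 turn_sd_log = turn_sd_log, p_interrupt = p_interrupt,
                 p_moderator = p_moderator, speakers = speakers,
                 moderator = moderator, seed = as.integer(seed)),
            class = "debate_config")
}

#' One salient-event kernel of the generative model
#'
#' @param onset_s Kernel onset, seconds from event onset.
#' @param lambda Novelty decay rate, 1/s.
#' @param m Adoption sigmoid slope, 1/s.
#' @param s Adoption sigmoid midpoint, seconds after onset.
#' @param amplitude Log-rate boost multiplying the kernel shape
#'   `M(t) N(t)` (dimensionless; the per-second log rate gains
#'   `amplitude * M * N` while the kernel is active).
#' @param term Lowercase match term injected into message texts while
#'   the kernel is active, so the filter and fit stages can isolate it.
#' @param window_s Seconds after onset during which the kernel is
#'   active and texts carry `term`.
#' @return A list describing the kernel.
#' @export
meme_kernel <- function(onset_s, lambda = 0.01, m = 0.2, s = 60,
                        amplitude = 1, term = "keyword", window_s = 600) {
  stopifnot(onset_s >= 0, lambda >= 0, m >= 0, window_s > 0)
  list(onset_s = onset_s, lambda = lambda, m = m, s = s,
       amplitude = amplitude, term = tolower(term), window_s = window_s)
}

#' Ground truth of the generative message-stream model
#'
#' Per second `t` and principal channel `c`, the generator draws
#' `count ~ Poisson(rate_c(t))` with
#' `log rate_c(t) = base + [floor = c] log(speaker_boost)
#'   + speaking-time slopes + [interrupting turn] log(interruption_boost)
#'   + quad_lin x + quad_quad x^2 + sum of active kernels`,
#' where `x = t / duration` is normalised event time.  Counts are
#' Poisson with a log link on purpose: the analysis models are Gaussian
#' linear approximations of realistic integer data, as in the field's
#' practice, and recovery tolerances account for that mismatch.
#'
#' Kernel-induced messages are drawn separately: per second each
#' channel draws its kernel-free count at `exp(log rate - kernel term)`
#' and the kernel-attributed excess at the difference of the two rates,
#' and only the excess messages carry the kernel's match term.  The
#' term channel recovered by filtering therefore follows the kernel's
#' burst-decay shape (messages about the remark mention the remark),
#' while the total stream still follows the full log-linear rate.
#'
#' Defaults are anchored to the descriptive statistics of televised
#' debate streams: about half of all messages are retweets, a speaking
#' candidate draws ~1.5x the mentions, and overall attention rises then
#' decays over the event.  The base rate of 10 messages/s per channel
#' is a deliberately scaled-down sample of a full firehose-style feed,
#' chosen so that the share of per-second variance the systematic
#' effects explain is comparable to what full-scale streams show
#' (roughly half); scaling the rate further down would leave the same
#' structure buried in Poisson noise.
#'
#' @param base_log_rate Log messages/s per channel outside any effect.
#' @param speaker_boost Multiplicative rate factor on a candidate's own
#'   channel while he holds the floor.
#' @param speaking_time_slope Length-2 numeric `c(own, cross)`:
#'   per-second change in log rate of a candidate's channel while his
#'   own turn progresses (`own`) and while the opponent's turn
#'   progresses (`cross`).
#' @param interruption_boost Multiplicative factor on all channels
#'   while the floor-holding turn is an interruption.
#' @param quad_coeffs Length-2 numeric `(linear, quadratic)` on
#'   normalised time `x = t / duration` in the log total rate.
#' @param meme_kernels List of [meme_kernel()]s.
#' @param retweet_fraction Fraction of messages flagged as retweets and
#'   prefixed `"RT @"`.
#' @param url_spam_rate Rate (messages/s) of appended URL-bearing spam
#'   messages, which the URL filter must remove.
#' @param seed Integer RNG seed for [generate_messages()].
#' @return An object of class `generative_truth`.
#' @export
generative_truth <- function(base_log_rate = log(10),
                             speaker_boost = 1.5,
                             speaking_time_slope = c(own = 0.004,
                                                     cross = -0.004),
                             interruption_boost = 1.5,
                             quad_coeffs = c(0.3, -0.5),
                             meme_kernels = list(meme_kernel(onset_s = 1800)),
                             retweet_fraction = 0.53,
                             url_spam_rate = 0.1,
                             seed = 1L) {
  stopifnot(speaker_boost > 0, interruption_boost > 0,
            length(speaking_time_slope) == 2L, length(quad_coeffs) == 2L,
            retweet_fraction >= 0, retweet_fraction <= 1,
            url_spam_rate >= 0)
  structure(list(base_log_rate = base_log_rate,
                 speaker_boost = speaker_boost,
                 speaking_time_slope = unname(speaking_time_slope),
                 interruption_boost = interruption_boost,
                 quad_coeffs = unname(quad_coeffs),
                 meme_kernels = meme_kernels,
                 retweet_fraction = retweet_fraction,
                 url_spam_rate = url_spam_rate,
                 seed = as.integer(seed)),
            class = "generative_truth")
}

#' Null generative truth (no effects)
#'
#' All effects off: constant base rate, no interruption or speaker
#' boosts, no trend, no kernels, no contaminants.  Used for type-I
#' error simulations.
#'
#' @param base_log_rate Log messages/s per channel.
#' @param seed Integer RNG seed.
#' @return A [generative_truth()] with every effect at its null value.
#' @export
null_truth <- function(base_log_rate = log(10), seed = 1L) {
  generative_truth(base_log_rate = base_log_rate, speaker_boost = 1,
                   speaking_time_slope = c(0, 0), interruption_boost = 1,
                   quad_coeffs = c(0, 0), meme_kernels = list(),
                   retweet_fraction = 0, url_spam_rate = 0, seed = seed)
}

#' Generate a synthetic debate timeline
#'
#' Alternating candidate turns with moderator interjections.  Turn
#' durations are log-normal with mean `mean_turn_s`; each non-initial
#' turn is an interruption with probability `p_interrupt`, in which
#' case it starts up to 2 s before the previous turn ends.  Salient
#' events matching the kernels of a [generative_truth()] can be
#' attached afterwards with [attach_salient_events()].
#'
#' @param config A [debate_config()].
#' @return A [debate_annotation()] (onset timestamp 0), a deterministic
#'   function of `config` (including its seed).
#' @export
generate_debate <- function(config) {
  stopifnot(inherits(config, "debate_config"))
  set.seed(config$seed)
  meanlog <- log(config$mean_turn_s) - config$turn_sd_log^2 / 2
  rows <- list()
  t <- 0
  ci <- 1L
  prev_start <- -Inf
  while (t < config$duration_s) {
    is_mod <- stats::runif(1) < config$p_moderator
    speaker <- if (is_mod) config$moderator else config$speakers[ci]
    if (!is_mod) ci <- 3L - ci
    dur <- max(stats::rlnorm(1, meanlog, config$turn_sd_log), 0.5)
    is_int <- length(rows) > 0L && stats::runif(1) < config$p_interrupt
    start <- if (is_int) {
      max(t - stats::runif(1, 0, 2), prev_start + 0.01)
    } else t
    if (start >= config$duration_s) break
    end <- min(start + dur, config$duration_s)
    if (end <= start) break
    rows[[length(rows) + 1L]] <- data.frame(
      speaker = speaker, start_s = start, end_s = end,
      is_interruption = is_int)
    prev_start <- start
    t <- end
  }
  debate_annotation(onset_timestamp = 0, duration_s = config$duration_s,
                    speakers = c(config$speakers, config$moderator),
                    moderator = config$moderator,
                    turns = do.call(rbind, rows))
}

#' Attach a truth's kernels to an annotation as salient events
#'
#' @param annotation A [debate_annotation()].
#' @param truth A [generative_truth()].
#' @return The annotation with one salient event per kernel.
#' @export
attach_salient_events <- function(annotation, truth) {
  if (!length(truth$meme_kernels)) return(annotation)
  ev <- data.frame(
    label = vapply(truth$meme_kernels, `[[`, character(1L), "term"),
    onset_s = vapply(truth$meme_kernels, `[[`, numeric(1L), "onset_s"))
  ev$match_terms <- lapply(truth$meme_kernels, function(k) k$term)
  debate_annotation(annotation$onset_timestamp, annotation$duration_s,
                    annotation$speakers, annotation$turns,
                    salient_events = ev, moderator = annotation$moderator)
}

#' Generate an entrained synthetic message stream
#'
#' Simulates per-second Poisson counts for each principal's mention
#' channel under the log-linear rate model of [generative_truth()],
#' places each message uniformly within its second, composes texts that
#' contain the channel's term (and any active kernel's term), flags a
#' `retweet_fraction` of messages as retweets, and appends URL-bearing
#' spam at `url_spam_rate` so that the exclusion filters are exercised.
#'
#' @param annotation A [debate_annotation()] with exactly two
#'   principals.
#' @param truth A [generative_truth()].
#' @return Message data frame (`timestamp`, `text`, `is_retweet`)
#'   sorted by timestamp; deterministic given `truth$seed`.
#' @export
generate_messages <- function(annotation, truth) {
  stopifnot(inherits(annotation, "debate_annotation"),
            inherits(truth, "generative_truth"))
  cands <- candidates(annotation)
  if (length(cands) != 2L)
    stop("generator requires exactly two principal speakers")
  set.seed(truth$seed)
  dur <- as.integer(floor(annotation$duration_s))
  secs <- seq_len(dur) - 1L
  fh <- floor_holder(annotation, secs)
  active <- !is.na(fh)
  sp <- rep(NA_character_, dur)
  st <- numeric(dur)
  int_now <- logical(dur)
  sp[active] <- annotation$turns$speaker[fh[active]]
  st[active] <- secs[active] - annotation$turns$start_s[fh[active]]
  int_now[active] <- annotation$turns$is_interruption[fh[active]]
  x <- secs / annotation$duration_s

  kernel_term <- function(k) {
    dt <- secs - k$onset_s
    on <- dt >= 0 & dt < k$window_s
    v <- numeric(dur)
    v[on] <- k$amplitude * stats::plogis(k$m * (dt[on] - k$s)) *
      exp(-k$lambda * dt[on])
    v
  }
  kernel_sum <- Reduce(`+`, lapply(truth$meme_kernels, kernel_term),
                       numeric(dur))

  all_msgs <- list()
  for (i in 1:2) {
    own <- !is.na(sp) & sp == cands[i]
    other <- !is.na(sp) & sp == cands[3L - i]
    lr <- truth$base_log_rate +
      own * log(truth$speaker_boost) +
      own * st * truth$speaking_time_slope[1L] +
      other * st * truth$speaking_time_slope[2L] +
      int_now * log(truth$interruption_boost) +
      truth$quad_coeffs[1L] * x + truth$quad_coeffs[2L] * x^2
    if (any(exp(lr + kernel_sum) > 1e6))
      stop("rate overflow (> 1e6 messages/s) at second ",
           secs[which(exp(lr + kernel_sum) > 1e6)[1L]])
    base_txt <- sprintf("talking about %s now", cands[i])
    # peel the kernels off one at a time so each excess message is
    # attributed to (and carries the term of) exactly one kernel
    rate_sofar <- exp(lr)
    sec_of <- rep(secs, stats::rpois(dur, rate_sofar))
    txt <- rep(base_txt, length(sec_of))
    for (k in truth$meme_kernels) {
      rate_next <- rate_sofar * exp(kernel_term(k))
      n_k <- stats::rpois(dur, rate_next - rate_sofar)
      sec_of <- c(sec_of, rep(secs, n_k))
      txt <- c(txt, rep(paste(base_txt, k$term), sum(n_k)))
      rate_sofar <- rate_next
    }
    if (length(sec_of)) {
      all_msgs[[i]] <- data.frame(
        timestamp = annotation$onset_timestamp + sec_of +
          stats::runif(length(sec_of)),
        text = txt, is_retweet = FALSE)
    }
  }
  msgs <- do.call(rbind, all_msgs)
  if (is.null(msgs))
    msgs <- data.frame(timestamp = numeric(), text = character(),
                       is_retweet = logical())
  if (nrow(msgs) && truth$retweet_fraction > 0) {
    rt <- stats::runif(nrow(msgs)) < truth$retweet_fraction
    msgs$text[rt] <- paste0("RT @user ", msgs$text[rt])
    msgs$is_retweet[rt] <- TRUE
  }
  if (truth$url_spam_rate > 0) {
    n_spam <- stats::rpois(dur, truth$url_spam_rate)
    sec_of <- rep(secs, n_spam)
    if (length(sec_of)) {
      spam <- data.frame(
        timestamp = annotation$onset_timestamp + sec_of +
          stats::runif(length(sec_of)),
        text = sprintf("great deal on %s merch http://spam.example",
                       sample(cands, length(sec_of), replace = TRUE)),
        is_retweet = FALSE)
      msgs <- rbind(msgs, spam)
    }
  }
  msgs <- msgs[order(msgs$timestamp), , drop = FALSE]
  rownames(msgs) <- NULL
  msgs
}

#' Serialise generative ground truth for recovery tests
#'
#' Produces a plain named list (JSON-ready) that round-trips through
#' `jsonlite` unchanged, so that a generated data set can be written to
#' disk alongside the truth that produced it.
#'
#' @param truth A [generative_truth()].
#' @return Named list mirroring the truth's fields.
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "generative_truth"))
  list(base_log_rate = truth$base_log_rate,
       speaker_boost = truth$speaker_boost,
       speaking_time_slope = truth$speaking_time_slope,
       interruption_boost = truth$interruption_boost,
       quad_coeffs = truth$quad_coeffs,
       meme_kernels = truth$meme_kernels,
       retweet_fraction = truth$retweet_fraction,
       url_spam_rate = truth$url_spam_rate,
       seed = truth$seed)
}

#' Simulate a complete synthetic event
#'
#' Convenience wrapper: timeline, salient events, and message stream in
#' one call.
#'
#' @param config A [debate_config()].
#' @param truth A [generative_truth()].
#' @return List with elements `annotation`, `messages`, `truth`.
#' @export
simulate_event <- function(config = debate_config(),
                           truth = generative_truth()) {
  ann <- attach_salient_events(generate_debate(config), truth)
  list(annotation = ann, messages = generate_messages(ann, truth),
       truth = truth)
}
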