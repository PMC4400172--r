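# Small hand-built fixtures shared across test files.

# 6-turn toy debate: two principals and a moderator, two interruptions
# (turn 5 overlaps turn 4, turn 6 overlaps turn 5), one salient event.
toy_annotation <- function(onset_timestamp = 1000) {
  turns <- data.frame(
    speaker = c("alpha", "bravo", "mod", "alpha", "bravo", "alpha"),
    start_s = c(0, 10, 20.5, 25, 34, 43.2),
    end_s = c(10, 20.5, 25, 35, 44, 50),
    is_interruption = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  ev <- data.frame(label = "zinger", onset_s = 30)
  ev$match_terms <- list("zing")
  debate_annotation(onset_timestamp = onset_timestamp, duration_s = 60,
                    speakers = c("alpha", "bravo", "mod"),
                    moderator = "mod", turns = turns, salient_events = ev)
}

make_messages <- function(offsets, texts, onset = 0, is_retweet = NULL) {
  if (is.null(is_retweet)) is_retweet <- startsWith(texts, "RT @")
  data.frame(timestamp = onset + offsets, text = texts,
             is_retweet = is_retweet)
}

make_series <- function(..., t0_s = 0, bin_width_s = 1) {
  rate_series(list(...), t0_s = t0_s, bin_width_s = bin_width_s)
}

# independent binning oracle: test every message against every bin
brute_bin <- function(timestamps, onset, duration, bw) {
  n <- as.integer(ceiling(duration / bw))
  counts <- integer(n)
  for (k in seq_len(n)) {
    lo <- onset + (k - 1) * bw
    hi <- onset + k * bw
    counts[k] <- sum(timestamps >= lo & timestamps < hi &
                       timestamps < onset + duration)
  }
  counts
}

# truth with a single focal effect switched on, everything else null
focused_truth <- function(seed, ...) {
  args <- list(...)
  base <- list(base_log_rate = log(10), speaker_boost = 1,
               speaking_time_slope = c(0, 0), interruption_boost = 1,
               quad_coeffs = c(0, 0), meme_kernels = list(),
               retweet_fraction = 0, url_spam_rate = 0, seed = seed)
  base[names(args)] <- args
  do.call(generative_truth, base)
}

# rate series for one candidate channel + total from a simulated event
sim_rates <- function(sim, extra_terms = character()) {
  spec <- filter_spec(c(candidates(sim$annotation), extra_terms))
  align_and_bin(filter_messages(sim$messages, spec), sim$annotation)
}
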