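test_that("filter assigns the hand-enumerated 4-message fixture exactly", {
  msgs <- make_messages(0:3, c("Obama wins", "RT @x Obama",
                               "Romney http://a.b", "obama & romney"))
  spec <- filter_spec(c("obama", "romney"))
  out <- filter_messages(msgs, spec)
  expect_equal(out$obama$text, c("Obama wins", "obama & romney"))
  expect_equal(out$romney$text, "obama & romney")

  # retweet exclusion off brings the retweet back under its term
  out2 <- filter_messages(msgs, filter_spec(c("obama", "romney"),
                                            exclude_retweets = FALSE))
  expect_equal(out2$obama$text,
               c("Obama wins", "RT @x Obama", "obama & romney"))

  # hashtags match by substring; www. counts as a URL
  out3 <- filter_messages(
    make_messages(0:1, c("go #obama2012!", "vote obama www.x.com")),
    spec)
  expect_equal(out3$obama$text, "go #obama2012!")

  empty <- filter_messages(msgs[0, ], spec)
  expect_equal(vapply(empty, nrow, integer(1L)),
               c(obama = 0L, romney = 0L))
})

test_that("filtering an already-filtered stream changes nothing", {
  set.seed(42)
  sim <- simulate_event(
    debate_config(duration_s = 400, seed = 5),
    generative_truth(seed = 6,
                     meme_kernels = list(meme_kernel(onset_s = 150))))
  spec <- filter_spec(candidates(sim$annotation))
  once <- filter_messages(sim$messages, spec)
  surviving <- do.call(rbind, once)
  surviving <- surviving[!duplicated(surviving$.idx), ]
  twice <- filter_messages(surviving, spec)
  for (term in names(once)) {
    expect_setequal(twice[[term]]$.idx, once[[term]]$.idx)
  }
})

test_that("binning matches hand counts and the brute-force oracle", {
  ann <- debate_annotation(50, 5, c("a", "b"),
    data.frame(speaker = "a", start_s = 0, end_s = 5,
               is_interruption = FALSE))
  msgs <- make_messages(c(0.2, 0.9, 1.1), rep("a!", 3), onset = 50)
  rs <- align_and_bin(filter_messages(msgs, filter_spec("a")), ann)
  expect_equal(rs$channels$a, c(2L, 1L, 0L, 0L, 0L))
  expect_equal(rs$channels$total, rs$channels$a)

  # no messages -> all-zero channels of length ceil(duration/bin)
  rs0 <- align_and_bin(filter_messages(msgs[0, ], filter_spec("a")), ann)
  expect_equal(rs0$channels$a, integer(5))

  # property: agreement with the per-bin brute force across random streams
  for (seed in 1:3) {
    set.seed(seed)
    ts <- 50 + stats::runif(200, -1, 7)  # includes out-of-window times
    msgs <- make_messages(ts - 50, rep("a b", 200), onset = 50)
    fl <- filter_messages(msgs, filter_spec(c("a", "b")))
    rs <- align_and_bin(fl, ann, bin_width_s = 1)
    expect_equal(rs$channels$a, brute_bin(fl$a$timestamp, 50, 5, 1))
    expect_equal(rs$channels$total, brute_bin(ts, 50, 5, 1))
    # conservation: channel sums equal in-window filtered counts
    inwin <- fl$a$timestamp >= 50 & fl$a$timestamp < 55
    expect_equal(sum(rs$channels$a), sum(inwin))
  }
})

test_that("channel sums are conserved on full synthetic streams", {
  for (seed in c(2, 9)) {
    sim <- simulate_event(
      debate_config(duration_s = 600, seed = seed),
      generative_truth(seed = seed + 100,
                       meme_kernels = list(meme_kernel(onset_s = 200))))
    spec <- filter_spec(c(candidates(sim$annotation), "keyword"))
    fl <- filter_messages(sim$messages, spec)
    rs <- align_and_bin(fl, sim$annotation)
    onset <- sim$annotation$onset_timestamp
    for (term in names(fl)) {
      inwin <- fl[[term]]$timestamp >= onset &
        fl[[term]]$timestamp < onset + sim$annotation$duration_s
      expect_equal(sum(rs$channels[[term]]), sum(inwin))
    }
    uni <- do.call(rbind, fl)
    uni <- uni[!duplicated(uni$.idx), ]
    expect_equal(sum(rs$channels$total),
                 sum(uni$timestamp >= onset &
                       uni$timestamp < onset + sim$annotation$duration_s))
  }
})

test_that("mention proportion handles symmetry, dominance and smoothing", {
  rs <- make_series(a = c(2L, 0L), b = c(2L, 0L), total = c(4L, 0L))
  expect_equal(mention_proportion(rs, "a", "b"), c(0.5, NA))
  rs2 <- make_series(a = c(3L, 1L), b = c(0L, 0L), total = c(3L, 1L))
  expect_equal(mention_proportion(rs2, "a", "b"), c(1, 1))
  expect_error(mention_proportion(rs, "a", "zz"), "unknown channel")

  # 3:1 generative rate ratio -> mean proportion ~ 0.75
  set.seed(7)
  a <- stats::rpois(2000, 3)
  b <- stats::rpois(2000, 1)
  rs3 <- make_series(a = a, b = b, total = a + b)
  p <- mention_proportion(rs3, "a", "b")
  expect_lt(abs(mean(p, na.rm = TRUE) - 0.75), 0.03)
  # smoothing fills isolated empty bins from neighbours
  p_sm <- mention_proportion(rs3, "a", "b", smooth_bins = 5)
  expect_lt(sum(is.na(p_sm)), sum(is.na(p)) + 5)
})

test_that("event-locked windows slice, rescale and guard degenerate cases", {
  x <- c(rep(0L, 100), 5L, 3L, 2L, 1L, rep(1L, 6))
  rs <- make_series(a = x, total = x)
  w <- event_locked_window(rs, onset_s = 100, pre_s = 0, post_s = 10)
  expect_equal(w$n_bins, 10L)
  expect_equal(w$t0_s, 0)
  expect_equal(w$channels$a, c(5L, 3L, 2L, 1L, rep(1L, 6)))

  const <- make_series(a = rep(2L, 20), total = rep(2L, 20))
  wc <- event_locked_window(const, 5, 0, 10, max_scale = TRUE)
  expect_equal(wc$channels$a, rep(1, 10))

  # max-scaling never moves the argmax
  ws <- event_locked_window(rs, 100, 0, 10, max_scale = TRUE)
  expect_equal(which.max(ws$channels$a), which.max(w$channels$a))

  zero <- make_series(a = integer(20), total = integer(20))
  expect_error(event_locked_window(zero, 5, 0, 10, max_scale = TRUE),
               "all-zero")
  expect_warning(event_locked_window(rs, 105, pre_s = 0, post_s = 100),
                 "clipped")
})

test_that("first and peak latencies follow their tie and missing rules", {
  ann <- toy_annotation()
  msgs <- make_messages(c(34, 72, 20), rep("zing", 3),
                        onset = ann$onset_timestamp)
  fl <- filter_messages(msgs, filter_spec("zing"))
  expect_equal(first_latency(fl$zing, ann, onset_s = 30), 4)
  expect_equal(first_latency(fl, ann, onset_s = 30), c(zing = 4))
  expect_true(is.na(first_latency(fl$zing[0, ], ann, 30)))

  rs <- make_series(a = c(1L, 3L, 3L, 1L), total = c(1L, 3L, 3L, 1L))
  expect_equal(peak_latency(rs, "a"), 1.5)  # first maximal bin's centre
  mono <- make_series(a = 1:5, total = 1:5)
  expect_equal(peak_latency(mono, "a"), 4.5)
  expect_true(is.na(peak_latency(make_series(a = integer(3),
                                             total = integer(3)), "a")))
})

test_that("rate tables are written as tidy CSV", {
  rs <- make_series(a = c(1L, 2L), total = c(1L, 2L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_rates(rs, f)
  back <- utils::read.csv(f)
  expect_equal(names(back), c("t_s", "channel", "count"))
  expect_equal(back$count[back$channel == "a"], c(1L, 2L))
})
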