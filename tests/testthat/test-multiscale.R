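ms_fixture <- function(seed = 1, with_salient = TRUE, scale_from = NULL,
                       cfg_seed = 200) {
  kern <- if (with_salient)
    list(meme_kernel(onset_s = 1000, term = "zing")) else list()
  tr <- generative_truth(seed = seed, meme_kernels = kern,
                         retweet_fraction = 0, url_spam_rate = 0)
  sim <- simulate_event(debate_config(duration_s = 2400, seed = cfg_seed),
                        tr)
  rs <- sim_rates(sim, extra_terms = if (with_salient) "zing")
  fits <- NULL
  if (with_salient) {
    w <- event_locked_window(rs, onset_s = 1000, post_s = 700)
    fits <- list(zing = fit_meme(w, "zing"))
  }
  design <- build_multiscale_design(sim$annotation, rs, meme_fits = fits,
                                    scale_from = scale_from)
  list(sim = sim, rs = rs, design = design)
}

test_that("the design has one row per second and definitional columns", {
  fx <- ms_fixture()
  d <- fx$design
  expect_equal(nrow(d), fx$rs$n_bins)
  expect_true(all(c("t_lin", "t_quad", "speak_time", "cand_a",
                    "interrupt", "salient") %in% names(d)))
  # interaction columns are elementwise products of their parents
  expect_equal(d$speak_time_x_interrupt, d$speak_time * d$interrupt)
  expect_equal(d$t_lin_x_salient, d$t_lin * d$salient)
  # salient block absent when no fits are supplied
  d0 <- ms_fixture(with_salient = FALSE)$design
  expect_false("salient" %in% names(d0))
  expect_false("salient" %in% names(attr(d0, "blocks")))
})

test_that("unique variance matches the exhaustive leave-one-block-out oracle", {
  # 4-block toy design assembled by hand
  set.seed(18)
  n <- 200
  d <- data.frame(t_lin = stats::rnorm(n), t_quad = stats::rnorm(n),
                  speak_time = stats::rnorm(n), cand_a = stats::rbinom(n, 1, 0.4),
                  interrupt = stats::rbinom(n, 1, 0.3),
                  salient = stats::rnorm(n))
  d$count_total <- 2 + d$t_lin - 0.5 * d$t_quad + 0.8 * d$speak_time +
    0.6 * d$interrupt + 1.2 * d$salient + stats::rnorm(n)
  blocks <- list(quadratic = c("t_lin", "t_quad"),
                 speaker_duration = c("speak_time", "cand_a"),
                 interruption = "interrupt", salient = "salient")
  design <- structure(d, blocks = blocks, scale_stats = list(),
                      class = c("multiscale_design", "data.frame"))
  preds <- setdiff(names(d), "count_total")
  r2_of <- function(cols) {
    f <- stats::as.formula(paste("count_total ~",
                                 paste(cols, collapse = " + ")))
    summary(stats::lm(f, data = d))$r.squared
  }
  for (b in names(blocks)) {
    oracle <- r2_of(preds) - r2_of(setdiff(preds, blocks[[b]]))
    expect_equal(unique_variance(design, b), oracle, tolerance = 1e-8)
    expect_gte(unique_variance(design, b), -1e-12)
  }
  expect_error(unique_variance(design, "nope"), "unknown block")

  # orthogonal block: unique variance equals its marginal R2
  d2 <- d
  qrX <- qr.Q(qr(cbind(1, as.matrix(d[setdiff(preds, "salient")]))))
  d2$salient <- stats::rnorm(n)
  d2$salient <- d2$salient - qrX %*% crossprod(qrX, d2$salient)
  d2$count_total <- d$count_total
  design2 <- structure(d2, blocks = blocks, scale_stats = list(),
                       class = c("multiscale_design", "data.frame"))
  marg <- summary(stats::lm(count_total ~ salient, data = d2))$r.squared
  expect_equal(unique_variance(design2, "salient"), marg,
               tolerance = 1e-8)
})

test_that("full fit nests sub-models and handles duplicated columns", {
  fx <- ms_fixture()
  fit <- fit_multiscale(fx$design)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
  # nesting: every block's unique variance is within [0, R2]
  expect_true(all(fit$unique_r2 >= -1e-10))
  expect_true(all(fit$unique_r2 <= fit$r2 + 1e-10))
  expect_lte(sum(fit$unique_r2), fit$r2 + 1e-8)
  # the full model beats the quadratic-only model
  r2_quad <- summary(stats::lm(count_total ~ t_lin + t_quad,
                               data = as.data.frame(fx$design)))$r.squared
  expect_gt(fit$r2, r2_quad)

  # duplicating a predictor leaves fitted values unchanged
  dup <- fx$design
  dup$speak_time2 <- dup$speak_time
  dup <- dup[c(setdiff(names(dup), "count_total"), "count_total")]
  attr(dup, "blocks") <- attr(fx$design, "blocks")
  attr(dup, "scale_stats") <- attr(fx$design, "scale_stats")
  class(dup) <- class(fx$design)
  fit_dup <- fit_multiscale(dup)
  expect_equal(length(fit_dup$dropped), 1L)
  expect_equal(unname(stats::fitted(fit_dup$model)),
               unname(stats::fitted(fit$model)), tolerance = 1e-10)
})

test_that("pure-noise response gives R2 near its chance expectation", {
  fx <- ms_fixture(with_salient = FALSE)
  d <- fx$design
  set.seed(19)
  d$count_total <- stats::rnorm(nrow(d))
  fit <- fit_multiscale(d)
  k <- length(fit$schema)
  expect_lt(fit$r2, 3 * k / nrow(d))
})

test_that("transfer self-prediction equals the square root of R2", {
  fx <- ms_fixture(with_salient = FALSE)
  fit <- fit_multiscale(fx$design)
  expect_equal(transfer_predict(fit, fx$design), sqrt(fit$r2),
               tolerance = 1e-10)
})

test_that("transfer to a paired event with shared truth is predictive", {
  fx1 <- ms_fixture(seed = 301, with_salient = FALSE, cfg_seed = 300)
  fit <- fit_multiscale(fx1$design)
  fx2 <- ms_fixture(seed = 311, with_salient = FALSE, cfg_seed = 310,
                    scale_from = fx1$design)
  r <- transfer_predict(fit, fx2$design)
  expect_gt(r, 0.3)
})

test_that("schema and salient-block mismatches are errors", {
  fx <- ms_fixture()
  fit_sal <- fit_multiscale(fx$design)
  d0 <- ms_fixture(with_salient = FALSE)$design
  expect_error(transfer_predict(fit_sal, d0), "without a salient block")
  fit0 <- fit_multiscale(d0)
  expect_error(transfer_predict(fit0, fx$design),
               "without a salient block")
  d_bad <- d0
  d_bad$t_quad <- NULL
  attr(d_bad, "blocks") <- attr(d0, "blocks")
  class(d_bad) <- class(d0)
  expect_error(predict(fit0, d_bad), "schema")
})
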