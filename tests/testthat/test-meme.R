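test_that("kernel components obey their analytic identities", {
  expect_equal(novelty(0, 0.3), 1)
  expect_equal(novelty(0:10, 0), rep(1, 11))
  expect_equal(novelty(1, log(2)), 0.5)
  expect_error(novelty(1, -0.1), "nonnegative")

  expect_equal(meme_sigmoid(60, 0.2, 60), 0.5)
  expect_equal(meme_sigmoid(log(3), 1, 0), 0.75)
  # step limit and numerical stability at extreme arguments
  expect_equal(meme_sigmoid(c(-1, 1), 1e6, 0), c(0, 1))
  expect_false(any(is.nan(meme_sigmoid(c(-1e5, 1e5), 50, 0))))

  p <- meme_params(0, 100, 0, 0)
  expect_equal(meme_composite(10, p), novelty(10, 0), tolerance = 1e-12)
  p2 <- meme_params(0.05, 0.2, 30, 0.2)
  expect_equal(meme_composite(1e6, p2), -0.2)  # printed-form asymptote
  expect_equal(meme_composite(60, meme_params(0, 0.2, 60, 0)), 0.5)
  expect_error(meme_params(-1, 1, 0, 0), "nonnegative")
})

test_that("base rate is the mean of the series tail", {
  rs <- make_series(a = rep(3, 300), total = rep(3, 300))
  expect_equal(estimate_base_rate(rs, "a"), 3)
  x <- c(rep(5, 200), rep(0, 99), 100)
  rs2 <- make_series(a = x, total = x)
  expect_equal(estimate_base_rate(rs2, "a"), 1)
  expect_equal(estimate_base_rate(rs2, "a", tail_s = 300), mean(x))
  expect_error(estimate_base_rate(rs2, "a", tail_s = 301), "shorter")
})

truth_series <- function(params, n = 900, noise_sd = 0, seed = 1,
                         offset = 2) {
  set.seed(seed)
  t <- seq_len(n) - 0.5
  y <- meme_composite(t, params) + offset
  if (noise_sd > 0) y <- y + stats::rnorm(n, sd = noise_sd)
  y <- pmax(y, 0)
  make_series(a = y, total = y)
}

test_that("a grid containing the truth is recovered exactly, r = 1", {
  p <- meme_params(0.01, 0.2, 60, 0.1)
  rs <- truth_series(p, offset = 2)
  g <- meme_grid(lambda = c(0.005, 0.01, 0.02), m = c(0.1, 0.2, 0.4),
                 s = c(50, 60, 70))
  fit <- fit_meme(rs, "a", grid = g, b = 0.1, refine = FALSE)
  expect_equal(coef(fit)[c("lambda", "m", "s")],
               c(lambda = 0.01, m = 0.2, s = 60))
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$n_evaluations, 27L)
  # local refinement cannot improve a perfect grid fit away from truth
  fit2 <- fit_meme(rs, "a", grid = g, b = 0.1, refine = TRUE)
  expect_equal(coef(fit2), coef(fit))
})

test_that("the fit is exactly invariant to positive affine transforms", {
  p <- meme_params(0.008, 0.15, 80, 0.1)
  rs <- truth_series(p, noise_sd = 0.02, seed = 4)
  rs_aff <- rate_series(list(a = 3 * rs$channels$a + 7,
                             total = 3 * rs$channels$total + 7))
  f1 <- fit_meme(rs, "a", b = 0.1)
  f2 <- fit_meme(rs_aff, "a", b = 0.1)
  expect_identical(coef(f1), coef(f2))
  expect_equal(f1$r, f2$r, tolerance = 1e-12)
  # max-scaling (a special case of the same invariance) changes nothing
  mx <- max(rs$channels$a)
  rs_mx <- rate_series(list(a = rs$channels$a / mx,
                            total = rs$channels$total / mx))
  f3 <- fit_meme(rs_mx, "a", b = 0.1)
  expect_identical(coef(f1)[c("lambda", "m", "s")],
                   coef(f3)[c("lambda", "m", "s")])
})

test_that("ties break toward the smallest lambda, then smallest s", {
  # constant-zero lambda row: with m huge the model is ~ a step at s;
  # duplicate lambdas produce literal ties resolved by ordering
  p <- meme_params(0.01, 0.2, 60, 0)
  rs <- truth_series(p, offset = 2)
  g <- meme_grid(lambda = c(0.01, 0.01), m = c(0.2, 0.2), s = c(60, 60))
  fit <- fit_meme(rs, "a", grid = g, b = 0, refine = FALSE)
  expect_equal(unname(coef(fit)[["lambda"]]), 0.01)
})

test_that("widening the grid never decreases the achieved correlation", {
  p <- meme_params(0.02, 0.3, 45, 0.1)
  rs <- truth_series(p, noise_sd = 0.03, seed = 5)
  narrow <- meme_grid(lambda = c(1e-3, 1e-2), m = c(0.05, 0.5),
                      s = c(0, 100, 200))
  wide <- meme_grid(lambda = c(1e-3, 1e-2, 2e-2, 5e-2),
                    m = c(0.05, 0.3, 0.5), s = c(0, 45, 100, 200))
  f_n <- fit_meme(rs, "a", grid = narrow, b = 0.1, refine = FALSE)
  f_w <- fit_meme(rs, "a", grid = wide, b = 0.1, refine = FALSE)
  expect_gte(f_w$r, f_n$r)
})

test_that("grid search is competitive with a random-restart optimizer", {
  set.seed(33)
  g <- meme_grid(lambda = 10^seq(-4, -1, length.out = 13),
                 m = 10^seq(-2, 0, length.out = 13),
                 s = seq(0, 300, length.out = 31))
  for (i in 1:5) {
    p <- meme_params(stats::runif(1, 0.002, 0.05),
                     stats::runif(1, 0.05, 0.5),
                     stats::runif(1, 20, 150), 0.1)
    rs <- truth_series(p, n = 500, noise_sd = 0.02, seed = 100 + i)
    fit <- fit_meme(rs, "a", grid = g, b = 0.1, refine = FALSE)
    # independent route: Nelder-Mead from random starts
    t <- seq_len(500) - 0.5
    y <- rs$channels$a
    obj <- function(par) {
      comp <- meme_composite(t, meme_params(exp(par[1]), exp(par[2]),
                                            par[3], 0.1))
      if (stats::sd(comp) == 0) return(1e10)
      -stats::cor(comp, y)
    }
    best <- -Inf
    for (j in 1:6) {
      st <- c(log(stats::runif(1, 1e-4, 0.1)),
              log(stats::runif(1, 0.01, 1)), stats::runif(1, 0, 300))
      o <- stats::optim(st, obj, method = "Nelder-Mead",
                        control = list(maxit = 400))
      best <- max(best, -o$value)
    }
    expect_gte(fit$r, best - 0.02)
  }
})

test_that("degenerate inputs are rejected", {
  flat <- make_series(a = rep(2, 700), total = rep(2, 700))
  expect_error(fit_meme(flat, "a", b = 0.1), "constant")
  expect_error(fit_meme(truth_series(meme_params(0.01, 0.2, 60, 0.1)),
                        "nope", b = 0.1), "unknown channel")
})
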