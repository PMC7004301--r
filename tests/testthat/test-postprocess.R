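# posterior summarization: HPD intervals, rates through time, shift
# frequencies, Bayes factors

test_that("HPD interval matches an exhaustive window search", {
  expect_equal(hpd_interval(rep(3.5, 10)), c(3.5, 3.5))
  expect_error(hpd_interval(numeric(0)), "samples")

  set.seed(4)
  x <- rgamma(200, 2, 1)  # skewed, so HPD differs from quantiles
  got <- hpd_interval(x, 0.95)
  xs <- sort(x)
  m <- ceiling(0.95 * 200)
  widths <- xs[m:200] - xs[1:(200 - m + 1)]
  i <- which.min(widths)
  expect_equal(got, c(xs[i], xs[i + m - 1]))
})

test_that("HPD of normal samples approximates the central interval", {
  set.seed(5)
  h <- rowMeans(replicate(5, hpd_interval(rnorm(1e5), 0.95)))
  expect_lt(abs(h[1] - (-1.959964)), 0.05)
  expect_lt(abs(h[2] - 1.959964), 0.05)
})

test_that("rtt summaries pool, degenerate, and stay flat as appropriate", {
  one <- fake_log("0.25", "", "0.1", "")
  s1 <- rtt_summary(one, grid = c(8, 5, 2), burn_in = 0)
  expect_equal(s1$lam_mean, rep(0.25, 3))
  expect_equal(s1$lam_lo, s1$lam_hi)  # degenerate HPD from one sample
  expect_equal(s1$r_mean, rep(0.15, 3))

  # pooling two identical logs changes nothing
  two <- fake_log(c("0.25", "0.3"), c("", ""), c("0.1", "0.1"), c("", ""))
  a <- rtt_summary(two, grid = c(8, 2), burn_in = 0)
  b <- rtt_summary(list(two, two), grid = c(8, 2), burn_in = 0)
  expect_equal(a, b)

  # piecewise sample evaluated on the grid
  pw <- fake_log("0.4;0.1", "5", "0.1", "")
  s2 <- rtt_summary(pw, grid = c(8, 3), burn_in = 0)
  expect_equal(s2$lam_mean, c(0.4, 0.1))
  expect_equal(s2$r_mean, c(0.3, 0))

  # mean within HPD bounds at every grid point
  fx <- make_fixture("constant_rates", seed = 3)
  log <- run_chain(fx$data, mode = "range", n_iter = 5000,
                   sample_every = 50, seed = 2)
  s3 <- rtt_summary(log, burn_in = 0.1)
  expect_true(all(s3$lam_lo <= s3$lam_mean + 1e-12))
  expect_true(all(s3$lam_mean <= s3$lam_hi + 1e-12))
})

test_that("summaries are invariant to splitting a log into pieces", {
  fx <- make_fixture("constant_rates", seed = 3)
  log <- run_chain(fx$data, mode = "range", n_iter = 4000,
                   sample_every = 40, seed = 2)
  half1 <- log; half1$samples <- log$samples[1:50, ]
  half2 <- log; half2$samples <- log$samples[51:100, ]
  whole <- rtt_summary(log, grid = c(20, 10, 5), burn_in = 0)
  split <- rtt_summary(list(half1, half2), grid = c(20, 10, 5), burn_in = 0)
  expect_equal(whole, split)
  sf_whole <- shift_frequency(log, burn_in = 0)
  sf_split <- shift_frequency(list(half1, half2), burn_in = 0)
  expect_equal(sf_whole, sf_split)
})

test_that("shift frequencies count at-least-one-shift bins", {
  none <- fake_log(c("0.2", "0.2"), c("", ""), c("0.1", "0.1"), c("", ""))
  sf <- shift_frequency(none, burn_in = 0)
  expect_true(all(sf$freq == 0))

  always <- fake_log(c("0.2;0.1", "0.3;0.2"), c("4.5", "4.2"),
                     c("0.1", "0.1"), c("", ""))
  sf2 <- shift_frequency(always, burn_in = 0)
  expect_equal(sf2$freq[sf2$old == 5], 1)  # bin (4, 5] holds both shifts
  expect_equal(sum(sf2$freq), 1)
  # row order of the log is irrelevant
  flipped <- fake_log(c("0.3;0.2", "0.2;0.1"), c("4.2", "4.5"),
                      c("0.1", "0.1"), c("", ""))
  expect_equal(shift_frequency(flipped, burn_in = 0), sf2)
})

test_that("prior shift frequency matches the Poisson thinning closed form", {
  pri <- bd_priors(shift_rate = 2)
  set.seed(6)
  pf <- prior_shift_frequency(pri, window = c(10, 0), bin_width = 1,
                              n_sim = 2e4)
  expected <- 1 - exp(-2 * 1 / 10)
  se <- sqrt(expected * (1 - expected) / 2e4)
  expect_true(all(abs(pf$freq - expected) < 3.5 * se))
  # equal-width bins have equal frequencies up to MC error
  expect_lt(diff(range(pf$freq)), 7 * se)

  pf0 <- prior_shift_frequency(bd_priors(shift_rate = 0), c(10, 0),
                               n_sim = 1e4)
  expect_true(all(pf0$freq == 0))
})

test_that("per-bin Bayes factors compare posterior to prior odds", {
  post <- data.frame(old = 5, young = 4, mid = 4.5, freq = 0.5)
  attr(post, "n_samples") <- 1e4
  prior <- data.frame(old = 5, young = 4, mid = 4.5, freq = 0.1)
  attr(prior, "n_samples") <- 1e4
  bf <- bayes_factor_bins(post, prior)
  expect_equal(bf$two_log_bf, 2 * (log(1) - log(1 / 9)), tolerance = 1e-12)
  expect_equal(bf$two_log_bf, 4.394, tolerance = 1e-3)
  expect_equal(bf$support, "positive")

  # equal frequencies give 0; monotone in the posterior frequency
  eq <- post; eq$freq <- 0.1
  expect_equal(bayes_factor_bins(eq, prior)$two_log_bf, 0)
  fs <- seq(0.05, 0.95, by = 0.1)
  vals <- vapply(fs, function(f) {
    p <- post; p$freq <- f; attr(p, "n_samples") <- 1e4
    bayes_factor_bins(p, prior)$two_log_bf
  }, numeric(1))
  expect_true(all(diff(vals) > 0))

  # extreme frequencies are clamped, never infinite
  ext <- post; ext$freq <- 1; attr(ext, "n_samples") <- 1e4
  expect_true(is.finite(bayes_factor_bins(ext, prior)$two_log_bf))
})
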