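# forward simulators and named fixtures

test_that("degenerate birth-death settings reproduce the founders", {
  w <- c(12, 0)
  tiny <- 1e-12  # rates must be positive; effectively zero events
  set.seed(1)
  sim <- simulate_bd(rate_model(tiny, window = w),
                     rate_model(tiny, window = w), n0 = 7)
  expect_equal(nrow(sim), 7)
  expect_true(all(sim$t_start == 12))
  expect_true(all(sim$t_end == 0))
  expect_true(all(sim$extant))
})

test_that("pure-birth simulation matches the Yule expectation", {
  lam <- 0.15; T_len <- 5; n0 <- 3
  w <- c(T_len, 0)
  set.seed(2)
  finals <- replicate(5000, sum(simulate_bd(
    rate_model(lam, window = w), rate_model(1e-12, window = w),
    n0 = n0)$extant))
  expected <- n0 * exp(lam * T_len)
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - expected), 3 * se)
})

test_that("pure-death simulation matches exponential survival", {
  mu <- 0.2; T_len <- 6; n0 <- 2000
  w <- c(T_len, 0)
  set.seed(3)
  sim <- simulate_bd(rate_model(1e-12, window = w),
                     rate_model(mu, window = w), n0 = n0)
  p_die <- 1 - exp(-mu * T_len)
  se <- sqrt(p_die * (1 - p_die) / n0)
  expect_lt(abs(mean(!sim$extant) - p_die), 3 * se)
})

test_that("two-regime simulation honors the piecewise rates", {
  w <- c(40, 0)
  set.seed(8)
  sim <- simulate_bd(rate_model(c(0.3, 0.05), 20, w),
                     rate_model(0.1, window = w), n0 = 10)
  st <- sufficient_stats(sim, w, shift_times = 20)
  expect_lt(abs(st$B[1] / st$S[1] - 0.3) / 0.3, 0.25)
  expect_lt(abs(st$B[2] / st$S[2] - 0.05) / 0.05, 0.35)
})

test_that("HPP preservation keeps the zero-truncated Poisson mean", {
  qs <- 5  # expected occurrences per retained lineage before truncation
  ranges <- lineage_ranges(sprintf("l%04d", 1:4000), rep(6, 4000),
                           rep(1, 4000), rep(FALSE, 4000))
  set.seed(4)
  occ <- simulate_preservation(ranges, "HPP", q = qs / 5)
  k <- vapply(ages_by_lineage(occ), length, integer(1))
  ztp_mean <- qs / (1 - exp(-qs))
  expect_lt(abs(mean(k) - ztp_mean), 3 * sd(k) / sqrt(length(k)))
  # occurrences lie within the lifespans
  expect_true(all(occ$records$age >= 1 & occ$records$age <= 6))
})

test_that("NHPP occurrence positions follow the bell distribution", {
  ranges <- lineage_ranges(sprintf("l%03d", 1:500), rep(10, 500),
                           rep(0, 500), rep(FALSE, 500))
  set.seed(5)
  occ <- simulate_preservation(ranges, "NHPP", q = 20, shapes = c(2, 2))
  u <- (10 - occ$records$age) / 10
  breaks <- seq(0, 1, by = 0.1)
  obs <- table(cut(u, breaks))
  p <- diff(pbeta(breaks, 2, 2))
  expect_gt(chisq.test(obs, p = p)$p.value, 0.01)
})

test_that("high preservation rates leave no lineage unobserved", {
  ranges <- lineage_ranges(sprintf("l%03d", 1:200), rep(6, 200),
                           rep(1, 200), rep(FALSE, 200))
  set.seed(6)
  occ <- simulate_preservation(ranges, "HPP", q = 10)  # q*s = 50
  expect_length(attr(occ, "dropped"), 0)
})

test_that("radiocarbon noise inverts calibration on the identity curve", {
  cv <- identity_curve(4000, 6000, err = 0)
  occ <- one_lineage_occ(c(4800, 5200))
  set.seed(7)
  noised <- simulate_radiocarbon(occ, cv, err = 1e-9)
  expect_equal(noised$records$age, c(4800, 5200), tolerance = 1e-6)
  expect_true(all(noised$records$age_type == "c14"))

  # round trip: mean calibrated age over replicates matches the truth
  set.seed(8)
  means <- replicate(300, {
    nz <- simulate_radiocarbon(one_lineage_occ(5000), cv, err = 30)
    cd <- calibrate(nz$records$age, 30, cv)
    sum(cd$grid * cd$pmf)
  })
  expect_lt(abs(mean(means) - 5000), 3 * sd(means) / sqrt(300))

  set.seed(9); a <- simulate_radiocarbon(occ, cv, err = 20)$records$age
  set.seed(9); b <- simulate_radiocarbon(occ, cv, err = 20)$records$age
  expect_identical(a, b)
  far <- one_lineage_occ(9999)
  expect_error(simulate_radiocarbon(far, cv, err = 20), "span")
})

test_that("fixtures regenerate bit-identically and honor their specs", {
  a <- make_fixture("two_regime", seed = 13)
  b <- make_fixture("two_regime", seed = 13)
  expect_identical(a$data, b$data)
  expect_identical(a$truth, b$truth)

  neo <- make_fixture("neolithic_like", seed = 42)
  expect_length(neo$data$extant, 22)
  expect_equal(neo$mode, "occurrence")

  f <- withr::local_tempfile(fileext = ".yaml")
  write_truth(neo, f)
  back <- read_truth(f)
  expect_equal(back$q, neo$truth$q)
  expect_equal(back$window, neo$truth$window)
  expect_equal(back$ranges$t_start, neo$truth$ranges$t_start,
               tolerance = 1e-9)
})

test_that("preservation fitting recovers simulated rates across seeds", {
  devs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    ranges <- lineage_ranges(sprintf("l%02d", 1:25), runif(25, 5, 9),
                             runif(25, 0, 2), rep(FALSE, 25))
    occ <- simulate_preservation(ranges, "HPP", q = 4)
    keep <- names(ages_by_lineage(occ))
    fit <- fit_preservation_ml(
      occ, "HPP", ts = setNames(ranges$t_start, ranges$lineage_id)[keep],
      te = setNames(ranges$t_end, ranges$lineage_id)[keep])
    (fit$q - 4) / 4
  }, numeric(1))
  # mean relative deviation near zero, individual fits close
  expect_lt(abs(mean(devs)), 0.05)
  expect_lt(max(abs(devs)), 0.25)
})
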