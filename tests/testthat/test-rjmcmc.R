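# sampler mechanics: initialization, invariants, determinism, and
# light prior-recovery checks (the full-scale prior-recovery runs live
# in the acceptance tests)

test_that("initialization starts from the constant-rate model", {
  fx <- make_fixture("constant_rates", seed = 9)
  st <- init_state(fx$data, mode = "range")
  expect_length(st$lam$rates, 1)
  expect_length(st$mu$rates, 1)
  mle <- mle_constant_rates(sufficient_stats(fx$data, st$window))
  expect_equal(unname(st$lam$rates), max(unname(mle["lam"]), 1e-4))
  expect_equal(unname(st$mu$rates), max(unname(mle["mu"]), 1e-4))

  occ <- one_lineage_occ(c(4, 6))
  sto <- init_state(occ, mode = "occurrence")
  expect_gte(sto$ts[["lin1"]], 6)
  expect_lte(sto$te[["lin1"]], 4)
  expect_error(init_state(
    lineage_ranges(character(0), numeric(0), numeric(0), logical(0)),
    mode = "range"), "empty")
})

test_that("chains are bit-identical under a fixed seed", {
  fx <- make_fixture("constant_rates", seed = 9)
  a <- run_chain(fx$data, mode = "range", n_iter = 2000, sample_every = 50,
                 seed = 123)
  b <- run_chain(fx$data, mode = "range", n_iter = 2000, sample_every = 50,
                 seed = 123)
  expect_identical(a$samples, b$samples)
  c <- run_chain(fx$data, mode = "range", n_iter = 2000, sample_every = 50,
                 seed = 124)
  expect_false(identical(a$samples, c$samples))
})

test_that("sampled states respect structural invariants", {
  fx <- make_fixture("two_regime", seed = 9)
  log <- run_chain(fx$data, mode = "range", n_iter = 1e4, sample_every = 20,
                   seed = 5)
  s <- log$samples
  for (i in seq(1, nrow(s), by = 25)) {
    for (side in c("lam", "mu")) {
      rates <- as.numeric(strsplit(s[[paste0(side, "_rates")]][i], ";")[[1]])
      expect_true(all(rates > 0))
      expect_length(rates, s[[paste0(side, "_k")]][i])
      sh <- strsplit(s[[paste0(side, "_shifts")]][i], ";")[[1]]
      sh <- as.numeric(sh[nzchar(sh)])
      if (length(sh) > 1) expect_true(all(diff(sh) < 0))
      if (length(sh))
        expect_true(all(sh < log$window[1] & sh > log$window[2]))
    }
  }
})

test_that("cached likelihood matches a from-scratch recomputation", {
  fx <- make_fixture("constant_rates", seed = 2)
  expect_no_error(run_chain(fx$data, mode = "range", n_iter = 3e4,
                            sample_every = 1000, seed = 77, debug = TRUE))
  occ <- make_fixture("neolithic_like", seed = 42)
  expect_no_error(run_chain(occ$data, mode = "occurrence", n_iter = 2e4,
                            sample_every = 1000, seed = 78,
                            preservation = list(kind = "NHPP",
                                                shapes = c(2, 2),
                                                gamma = FALSE, n_cat = 4),
                            debug = TRUE))
})

test_that("occurrence-mode latent times stay within their bounds", {
  fx <- make_fixture("neolithic_like", seed = 42)
  log <- run_chain(fx$data, mode = "occurrence", n_iter = 5000,
                   sample_every = 50, seed = 6)
  ages <- ages_by_lineage(fx$data)
  max_occ <- vapply(ages, max, numeric(1))
  min_occ <- vapply(ages, min, numeric(1))
  extant <- fx$data$extant[names(ages)]
  for (i in seq_len(nrow(log$samples))) {
    ts <- as.numeric(strsplit(log$samples$ts[i], ";")[[1]])
    te <- as.numeric(strsplit(log$samples$te[i], ";")[[1]])
    expect_true(all(ts >= max_occ - 1e-9))
    expect_true(all(te <= min_occ + 1e-9))
    expect_true(all(te >= 0))
    expect_true(all(te[extant] == 0))
    expect_true(all(log$samples$q > 0))
  }
})

test_that("one-lineage occurrence fixture recovers its true times", {
  # truth: lifespan [1, 6] densely sampled; posterior ts should sit near
  # the oldest occurrence plus one expected gap
  set.seed(99)
  truth_ts <- 6; truth_te <- 1
  covered <- 0
  for (rep in 1:5) {
    ages <- runif(40, truth_te, truth_ts)
    occ <- one_lineage_occ(ages)
    log <- run_chain(occ, mode = "occurrence", n_iter = 2e4,
                     sample_every = 20, seed = 100 + rep,
                     window = c(10, 0))
    ts <- as.numeric(sapply(strsplit(log$samples$ts, ";"), `[`, 1))
    ts <- ts[-(1:200)]
    expect_lt(abs(mean(ts) - truth_ts), max(3 * sd(ts), 0.5))
    h <- hpd_interval(ts)
    covered <- covered + (truth_ts >= h[1] - 0.25 && truth_ts <= h[2] + 0.25)
  }
  expect_gte(covered, 4)
})

test_that("short prior-only runs approximate their priors", {
  fx <- make_fixture("constant_rates", seed = 2)
  pri <- bd_priors(shift_rate = 0.5, rate_rate_lam = 2, rate_rate_mu = 2)
  log <- run_chain(fx$data, priors = pri, mode = "range", n_iter = 1e5,
                   sample_every = 10, seed = 21, prior_only = TRUE,
                   move_weights = c(rates = 0.3, shift_time = 0.2,
                                    rj = 0.5))
  m <- c(log$samples$lam_k, log$samples$mu_k) - 1
  expect_lt(abs(mean(m) - 0.5), 0.05)
  rates <- unlist(lapply(strsplit(log$samples$lam_rates, ";"), as.numeric))
  expect_lt(abs(mean(rates) - 1.1 / 2), 0.05)  # gamma(1.1, 2) mean
})

test_that("improvement proposals with symmetric corrections are accepted", {
  # with a single permitted move type and a huge likelihood advantage,
  # the chain must move: run on strongly informative data and check the
  # rate mixes toward the MLE from a distant start
  set.seed(1)
  w <- c(20, 0)
  sim <- simulate_bd(rate_model(0.3, window = w),
                     rate_model(0.05, window = w), n0 = 50)
  log <- run_chain(sim, mode = "range", n_iter = 5000, sample_every = 50,
                   move_weights = c(rates = 1), seed = 3)
  lam_end <- as.numeric(tail(log$samples$lam_rates[log$samples$lam_k == 1],
                             50))
  expect_lt(abs(mean(lam_end) - 0.3), 0.05)
  expect_gt(log$acceptance[["rates"]], 0)
})
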