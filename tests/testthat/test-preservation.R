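# preservation likelihoods, gamma heterogeneity, ML fitting, AICc

test_that("HPP log-likelihood matches the conditioned closed form", {
  expect_equal(hpp_loglik(1, 1, 1), -1 - log(1 - exp(-1)), tolerance = 1e-12)
  expect_equal(hpp_loglik(1, 1, 1), -0.54132485, tolerance = 1e-7)

  # q -> 0 limit with k = 1: the single occurrence is uniform on the
  # lifespan, so the loglik tends to -log(s)
  s <- 3.7
  expect_equal(hpp_loglik(1, s, 1e-9), -log(s), tolerance = 1e-6)

  expect_error(hpp_loglik(0, 1, 1), "k")
  expect_error(hpp_loglik(1, 0, 1), "s > 0")
})

test_that("HPP count marginal recovers the zero-truncated Poisson", {
  # exp(loglik) is the density of k ordered occurrence times; the count
  # marginal multiplies by s^k / k! (integral of the ordered times over
  # the lifespan) and must sum to one over k >= 1
  q <- 0.8; s <- 4
  total <- sum(vapply(1:50, function(k)
    exp(hpp_loglik(k, s, q) + k * log(s) - lfactorial(k)), numeric(1)))
  expect_equal(total, 1, tolerance = 1e-10)
  # and each term equals the zero-truncated Poisson pmf
  k <- 3
  ztp <- dpois(k, q * s) / (1 - dpois(0, q * s))
  expect_equal(exp(hpp_loglik(k, s, q) + k * log(s) - lfactorial(k)), ztp,
               tolerance = 1e-12)
})

test_that("NHPP reduces to HPP at uniform shapes and is bell-symmetric", {
  set.seed(2)
  for (rep in 1:10) {
    ts <- runif(1, 5, 10); te <- runif(1, 0, 3)
    ages <- runif(7, te, ts)
    q <- runif(1, 0.5, 3)
    expect_equal(nhpp_loglik(ages, ts, te, q, 1, 1),
                 hpp_loglik(7, ts - te, q), tolerance = 1e-12)
    # symmetric shapes: reflection about the lifespan midpoint
    mid <- (ts + te) / 2
    expect_equal(nhpp_loglik(2 * mid - ages, ts, te, q, 2.5, 2.5),
                 nhpp_loglik(ages, ts, te, q, 2.5, 2.5), tolerance = 1e-10)
  }
  expect_error(nhpp_loglik(c(2, 11), 10, 1, 1), "outside")
})

test_that("NHPP matches numerical quadrature of its intensity", {
  ts <- 9; te <- 2; q <- 1.7; a <- 2; b <- 3.5
  ages <- c(8.2, 7.7, 5.1, 4.4, 3.3)
  s <- ts - te
  tt <- seq(te, ts, length.out = 1e5 + 1)
  qt <- function(t) q * dbeta((ts - t) / s, a, b)
  Lam <- sum((qt(tt)[-1] + qt(tt)[-length(tt)]) / 2) * (s / 1e5)
  oracle <- sum(log(qt(ages))) - Lam - log(1 - exp(-Lam))
  expect_equal(nhpp_loglik(ages, ts, te, q, a, b), oracle,
               tolerance = 1e-6)
})

test_that("TPP reduces to HPP and matches direct arithmetic", {
  ages <- c(8, 6, 3)
  expect_equal(tpp_loglik(ages, 9, 2, 1.3), hpp_loglik(3, 7, 1.3),
               tolerance = 1e-12)
  expect_equal(tpp_loglik(ages, 9, 2, c(1.3, 1.3), 5),
               hpp_loglik(3, 7, 1.3), tolerance = 1e-12)
  # 3-epoch direct evaluation
  qv <- c(0.5, 2, 1)
  eb <- c(7, 4)
  # lifespan [2, 9]: overlaps 2 (epoch 1), 3 (epoch 2), 2 (epoch 3)
  Lam <- 0.5 * 2 + 2 * 3 + 1 * 2
  # ages 8 -> epoch 1, 6 -> epoch 2, 3 -> epoch 3
  oracle <- log(0.5) + log(2) + log(1) - Lam - log(1 - exp(-Lam))
  expect_equal(tpp_loglik(ages, 9, 2, qv, eb), oracle, tolerance = 1e-10)
})

test_that("gamma heterogeneity discretization behaves", {
  expect_equal(gamma_categories(0.7, 1), 1)
  m <- gamma_categories(0.5, 4)
  expect_equal(mean(m), 1, tolerance = 1e-12)
  expect_true(all(diff(m) > 0))

  ll_fn <- function(mult) c(hpp_loglik(3, 2, 0.9 * mult),
                            hpp_loglik(5, 4, 0.9 * mult))
  # single category is exactly the homogeneous model
  expect_equal(gamma_mixture_loglik(ll_fn, 0.8, n_cat = 1), sum(ll_fn(1)))
  # huge shape collapses to homogeneity
  expect_equal(gamma_mixture_loglik(ll_fn, 1e6, 4), sum(ll_fn(1)),
               tolerance = 1e-4)
  # mixture bounded by the extreme categories per lineage
  m4 <- gamma_categories(0.8, 4)
  lo <- sum(pmin(ll_fn(m4[1]), ll_fn(m4[4])))
  hi <- sum(pmax(ll_fn(m4[1]), ll_fn(m4[4])))
  mix <- gamma_mixture_loglik(ll_fn, 0.8, 4)
  expect_gte(mix, lo)
  expect_lte(mix, hi)
})

test_that("ML fitting recovers the preservation rate", {
  set.seed(17)
  # lineage set at the scale of the occurrence workflow: 22 lineages,
  # preservation rate 80 occurrences per lineage per time unit
  ranges <- lineage_ranges(sprintf("l%02d", 1:22),
                           t_start = runif(22, 1.5, 3),
                           t_end = runif(22, 0, 1),
                           extant = rep(FALSE, 22))
  occ <- simulate_preservation(ranges, "HPP", q = 80)
  fit <- fit_preservation_ml(occ, "HPP",
                             ts = setNames(ranges$t_start,
                                           ranges$lineage_id),
                             te = setNames(ranges$t_end,
                                           ranges$lineage_id))
  expect_lt(abs(fit$q - 80) / 80, 0.1)
})

test_that("single-lineage HPP fit matches a grid search", {
  occ <- one_lineage_occ(c(1.2, 2.4, 3.1, 4.9, 5.5))
  ts <- c(lin1 = 6); te <- c(lin1 = 1)
  fit <- fit_preservation_ml(occ, "HPP", ts = ts, te = te)
  qs <- seq(0.05, 10, length.out = 1e4)
  ll <- vapply(qs, function(q) hpp_loglik(5, 5, q), numeric(1))
  expect_lt(abs(fit$q - qs[which.max(ll)]), diff(qs[1:2]))
})

test_that("HPP fit never beats NHPP fit on the same data (nesting)", {
  set.seed(23)
  ranges <- lineage_ranges(sprintf("l%02d", 1:10), runif(10, 6, 9),
                           runif(10, 0, 2), rep(FALSE, 10))
  occ <- simulate_preservation(ranges, "NHPP", q = 8, shapes = c(2, 2))
  ts <- setNames(ranges$t_start, ranges$lineage_id)
  te <- setNames(ranges$t_end, ranges$lineage_id)
  keep <- names(ages_by_lineage(occ))
  hpp <- fit_preservation_ml(occ, "HPP", ts = ts[keep], te = te[keep])
  nhpp <- fit_preservation_ml(occ, "NHPP", ts = ts[keep], te = te[keep],
                              estimate_shapes = TRUE)
  expect_lte(hpp$loglik, nhpp$loglik + 1e-6)
})

test_that("AICc arithmetic and limits", {
  expect_equal(aicc(-10, 2, 22), 20 + 4 + 12 / 19, tolerance = 1e-12)
  expect_equal(aicc(-10, 2, 22), 24.6316, tolerance = 1e-4)
  expect_equal(aicc(-7, 0, 22), 14)
  expect_equal(aicc(-10, 2, 1e9), -2 * -10 + 4, tolerance = 1e-6)
  expect_error(aicc(-10, 2, 3), "n")
})

test_that("model-selection reports rank by AICc with stable ties", {
  tied <- model_selection_report(
    data.frame(model = c("B", "A"), aicc = c(100, 100)))
  expect_equal(tied$daicc, c(0, 0))
  expect_equal(tied$model, c("A", "B"))  # tie broken by name

  close2 <- model_selection_report(
    data.frame(model = c("X", "Y"), aicc = c(50, 51)))
  expect_equal(close2$daicc, c(0, 1))
  expect_equal(close2$support, c("-", ""))  # dAICc 1 carries no flag

  expect_error(model_selection_report(list()), "2 fits")
})
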