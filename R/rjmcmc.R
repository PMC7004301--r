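# Reversible-jump MCMC over piecewise-constant birth-death models.
#
# Range mode ("LiteRate-style"): origination and extinction times are
# known; the chain samples the two rate models (number, placement, and
# values of their shifts). Occurrence mode ("PyRate-style"): origination
# and extinction times are latent, constrained by each lineage's oldest
# and youngest occurrence, and are jointly sampled together with the
# preservation rate.
#
# Priors: number of shifts per rate model ~ Poisson(shift_rate); shift
# times ~ uniform over the observation window (order statistics); each
# rate ~ Gamma(rate_shape, rate_rate); preservation rate q ~
# Exponential(q_rate); gamma-heterogeneity shape ~ Exponential(alpha_rate).
#
# The dimension-changing move splits an interval at a uniform time,
# perturbing the old rate symmetrically in log space with an auxiliary
# Gaussian variable (the reverse merge restores the length-weighted
# geometric-mean rate); the Jacobian and reverse-move densities enter the
# acceptance ratio. Correctness of the transdimensional bookkeeping is
# validated by sampling-the-prior tests (likelihood disabled, every
# marginal must match its prior).

#' Prior specification for the rate-shift sampler
#'
#' @param shift_rate Poisson prior mean on the number of rate shifts per
#'   rate model (default 0.5: the prior mode is the constant-rate model).
#' @param rate_shape gamma prior shape on each origination/extinction
#'   rate (default 1.1).
#' @param rate_rate_lam,rate_rate_mu gamma prior rate parameters; `NULL`
#'   (default) auto-scales each so the prior mean equals the constant-rate
#'   MLE of the data.
#' @param q_rate exponential prior rate on the preservation rate
#'   (default 0.01, vague: prior mean 100).
#' @param alpha_rate exponential prior rate on the gamma-heterogeneity
#'   shape (default 0.1).
#' @return list of class `"bd_priors"`.
#' @export
bd_priors <- function(shift_rate = 0.5, rate_shape = 1.1,
                      rate_rate_lam = NULL, rate_rate_mu = NULL,
                      q_rate = 0.01, alpha_rate = 0.1) {
  stopifnot(shift_rate >= 0, rate_shape > 0, q_rate > 0, alpha_rate > 0)
  structure(list(shift_rate = shift_rate, rate_shape = rate_shape,
                 rate_rate_lam = rate_rate_lam, rate_rate_mu = rate_rate_mu,
                 q_rate = q_rate, alpha_rate = alpha_rate),
            class = "bd_priors")
}

#' Initialize the sampler state
#'
#' The chain starts from the simplest model: zero shifts in both rate
#' models, rates at the constant-rate MLEs (floored at `1e-4`). In
#' occurrence mode the latent times start at each lineage's observed
#' occurrence span padded by one expected occurrence gap (`1/q_init`),
#' and extant lineages have `te = 0` fixed.
#'
#' @param data a [lineage_ranges()] (range mode) or [occurrence_set()]
#'   with calendar ages (occurrence mode).
#' @param priors a [bd_priors()] object.
#' @param mode `"range"` or `"occurrence"`.
#' @param window observation window `c(t_old, 0)`; `NULL` derives it from
#'   the data (range: oldest `t_start`; occurrence: oldest occurrence
#'   plus `window_pad` of the observed span).
#' @param window_pad occurrence-mode padding fraction (default 0.2).
#' @return list with elements `lam`, `mu` ([rate_model()]s), `window`,
#'   `mode`, and in occurrence mode `ts`, `te`, `extant`, `q`.
#' @export
init_state <- function(data, priors = bd_priors(),
                       mode = c("range", "occurrence"), window = NULL,
                       window_pad = 0.2) {
  mode <- match.arg(mode)
  if (mode == "range") {
    if (nrow(data) == 0) lr_stop("empty range data")
    if (is.null(window)) window <- c(max(data$t_start), 0)
    st <- sufficient_stats(data, window)
    mle <- suppressWarnings(mle_constant_rates(st))
    lam0 <- max(mle["lam"], 1e-4)
    mu0 <- max(mle["mu"], 1e-4)
    return(list(lam = rate_model(lam0, window = window),
                mu = rate_model(mu0, window = window),
                window = window, mode = mode))
  }
  ages <- ages_by_lineage(data)
  if (!length(ages)) lr_stop("empty occurrence data")
  max_occ <- vapply(ages, max, numeric(1))
  min_occ <- vapply(ages, min, numeric(1))
  k <- vapply(ages, length, integer(1))
  span_total <- max(max_occ) - min(min_occ)
  if (is.null(window))
    window <- c(max(max_occ) + window_pad * span_total, 0)
  if (window[1] <= max(max_occ))
    lr_stop("window old edge must be older than the oldest occurrence")
  q_init <- max(sum(k) / max(sum(max_occ - min_occ), 1e-8), 1e-4)
  pad <- 1 / q_init
  extant <- data$extant[names(ages)]
  ts <- pmin(max_occ + pad, window[1] - 1e-6 * window[1])
  te <- ifelse(extant, 0, pmax(min_occ - pad, 0))
  rng <- lineage_ranges(names(ages), ts, te, extant)
  st <- sufficient_stats(rng, window)
  mle <- suppressWarnings(mle_constant_rates(st))
  list(lam = rate_model(max(mle["lam"], 1e-4), window = window),
       mu = rate_model(max(mle["mu"], 1e-4), window = window),
       window = window, mode = mode,
       ts = ts, te = te, extant = extant, q = q_init,
       max_occ = max_occ, min_occ = min_occ)
}

# default move weights; range mode redistributes the occurrence-only moves
#' @noRd
default_move_weights <- function(mode) {
  if (mode == "range")
    c(rates = 0.5, shift_time = 0.25, rj = 0.25, times = 0, preservation = 0)
  else
    c(rates = 0.4, shift_time = 0.2, rj = 0.2, times = 0.15,
      preservation = 0.05)
}

#' Run the reversible-jump MCMC chain
#'
#' Cycles randomly through move types (rate updates, shift-time slides,
#' dimension-changing add/remove-shift moves, and, in occurrence mode,
#' latent origination/extinction-time updates and preservation-rate
#' updates), logging one thinned sample every `sample_every` iterations.
#' Runs are deterministic given `seed`.
#'
#' @param data a [lineage_ranges()] (range mode) or [occurrence_set()]
#'   with calendar ages (occurrence mode).
#' @param priors a [bd_priors()] object.
#' @param mode `"range"` or `"occurrence"`.
#' @param n_iter total iterations.
#' @param sample_every thinning interval (`n_iter >= sample_every >= 1`).
#' @param move_weights named weights over
#'   `c("rates", "shift_time", "rj", "times", "preservation")`; `NULL`
#'   uses mode defaults. Setting a single positive weight isolates one
#'   move type (used by the prior-recovery tests).
#' @param seed integer seed (`NULL` leaves the RNG stream untouched).
#' @param prior_only if `TRUE` the likelihood is identically zero, so the
#'   chain samples the joint prior (the canonical correctness check for
#'   transdimensional moves).
#' @param preservation occurrence-mode preservation model: list with
#'   `kind` (`"HPP"` or `"NHPP"`), `shapes` (NHPP bell shapes), `gamma`
#'   (logical: gamma heterogeneity across lineages), `n_cat`.
#' @param window,window_pad see [init_state()].
#' @param proposal list of proposal scales: `rate_mult` (log-window for
#'   rate multipliers), `shift_win` (shift-time slide, default W/10),
#'   `time_win` (latent-time slide, default W/20), `q_mult`, `sigma_rj`
#'   (auxiliary-variable SD of the split move).
#' @param debug if `TRUE`, every 10^4 iterations the cached
#'   log-likelihood is recomputed from scratch and compared (tolerance
#'   `1e-8`).
#' @return object of class `"posterior_log"`: list with `samples` (a
#'   `data.frame`, one row per thinned sample), `mode`, `window`,
#'   `acceptance` (per-move acceptance rates), `priors`.
#' @export
run_chain <- function(data, priors = bd_priors(),
                      mode = c("range", "occurrence"),
                      n_iter = 1e5, sample_every = 100,
                      move_weights = NULL, seed = NULL, prior_only = FALSE,
                      preservation = list(kind = "HPP", shapes = c(2, 2),
                                          gamma = FALSE, n_cat = 4),
                      window = NULL, window_pad = 0.2, proposal = list(),
                      debug = FALSE) {
  mode <- match.arg(mode)
  if (n_iter < sample_every || sample_every < 1)
    lr_stop("need n_iter >= sample_every >= 1")
  if (!is.null(seed)) set.seed(seed)

  st <- init_state(data, priors, mode, window, window_pad)
  w1 <- st$window[1]; w2 <- st$window[2]; W <- w1 - w2
  nu <- priors$shift_rate
  shp <- priors$rate_shape

  ## data vectors
  if (mode == "range") {
    ts <- data$t_start; te <- data$t_end; extant <- data$extant
  } else {
    ts <- st$ts; te <- st$te; extant <- st$extant
    max_occ <- st$max_occ; min_occ <- st$min_occ
    ages <- ages_by_lineage(data)
    k_occ <- vapply(ages, length, integer(1))
    pk <- preservation$kind %||% "HPP"
    if (!pk %in% c("HPP", "NHPP"))
      lr_stop("sampler preservation kind must be HPP or NHPP")
    pshapes <- preservation$shapes %||% c(2, 2)
    pgamma_on <- isTRUE(preservation$gamma)
    n_cat <- preservation$n_cat %||% 4
    q <- st$q
    alpha <- if (pgamma_on) 2 else NULL
  }
  n_lin <- length(ts)

  ## gamma prior rates auto-scaled to the constant-rate MLE
  rt_lam <- priors$rate_rate_lam %||% (shp / max(st$lam$rates[1], 1e-4))
  rt_mu <- priors$rate_rate_mu %||% (shp / max(st$mu$rates[1], 1e-4))

  mw <- move_weights %||% default_move_weights(mode)
  mw_names <- c("rates", "shift_time", "rj", "times", "preservation")
  w_full <- stats::setNames(numeric(5), mw_names)
  w_full[names(mw)] <- mw
  if (mode == "range") w_full[c("times", "preservation")] <- 0
  if (sum(w_full) <= 0) lr_stop("move weights must have positive sum")
  cw <- cumsum(w_full / sum(w_full))

  prop <- list(rate_mult = 1.2, shift_win = W / 10, time_win = W / 20,
               q_mult = 1.5, sigma_rj = 0.8)
  prop[names(proposal)] <- proposal

  ## per-model mutable pieces: shifts, rates, stats (counts + exposure),
  ## loglik component. counts = B for lam, D for mu.
  mk_side <- function(model, count_field) {
    side <- list(shifts = model$shift_times, rates = model$rates)
    if (!prior_only) {
      stt <- suffstats_core(ts, te, extant, st$window, side$shifts)
      side$cnt <- stt[[count_field]]
      side$S <- stt$S
      side$ll <- sum(ifelse(side$cnt > 0, side$cnt * log(side$rates), 0)) -
        sum(side$rates * side$S)
    } else side$ll <- 0
    side
  }
  side_ll <- function(cnt, S, rates)
    sum(ifelse(cnt > 0, cnt * log(rates), 0)) - sum(rates * S)
  lam <- mk_side(st$lam, "B")
  mu <- mk_side(st$mu, "D")

  ## occurrence-mode preservation cache
  if (mode == "occurrence") {
    beta_sum <- numeric(n_lin)
    comp_beta_sum <- function(i, tsi, tei) {
      if (pk != "NHPP") return(0)
      u <- (tsi - ages[[i]]) / (tsi - tei)
      sum(stats::dbeta(pmin(pmax(u, 1e-12), 1 - 1e-12),
                       pshapes[1], pshapes[2], log = TRUE))
    }
    for (i in seq_len(n_lin)) beta_sum[i] <- comp_beta_sum(i, ts[i], te[i])
    pres_vec <- function(qv, al, s_vec, bsum, k_vec) {
      if (prior_only) return(numeric(length(s_vec)))
      base <- function(m) k_vec * log(qv * m) + bsum - qv * m * s_vec -
        log1mexp(qv * m * s_vec)
      if (!pgamma_on) return(base(1))
      mlt <- gamma_categories(al, n_cat)
      mat <- vapply(mlt, base, numeric(length(s_vec)))
      if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(s_vec))
      apply(mat, 1, logmeanexp)
    }
    pres_ll_i <- pres_vec(q, alpha, ts - te, beta_sum, k_occ)
    pres_ll <- sum(pres_ll_i)
  } else pres_ll <- 0

  ## per-lineage birth-death contribution (occurrence mode deltas)
  lineage_contrib <- function(tsi, tei, ext_i) {
    if (prior_only) return(0)
    bl <- c(w1, lam$shifts); by <- c(lam$shifts, w2)
    ovl_l <- pmax(0, pmin(tsi, bl) - pmax(tei, by))
    bm <- c(w1, mu$shifts); bym <- c(mu$shifts, w2)
    ovl_m <- pmax(0, pmin(tsi, bm) - pmax(tei, bym))
    ll <- -sum(lam$rates * ovl_l) - sum(mu$rates * ovl_m)
    if (tsi < w1 && tsi > w2)
      ll <- ll + log(lam$rates[interval_index(tsi, lam$shifts)])
    if (!ext_i && tei >= w2 && tei < w1)
      ll <- ll + log(mu$rates[interval_index(tei, mu$shifts)])
    ll
  }

  lg_const <- -lgamma(shp)
  dg <- function(x, rate)
    lg_const + shp * log(rate) + (shp - 1) * log(x) - rate * x

  n_samp <- n_iter %/% sample_every
  cols <- list(iteration = integer(n_samp), log_posterior = numeric(n_samp),
               log_likelihood = numeric(n_samp),
               lam_k = integer(n_samp), lam_rates = character(n_samp),
               lam_shifts = character(n_samp),
               mu_k = integer(n_samp), mu_rates = character(n_samp),
               mu_shifts = character(n_samp))
  if (mode == "occurrence") {
    cols$q <- numeric(n_samp)
    cols$alpha <- numeric(n_samp)
    cols$ts <- character(n_samp)
    cols$te <- character(n_samp)
  }
  acc <- stats::setNames(numeric(5), mw_names)
  try_cnt <- stats::setNames(numeric(5), mw_names)

  log_prior_total <- function() {
    lp <- dpois(length(lam$shifts), nu, log = TRUE) +
      dpois(length(mu$shifts), nu, log = TRUE) +
      lfactorial(length(lam$shifts)) - length(lam$shifts) * log(W) +
      lfactorial(length(mu$shifts)) - length(mu$shifts) * log(W) +
      sum(dg(lam$rates, rt_lam)) + sum(dg(mu$rates, rt_mu))
    if (mode == "occurrence") {
      lp <- lp + dexp(q, priors$q_rate, log = TRUE)
      if (pgamma_on) lp <- lp + dexp(alpha, priors$alpha_rate,
                                            log = TRUE)
    }
    lp
  }

  total_ll <- function() lam$ll + mu$ll + pres_ll

  si <- 0L
  chunk <- 100000L
  mv_buf <- integer(0)
  mv_at <- 0L
  for (it in seq_len(n_iter)) {
    if (mv_at == length(mv_buf)) {
      mv_buf <- findInterval(runif(min(chunk, n_iter - it + 1L)), cw) + 1L
      mv_at <- 0L
    }
    mv_at <- mv_at + 1L
    mv <- mv_buf[mv_at]
    mv_name <- mw_names[mv]
    try_cnt[mv] <- try_cnt[mv] + 1

    if (mv_name == "rates") {
      on_lam <- runif(1) < 0.5
      side <- if (on_lam) lam else mu
      rt <- if (on_lam) rt_lam else rt_mu
      j <- 1L + as.integer(runif(1) * length(side$rates))
      r <- side$rates[j]
      r2 <- r * exp(prop$rate_mult * (runif(1) - 0.5))
      dll <- if (prior_only) 0 else {
        cnt_j <- side$cnt[j]
        (if (cnt_j > 0) cnt_j * (log(r2) - log(r)) else 0) -
          (r2 - r) * side$S[j]
      }
      logA <- dll + dg(r2, rt) - dg(r, rt) + log(r2) - log(r)
      if (log(runif(1)) < logA) {
        side$rates[j] <- r2
        side$ll <- side$ll + dll
        if (on_lam) lam <- side else mu <- side
        acc[mv] <- acc[mv] + 1
      }

    } else if (mv_name == "shift_time") {
      on_lam <- runif(1) < 0.5
      side <- if (on_lam) lam else mu
      m <- length(side$shifts)
      if (m >= 1) {
        j <- 1L + as.integer(runif(1) * m)
        lo <- if (j == m) w2 else side$shifts[j + 1]
        hi <- if (j == 1) w1 else side$shifts[j - 1]
        t2 <- reflect_into(side$shifts[j] +
                             prop$shift_win * (runif(1) - 0.5),
                           lo, hi)
        new_shifts <- side$shifts
        new_shifts[j] <- t2
        if (prior_only) {
          side$shifts <- new_shifts
          if (on_lam) lam <- side else mu <- side
          acc[mv] <- acc[mv] + 1
        } else {
          stt <- suffstats_core(ts, te, extant, st$window, new_shifts)
          cnt2 <- if (on_lam) stt$B else stt$D
          ll2 <- side_ll(cnt2, stt$S, side$rates)
          if (log(runif(1)) < ll2 - side$ll) {
            side$shifts <- new_shifts
            side$cnt <- cnt2; side$S <- stt$S; side$ll <- ll2
            if (on_lam) lam <- side else mu <- side
            acc[mv] <- acc[mv] + 1
          }
        }
      }

    } else if (mv_name == "rj") {
      on_lam <- runif(1) < 0.5
      side <- if (on_lam) lam else mu
      rt <- if (on_lam) rt_lam else rt_mu
      m <- length(side$shifts)
      birth <- runif(1) < 0.5
      if (birth) {
        tstar <- runif(1, w2, w1)
        j <- interval_index(tstar, side$shifts)
        a <- if (j == 1) w1 else side$shifts[j - 1]
        b <- if (j == m + 1) w2 else side$shifts[j]
        lL <- a - tstar; lR <- tstar - b; l <- a - b
        z <- rnorm(1, 0, prop$sigma_rj)
        rj_old <- side$rates[j]
        lrL <- log(rj_old) + (lR / l) * z
        lrR <- log(rj_old) - (lL / l) * z
        rL <- exp(lrL); rR <- exp(lrR)
        new_shifts <- append(side$shifts, tstar, after = j - 1)
        new_rates <- append(side$rates[-j], c(rL, rR), after = j - 1)
        if (prior_only) {
          dll <- 0; stt <- NULL; cnt2 <- NULL
        } else {
          stt <- suffstats_core(ts, te, extant, st$window, new_shifts)
          cnt2 <- if (on_lam) stt$B else stt$D
          ll2 <- side_ll(cnt2, stt$S, new_rates)
          dll <- ll2 - side$ll
        }
        logA <- dll + log(nu) - log(m + 1) +
          dg(rL, rt) + dg(rR, rt) - dg(rj_old, rt) -
          dnorm(z, 0, prop$sigma_rj, log = TRUE) +
          (lrL + lrR - log(rj_old))
        if (log(runif(1)) < logA) {
          side$shifts <- new_shifts
          side$rates <- new_rates
          if (!prior_only) {
            side$cnt <- cnt2; side$S <- stt$S; side$ll <- side$ll + dll
          }
          if (on_lam) lam <- side else mu <- side
          acc[mv] <- acc[mv] + 1
        }
      } else if (m >= 1) {
        j <- 1L + as.integer(runif(1) * m)
        a <- if (j == 1) w1 else side$shifts[j - 1]
        mid <- side$shifts[j]
        b <- if (j == m) w2 else side$shifts[j + 1]
        lL <- a - mid; lR <- mid - b; l <- a - b
        rL <- side$rates[j]; rR <- side$rates[j + 1]
        lr_m <- (lL * log(rL) + lR * log(rR)) / l
        r_m <- exp(lr_m)
        z <- log(rL) - log(rR)
        new_shifts <- side$shifts[-j]
        new_rates <- append(side$rates[-c(j, j + 1)], r_m, after = j - 1)
        if (prior_only) {
          dll <- 0; stt <- NULL; cnt2 <- NULL
        } else {
          stt <- suffstats_core(ts, te, extant, st$window, new_shifts)
          cnt2 <- if (on_lam) stt$B else stt$D
          ll2 <- side_ll(cnt2, stt$S, new_rates)
          dll <- ll2 - side$ll
        }
        logA <- dll + log(m) - log(nu) +
          dg(r_m, rt) - dg(rL, rt) - dg(rR, rt) +
          dnorm(z, 0, prop$sigma_rj, log = TRUE) -
          (log(rL) + log(rR) - lr_m)
        if (log(runif(1)) < logA) {
          side$shifts <- new_shifts
          side$rates <- new_rates
          if (!prior_only) {
            side$cnt <- cnt2; side$S <- stt$S; side$ll <- side$ll + dll
          }
          if (on_lam) lam <- side else mu <- side
          acc[mv] <- acc[mv] + 1
        }
      }

    } else if (mv_name == "times") {
      i <- 1L + as.integer(runif(1) * n_lin)
      move_ts <- extant[i] || runif(1) < 0.5
      if (move_ts) {
        lo <- max_occ[i]; hi <- w1
        t2 <- reflect_into(ts[i] + prop$time_win * (runif(1) - 0.5),
                           lo, hi)
        new_ts <- t2; new_te <- te[i]
      } else {
        lo <- w2; hi <- min_occ[i]
        t2 <- reflect_into(te[i] + prop$time_win * (runif(1) - 0.5),
                           lo, hi)
        new_ts <- ts[i]; new_te <- t2
      }
      old_bd <- lineage_contrib(ts[i], te[i], extant[i])
      new_bd <- lineage_contrib(new_ts, new_te, extant[i])
      new_bsum <- if (mode == "occurrence") comp_beta_sum(i, new_ts, new_te)
      new_pres <- if (prior_only) 0 else
        pres_vec(q, alpha, new_ts - new_te, new_bsum, k_occ[i])
      d_pres <- if (prior_only) 0 else new_pres - pres_ll_i[i]
      logA <- (new_bd - old_bd) + d_pres
      if (log(runif(1)) < logA) {
        if (!prior_only) {
          # stats delta for both rate-model partitions
          upd_side <- function(side, count_kind) {
            bl <- c(w1, side$shifts); by <- c(side$shifts, w2)
            d_ovl <- pmax(0, pmin(new_ts, bl) - pmax(new_te, by)) -
              pmax(0, pmin(ts[i], bl) - pmax(te[i], by))
            side$S <- side$S + d_ovl
            if (count_kind == "B") {
              if (ts[i] < w1 && ts[i] > w2) {
                ix <- interval_index(ts[i], side$shifts)
                side$cnt[ix] <- side$cnt[ix] - 1L
              }
              if (new_ts < w1 && new_ts > w2) {
                ix <- interval_index(new_ts, side$shifts)
                side$cnt[ix] <- side$cnt[ix] + 1L
              }
            } else if (!extant[i]) {
              if (te[i] >= w2 && te[i] < w1) {
                ix <- interval_index(te[i], side$shifts)
                side$cnt[ix] <- side$cnt[ix] - 1L
              }
              if (new_te >= w2 && new_te < w1) {
                ix <- interval_index(new_te, side$shifts)
                side$cnt[ix] <- side$cnt[ix] + 1L
              }
            }
            side$ll <- side_ll(side$cnt, side$S, side$rates)
            side
          }
          lam <- upd_side(lam, "B")
          mu <- upd_side(mu, "D")
          pres_ll <- pres_ll + d_pres
          pres_ll_i[i] <- new_pres
        }
        ts[i] <- new_ts; te[i] <- new_te
        beta_sum[i] <- new_bsum
        acc[mv] <- acc[mv] + 1
      }

    } else if (mv_name == "preservation") {
      move_alpha <- pgamma_on && runif(1) < 0.5
      if (move_alpha) {
        a2 <- alpha * exp(prop$q_mult * (runif(1) - 0.5))
        new_i <- pres_vec(q, a2, ts - te, beta_sum, k_occ)
        dll <- sum(new_i) - pres_ll
        logA <- dll +
          dexp(a2, priors$alpha_rate, log = TRUE) -
          dexp(alpha, priors$alpha_rate, log = TRUE) +
          log(a2) - log(alpha)
        if (log(runif(1)) < logA) {
          alpha <- a2; pres_ll_i <- new_i; pres_ll <- sum(new_i)
          acc[mv] <- acc[mv] + 1
        }
      } else {
        q2 <- q * exp(prop$q_mult * (runif(1) - 0.5))
        new_i <- pres_vec(q2, alpha, ts - te, beta_sum, k_occ)
        dll <- sum(new_i) - pres_ll
        logA <- dll +
          dexp(q2, priors$q_rate, log = TRUE) -
          dexp(q, priors$q_rate, log = TRUE) +
          log(q2) - log(q)
        if (log(runif(1)) < logA) {
          q <- q2; pres_ll_i <- new_i; pres_ll <- sum(new_i)
          acc[mv] <- acc[mv] + 1
        }
      }
    }

    if (debug && it %% 10000L == 0L && !prior_only) {
      lam_chk <- suffstats_core(ts, te, extant, st$window, lam$shifts)
      mu_chk <- suffstats_core(ts, te, extant, st$window, mu$shifts)
      ll_chk <- side_ll(lam_chk$B, lam_chk$S, lam$rates) +
        side_ll(mu_chk$D, mu_chk$S, mu$rates)
      if (abs(ll_chk - (lam$ll + mu$ll)) > 1e-8)
        lr_stop("cached log-likelihood drifted at iteration ", it,
                ": cached ", lam$ll + mu$ll, " vs ", ll_chk)
    }

    if (it %% sample_every == 0L) {
      si <- si + 1L
      cols$iteration[si] <- it
      cols$log_likelihood[si] <- total_ll()
      cols$log_posterior[si] <- cols$log_likelihood[si] + log_prior_total()
      cols$lam_k[si] <- length(lam$rates)
      cols$lam_rates[si] <- paste(lam$rates, collapse = ";")
      cols$lam_shifts[si] <- paste(lam$shifts, collapse = ";")
      cols$mu_k[si] <- length(mu$rates)
      cols$mu_rates[si] <- paste(mu$rates, collapse = ";")
      cols$mu_shifts[si] <- paste(mu$shifts, collapse = ";")
      if (mode == "occurrence") {
        cols$q[si] <- q
        cols$alpha[si] <- if (pgamma_on) alpha else NA_real_
        cols$ts[si] <- paste(signif(ts, 10), collapse = ";")
        cols$te[si] <- paste(signif(te, 10), collapse = ";")
      }
      if (!is.finite(cols$log_likelihood[si]))
        lr_stop("non-finite likelihood at iteration ", it)
    }
  }

  samples <- as.data.frame(cols, stringsAsFactors = FALSE)
  structure(list(samples = samples, mode = mode, window = st$window,
                 acceptance = ifelse(try_cnt > 0, acc / try_cnt, NA),
                 priors = priors),
            class = "posterior_log")
}

#' @export
print.posterior_log <- function(x, ...) {
  cat(sprintf("posterior_log: %d samples, mode '%s', window [%g, %g]\n",
              nrow(x$samples), x$mode, x$window[1], x$window[2]))
  ar <- x$acceptance[!is.na(x$acceptance)]
  if (length(ar))
    cat(" acceptance:", paste(sprintf("%s %.2f", names(ar), ar),
                              collapse = ", "), "\n")
  invisible(x)
}
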