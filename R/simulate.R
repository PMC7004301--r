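# Forward simulators: birth-death lineage histories, Poisson preservation
# of occurrences, and radiocarbon measurement noise. These exercise every
# likelihood in the package as a generative model and build the named
# test fixtures.

#' Simulate a piecewise-constant birth-death lineage history
#'
#' Event-driven simulation from the old window edge: `n0` founder
#' lineages start at `t_old`; every living lineage spawns new lineages at
#' rate `lam(t)` and goes extinct at rate `mu(t)` (exact piecewise-
#' exponential waiting times across rate-shift boundaries, by memoryless
#' restart at each boundary). Lineages alive at the young edge are marked
#' extant with `t_end = t_young`.
#'
#' @param lam,mu [rate_model()] objects sharing a window.
#' @param n0 number of founding lineages at the old window edge.
#' @param cap abort threshold on the total number of lineages (guards
#'   runaway supercritical growth).
#' @return a [lineage_ranges()] object (founders have
#'   `t_start = t_old`).
#' @examples
#' set.seed(1)
#' w <- c(25, 0)
#' sim <- simulate_bd(rate_model(0.2, window = w),
#'                    rate_model(0.1, window = w), n0 = 10)
#' @export
simulate_bd <- function(lam, mu, n0, cap = 1e6) {
  if (!isTRUE(all.equal(lam$window, mu$window)))
    lr_stop("lam and mu must share the same window")
  if (n0 < 1) lr_stop("n0 must be >= 1")
  window <- lam$window
  bounds <- sort(unique(c(lam$shift_times, mu$shift_times)),
                 decreasing = TRUE)
  bounds <- c(bounds, window[2])
  n_alloc <- max(64, 4 * n0)
  ts <- numeric(n_alloc); te <- numeric(n_alloc); ext <- logical(n_alloc)
  ts[seq_len(n0)] <- window[1]
  n_total <- n0
  alive <- seq_len(n0)
  n_alive <- n0
  t <- window[1]
  bi <- 1L
  repeat {
    if (n_alive == 0 || t <= window[2]) break
    lam_c <- rate_at(lam, t - 1e-12 * max(1, abs(t)))
    mu_c <- rate_at(mu, t - 1e-12 * max(1, abs(t)))
    next_bound <- bounds[bi]
    R <- n_alive * (lam_c + mu_c)
    t_next <- if (R > 0) t - stats::rexp(1, R) else -Inf
    if (t_next <= next_bound) {
      t <- next_bound
      if (t <= window[2]) break
      bi <- bi + 1L
      next
    }
    t <- t_next
    if (stats::runif(1) < lam_c / (lam_c + mu_c)) {
      n_total <- n_total + 1L
      if (n_total > cap) lr_stop("simulation exceeded cap of ", cap,
                                 " lineages")
      if (n_total > n_alloc) {
        ts <- c(ts, numeric(n_alloc))
        te <- c(te, numeric(n_alloc))
        ext <- c(ext, logical(n_alloc))
        n_alloc <- 2 * n_alloc
      }
      ts[n_total] <- t
      n_alive <- n_alive + 1L
      alive[n_alive] <- n_total
    } else {
      j <- sample.int(n_alive, 1)
      te[alive[j]] <- t
      alive[j] <- alive[n_alive]
      n_alive <- n_alive - 1L
    }
  }
  if (n_alive > 0) {
    surv <- alive[seq_len(n_alive)]
    te[surv] <- window[2]
    ext[surv] <- TRUE
  }
  idx <- seq_len(n_total)
  out <- lineage_ranges(sprintf("sim_%d", idx), ts[idx],
                        pmax(te[idx], window[2]), ext[idx])
  attr(out, "window") <- window
  out
}

#' Simulate preservation of occurrences along lineage ranges
#'
#' Per lineage: draw a gamma multiplier if heterogeneity is active, then
#' generate occurrence times from the model's Poisson intensity over the
#' lineage's lifespan (HPP: uniform times; NHPP: beta-positioned times;
#' TPP: per-epoch homogeneous segments). Lineages with zero occurrences
#' are dropped, matching the at-least-one-occurrence conditioning of the
#' likelihoods; their ids are reported in `attr(result, "dropped")`.
#'
#' @param ranges a [lineage_ranges()] object.
#' @param kind `"HPP"`, `"NHPP"` or `"TPP"`.
#' @param q base preservation rate (HPP/NHPP) or vector of per-epoch
#'   rates (TPP).
#' @param shapes NHPP beta shapes (default `c(2, 2)`).
#' @param epoch_bounds TPP epoch boundaries (strictly decreasing).
#' @param gamma_shape optional gamma heterogeneity shape; `NULL` disables.
#' @return an [occurrence_set()] with `"cal"` ages; dropped lineage ids in
#'   `attr(, "dropped")`, drawn multipliers in `attr(, "multipliers")`.
#' @export
simulate_preservation <- function(ranges, kind = c("HPP", "NHPP", "TPP"),
                                  q, shapes = c(2, 2),
                                  epoch_bounds = numeric(0),
                                  gamma_shape = NULL) {
  kind <- match.arg(kind)
  n <- nrow(ranges)
  mult <- if (is.null(gamma_shape)) rep(1, n)
          else stats::rgamma(n, shape = gamma_shape, rate = gamma_shape)
  ages <- vector("list", n)
  for (i in seq_len(n)) {
    tsi <- ranges$t_start[i]; tei <- ranges$t_end[i]
    s <- tsi - tei
    if (s <= 0) { ages[[i]] <- numeric(0); next }
    if (kind == "TPP") {
      old <- c(Inf, epoch_bounds); yng <- c(epoch_bounds, -Inf)
      hi <- pmin(tsi, old); lo <- pmax(tei, yng)
      ovl <- pmax(0, hi - lo)
      kk <- stats::rpois(length(q), q * mult[i] * ovl)
      ages[[i]] <- unlist(lapply(seq_along(kk), function(e)
        if (kk[e] > 0) stats::runif(kk[e], lo[e], hi[e]) else numeric(0)))
    } else {
      kk <- stats::rpois(1, q * mult[i] * s)
      ages[[i]] <- if (kk == 0) numeric(0)
        else if (kind == "HPP") stats::runif(kk, tei, tsi)
        else tsi - s * stats::rbeta(kk, shapes[1], shapes[2])
    }
  }
  keep <- vapply(ages, length, integer(1)) > 0
  if (!any(keep)) lr_stop("no lineage retained any occurrence; raise q")
  rec <- data.frame(
    lineage_id = rep(ranges$lineage_id[keep],
                     vapply(ages[keep], length, integer(1))),
    age_type = "cal", age = unlist(ages[keep]), err = NA_real_,
    stringsAsFactors = FALSE)
  out <- occurrence_set(rec, stats::setNames(ranges$extant, ranges$lineage_id))
  attr(out, "dropped") <- ranges$lineage_id[!keep]
  attr(out, "multipliers") <- stats::setNames(mult, ranges$lineage_id)
  out
}

#' Add radiocarbon measurement noise to calendar-aged occurrences
#'
#' The inverse of calibration: each calendar age is pushed through the
#' calibration curve and jittered,
#' `uncal ~ Normal(c14_age(age), sqrt(err^2 + curve_err(age)^2))`.
#'
#' @param occ an [occurrence_set()] with `"cal"` ages within the curve
#'   span.
#' @param curve a [calibration_curve()].
#' @param err measurement 1-sigma error assigned to every occurrence.
#' @return an [occurrence_set()] with `"c14"` records.
#' @export
simulate_radiocarbon <- function(occ, curve, err) {
  rec <- occ$records
  if (any(rec$age < min(curve$cal_bp) | rec$age > max(curve$cal_bp)))
    lr_stop("occurrence age(s) outside the calibration curve span")
  mu <- stats::approx(curve$cal_bp, curve$c14_age, rec$age)$y
  ce <- stats::approx(curve$cal_bp, curve$err, rec$age)$y
  rec$age <- stats::rnorm(nrow(rec), mu, sqrt(err^2 + ce^2))
  rec$age_type <- "c14"
  rec$err <- err
  occurrence_set(rec, occ$extant)
}

#' Named synthetic fixtures with known parameters
#'
#' Deterministic (seed-derived) datasets used throughout the tests:
#' \describe{
#'   \item{`constant_rates`}{range data, constant `lam = 0.2`,
#'     `mu = 0.1`, window `[25, 0]`, 30 founders.}
#'   \item{`two_regime`}{range data, `lam` drops 0.3 to 0.05 at the
#'     window midpoint (t = 20 of `[40, 0]`), constant `mu = 0.1`, 10
#'     founders.}
#'   \item{`car_like`}{range data on a century-long window `[110, 0]`
#'     (year-grain), near-critical rates, many lineages.}
#'   \item{`neolithic_like`}{occurrence data: 22 lineages on a `[3, 0]`
#'     window (time unit = 1000 years), bell-shaped (NHPP, shapes 2, 2)
#'     preservation with `q = 80` occurrences per lineage per time unit.
#'     The founder seed is scanned deterministically until exactly 22
#'     lineages survive with occurrences.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed; the fixture regenerates bit-identically from
#'   the same seed.
#' @return list with elements `data` (a [lineage_ranges()] or
#'   [occurrence_set()]), `truth` (named list of generating parameters,
#'   YAML-serializable), and `mode` (`"range"` or `"occurrence"`).
#' @export
make_fixture <- function(name = c("constant_rates", "two_regime",
                                  "car_like", "neolithic_like"),
                         seed = 42) {
  name <- match.arg(name)
  if (name == "constant_rates") {
    w <- c(25, 0)
    truth <- list(name = name, seed = seed, window = w, lam = 0.2, mu = 0.1,
                  n0 = 30)
    set.seed(seed)
    data <- simulate_bd(rate_model(0.2, window = w),
                        rate_model(0.1, window = w), n0 = 30)
    return(list(data = data, truth = truth, mode = "range"))
  }
  if (name == "two_regime") {
    w <- c(40, 0)
    truth <- list(name = name, seed = seed, window = w,
                  lam = c(0.3, 0.05), lam_shift = 20, mu = 0.1, n0 = 10)
    set.seed(seed)
    data <- simulate_bd(rate_model(c(0.3, 0.05), 20, w),
                        rate_model(0.1, window = w), n0 = 10)
    return(list(data = data, truth = truth, mode = "range"))
  }
  if (name == "car_like") {
    w <- c(110, 0)
    truth <- list(name = name, seed = seed, window = w, lam = 0.15,
                  mu = 0.145, n0 = 40)
    set.seed(seed)
    data <- simulate_bd(rate_model(0.15, window = w),
                        rate_model(0.145, window = w), n0 = 40)
    return(list(data = data, truth = truth, mode = "range"))
  }
  # neolithic_like: scan sub-seeds until exactly 22 observed lineages
  w <- c(3, 0)
  truth <- list(name = name, seed = seed, window = w, lam = 0.4, mu = 0.3,
                n0 = 10, preservation = "NHPP", q = 80, shapes = c(2, 2),
                n_lineages = 22)
  for (j in 0:200) {
    set.seed(seed + 1000L * j)
    ranges <- simulate_bd(rate_model(0.4, window = w),
                          rate_model(0.3, window = w), n0 = 10)
    occ <- simulate_preservation(ranges, "NHPP", q = 80, shapes = c(2, 2))
    if (length(occ$extant) == 22) {
      truth$subseed <- seed + 1000L * j
      truth$ranges <- list(lineage_id = ranges$lineage_id,
                           t_start = ranges$t_start,
                           t_end = ranges$t_end,
                           extant = ranges$extant)
      truth$dropped <- as.character(attr(occ, "dropped"))
      return(list(data = occ, truth = truth, mode = "occurrence"))
    }
  }
  lr_stop("no sub-seed yielding 22 observed lineages found")
}

#' Write a fixture's ground-truth parameters as YAML
#'
#' @param fixture output of [make_fixture()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(fixture, path) {
  yaml::write_yaml(fixture$truth, path, precision = 15)
  invisible(path)
}

#' Read a ground-truth parameter file
#'
#' @param path YAML file written by [write_truth()].
#' @return named list.
#' @export
read_truth <- function(path) {
  yaml::read_yaml(path)
}
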