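# shared builders for small in-code fixtures

# synthetic wiggly calibration curve on [4000, 6000] cal BP
wiggly_curve <- function() {
  cal <- seq(4000, 6000, by = 5)
  c14 <- cal - 300 + 40 * sin(cal / 50) + 15 * sin(cal / 13)
  err <- 8 + 4 * abs(sin(cal / 200))
  calibration_curve(cal, c14, err)
}

# identity curve (c14 age == calendar age), optionally zero curve error
identity_curve <- function(lo = 4000, hi = 6000, err = 0) {
  cal <- seq(lo, hi, by = 5)
  calibration_curve(cal, cal, rep(err, length(cal)))
}

# brute-force calibration oracle: direct normalization of the Normal
# measurement density on the same grid (independent of calibrate()
# internals except for the published truncation rule)
calibrate_oracle <- function(uncal, uerr, curve, grid_step = 1,
                             truncate = TRUE) {
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  mu <- approx(curve$cal_bp, curve$c14_age, grid)$y
  ce <- approx(curve$cal_bp, curve$err, grid)$y
  w <- dnorm(uncal, mu, sqrt(uerr^2 + ce^2))
  pmf <- w / sum(w)
  if (truncate) {
    cum <- cumsum(pmf)
    keep <- which(cum >= 1e-6 & (1 - cum + pmf) >= 1e-6)
    grid <- grid[keep]
    pmf <- pmf[keep] / sum(pmf[keep])
  }
  list(grid = grid, pmf = pmf)
}

# hand-built posterior_log with given shift/rate strings (for
# postprocess unit tests)
fake_log <- function(lam_rates, lam_shifts, mu_rates, mu_shifts,
                     window = c(10, 0)) {
  n <- length(lam_rates)
  structure(list(
    samples = data.frame(
      iteration = seq_len(n), log_posterior = 0, log_likelihood = 0,
      lam_k = lengths(strsplit(lam_rates, ";")),
      lam_rates = lam_rates, lam_shifts = lam_shifts,
      mu_k = lengths(strsplit(mu_rates, ";")),
      mu_rates = mu_rates, mu_shifts = mu_shifts,
      stringsAsFactors = FALSE),
    mode = "range", window = window, acceptance = NULL, priors = NULL),
    class = "posterior_log")
}

# occurrence set with a single lineage from explicit ages
one_lineage_occ <- function(ages, id = "lin1", extant = FALSE) {
  occurrence_set(data.frame(lineage_id = id, age_type = "cal",
                            age = ages, err = NA_real_),
                 setNames(extant, id))
}
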