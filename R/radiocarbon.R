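# Radiocarbon calibration: turn an uncalibrated 14C age +/- error into a
# probability distribution over calendar ages using an IntCal-format
# calibration curve, and resample the distributions into replicate
# datasets of fixed calendar ages.

#' Load an IntCal-format calibration curve
#'
#' IntCal text format: comment/header lines starting with `#`, then
#' comma-separated rows `CAL BP, 14C age, Error, ...` (extra columns are
#' ignored).
#'
#' @param path path to the curve file.
#' @return `data.frame` of class `"calibration_curve"` with columns
#'   `cal_bp`, `c14_age`, `err`, ordered by increasing `cal_bp`.
#' @export
load_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) lr_stop("no data rows in curve file")
  tab <- utils::read.csv(text = lines, header = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    lr_stop("curve file needs at least 3 columns: cal BP, 14C age, error")
  calibration_curve(tab[[1]], tab[[2]], tab[[3]])
}

#' Construct a calibration curve
#'
#' @param cal_bp calendar ages BP, strictly monotone.
#' @param c14_age radiocarbon age of the curve at each calendar age.
#' @param err 1-sigma curve uncertainty at each calendar age (>= 0).
#' @return `data.frame` of class `"calibration_curve"` sorted by
#'   increasing `cal_bp`.
#' @export
calibration_curve <- function(cal_bp, c14_age, err) {
  n <- length(cal_bp)
  if (length(c14_age) != n || length(err) != n)
    lr_stop("curve columns must have equal length")
  if (any(!is.finite(cal_bp)) || any(!is.finite(c14_age)) ||
      any(!is.finite(err)))
    lr_stop("non-finite values in curve")
  if (any(err < 0)) lr_stop("curve errors must be >= 0")
  o <- order(cal_bp)
  cal_bp <- cal_bp[o]; c14_age <- c14_age[o]; err <- err[o]
  if (any(diff(cal_bp) == 0))
    lr_stop("calibration curve calendar ages must be strictly monotone")
  out <- data.frame(cal_bp = cal_bp, c14_age = c14_age, err = err)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Calibrate a radiocarbon age
#'
#' Evaluates, on a calendar-age grid, the probability that the sample's
#' true calendar age is theta: proportional to the Normal density of
#' `uncal_age - c14_age(theta)` with variance
#' `uncal_err^2 + curve_err(theta)^2` (curve mean and error linearly
#' interpolated onto the grid), normalized to sum to one. The support is
#' truncated where the cumulative mass in either tail is below `1e-6`,
#' then renormalized.
#'
#' @param uncal_age uncalibrated radiocarbon age (14C yr BP).
#' @param uncal_err 1-sigma measurement error (> 0).
#' @param curve a [calibration_curve()].
#' @param grid_step calendar grid resolution in years (default 1).
#' @return list of class `"calibrated_date"` with elements `grid`
#'   (calendar ages BP, increasing) and `pmf` (probability mass per grid
#'   age, summing to 1).
#' @export
calibrate <- function(uncal_age, uncal_err, curve, grid_step = 1) {
  if (uncal_err <= 0) lr_stop("uncal_err must be > 0")
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  mu <- stats::approx(curve$cal_bp, curve$c14_age, grid)$y
  ce <- stats::approx(curve$cal_bp, curve$err, grid)$y
  sd <- sqrt(uncal_err^2 + ce^2)
  logw <- stats::dnorm(uncal_age, mean = mu, sd = sd, log = TRUE)
  m <- max(logw)
  if (!is.finite(m) ||
      uncal_age > max(curve$c14_age) + 8 * max(sd) ||
      uncal_age < min(curve$c14_age) - 8 * max(sd))
    lr_stop("radiocarbon age ", uncal_age, " outside curve support")
  w <- exp(logw - m)
  pmf <- w / sum(w)
  cum <- cumsum(pmf)
  keep <- which(cum >= 1e-6 & (1 - cum + pmf) >= 1e-6)
  if (!length(keep)) keep <- which.max(pmf)
  grid <- grid[keep]
  pmf <- pmf[keep]
  pmf <- pmf / sum(pmf)
  structure(list(grid = grid, pmf = pmf), class = "calibrated_date")
}

#' @export
print.calibrated_date <- function(x, ...) {
  mean_age <- sum(x$grid * x$pmf)
  cat(sprintf("calibrated_date: %d grid ages on [%g, %g], mean %.1f cal BP\n",
              length(x$grid), min(x$grid), max(x$grid), mean_age))
  invisible(x)
}

#' Sample calendar ages from a calibrated date
#'
#' @param cd a [calibrate()]d date.
#' @param n number of draws (>= 1).
#' @return numeric vector of `n` calendar ages drawn i.i.d. from the
#'   calibrated probability distribution (reproducible under
#'   [set.seed()]).
#' @export
sample_ages <- function(cd, n) {
  if (!length(cd$grid)) lr_stop("degenerate calibrated date (empty support)")
  if (n < 1) lr_stop("n must be >= 1")
  cd$grid[sample.int(length(cd$grid), n, replace = TRUE, prob = cd$pmf)]
}

#' Build weighted-resample replicate datasets
#'
#' Every radiocarbon (`c14`) occurrence is calibrated and one calendar age
#' is drawn per replicate from its calibrated distribution, weighted by
#' the calibrated probabilities; `cal` occurrences pass through unchanged.
#' The result is `n_rep` occurrence sets with fixed calendar ages, used to
#' propagate dating uncertainty by replicating the downstream analysis.
#'
#' @param occ an [occurrence_set()].
#' @param curve a [calibration_curve()].
#' @param n_rep number of replicates (default 100).
#' @param grid_step calibration grid resolution (default 1 yr).
#' @return list of `n_rep` [occurrence_set()] objects, all ages `"cal"`.
#' @export
build_replicates <- function(occ, curve, n_rep = 100, grid_step = 1) {
  rec <- occ$records
  is14 <- rec$age_type == "c14"
  draws <- matrix(rep(rec$age, n_rep), nrow = nrow(rec))
  for (j in which(is14)) {
    cd <- tryCatch(calibrate(rec$age[j], rec$err[j], curve, grid_step),
                   error = function(e)
                     lr_stop("record ", j, " (", rec$lineage_id[j], "): ",
                             conditionMessage(e)))
    draws[j, ] <- sample_ages(cd, n_rep)
  }
  lapply(seq_len(n_rep), function(r) {
    out <- rec
    out$age <- draws[, r]
    out$age_type <- "cal"
    out$err <- NA_real_
    occurrence_set(out, occ$extant)
  })
}
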