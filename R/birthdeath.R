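# Piecewise-constant birth-death model for range data.
#
# A rate model is a piecewise-constant rate function on the observation
# window [t_old, t_young] (time before reference, t_old > t_young): shift
# times (strictly decreasing, strictly inside the window) split the window
# into intervals, each with its own positive rate. One instance describes
# the origination rate (lambda), a second the extinction rate (mu); their
# partitions are independent.

#' Construct a piecewise-constant rate model
#'
#' @param rates positive rates, one per interval, oldest interval first;
#'   units are events per lineage per time unit.
#' @param shift_times strictly decreasing shift times strictly inside the
#'   window (may be empty for a constant rate).
#' @param window numeric `c(t_old, t_young)` with `t_old > t_young`.
#' @return list of class `"rate_model"`.
#' @examples
#' rate_model(c(0.3, 0.05), shift_times = 20, window = c(40, 0))
#' @export
rate_model <- function(rates, shift_times = numeric(0), window) {
  check_window(window)
  shift_times <- as.numeric(shift_times)
  rates <- as.numeric(rates)
  if (length(rates) != length(shift_times) + 1L)
    lr_stop("need one rate per interval: length(rates) == length(shift_times) + 1")
  if (any(rates <= 0)) lr_stop("rates must be > 0")
  if (length(shift_times)) {
    if (is.unsorted(rev(shift_times), strictly = TRUE))
      lr_stop("shift_times must be strictly decreasing")
    if (any(shift_times >= window[1]) || any(shift_times <= window[2]))
      lr_stop("shift_times must lie strictly inside the window")
  }
  structure(list(rates = rates, shift_times = shift_times, window = window),
            class = "rate_model")
}

#' @noRd
check_window <- function(window) {
  if (length(window) != 2 || !all(is.finite(window)) ||
      window[1] <= window[2])
    lr_stop("window must be c(t_old, t_young) with t_old > t_young")
  invisible(window)
}

# interval index of times t for decreasing boundaries (t_old, shifts...):
# interval i covers (s_i, s_{i-1}], boundary times belong to the younger
# interval
#' @noRd
interval_index <- function(t, shift_times) {
  if (!length(shift_times)) return(rep(1L, length(t)))
  1L + findInterval(-t, -shift_times)
}

#' Evaluate a rate model
#'
#' @param model a [rate_model()].
#' @param t numeric times before reference (inside the window).
#' @return numeric vector of rates at `t`.
#' @export
rate_at <- function(model, t) {
  model$rates[interval_index(t, model$shift_times)]
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("rate_model on [%g, %g]: %d interval(s)\n",
              x$window[1], x$window[2], length(x$rates)))
  cat(" rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
  if (length(x$shift_times))
    cat(" shifts:", paste(signif(x$shift_times, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Sufficient statistics of the piecewise-constant birth-death likelihood
#'
#' For each interval of the partition: `B` counts origination events
#' (lineages with `t_start` strictly inside the window falling in the
#' interval; lineages already alive at the window's old edge contribute no
#' birth), `D` counts extinctions of non-extant lineages, and `S` is the
#' total lineage-time (sum of each lineage's overlap with the interval).
#' Ranges are clipped to the window.
#'
#' @param ranges a [lineage_ranges()] object.
#' @param window `c(t_old, t_young)`.
#' @param shift_times strictly decreasing interior partition boundaries
#'   (may be empty: single interval).
#' @return list of class `"bd_stats"` with vectors `B`, `D`, `S` (one
#'   entry per interval, oldest first), plus `shift_times` and `window`.
#' @export
sufficient_stats <- function(ranges, window, shift_times = numeric(0)) {
  check_window(window)
  suffstats_core(ranges$t_start, ranges$t_end, ranges$extant,
                 window, shift_times)
}

# vector core shared with the sampler (no data.frame overhead)
#' @noRd
suffstats_core <- function(ts, te, extant, window, shift_times) {
  k <- length(shift_times) + 1L
  bounds_old <- c(window[1], shift_times)
  bounds_yng <- c(shift_times, window[2])
  B <- D <- integer(k)
  S <- numeric(k)
  births <- ts < window[1] & ts > window[2]
  if (any(births)) {
    idx <- interval_index(ts[births], shift_times)
    tb <- tabulate(idx, nbins = k)
    B <- tb
  }
  deaths <- !extant & te >= window[2] & te < window[1]
  if (any(deaths)) {
    idx <- interval_index(te[deaths], shift_times)
    D <- tabulate(idx, nbins = k)
  }
  for (i in seq_len(k)) {
    S[i] <- sum(pmax(0, pmin(ts, bounds_old[i]) - pmax(te, bounds_yng[i])))
  }
  structure(list(B = B, D = D, S = S, shift_times = shift_times,
                 window = window), class = "bd_stats")
}

#' Birth-death log-likelihood from sufficient statistics
#'
#' Evaluates `sum_i [ B_i log(lam_i) + D_i log(mu_i) - (lam_i + mu_i) S_i ]`
#' for rate vectors on the same partition as `stats`. A zero rate facing a
#' positive event count gives `-Inf`.
#'
#' @param stats a [sufficient_stats()] result.
#' @param lam,mu positive rate vectors, one entry per interval of `stats`.
#' @return log-likelihood (scalar).
#' @export
bd_loglik <- function(stats, lam, mu) {
  k <- length(stats$S)
  if (length(lam) != k || length(mu) != k)
    lr_stop("lam and mu must have one rate per interval of stats")
  if (any(lam < 0) || any(mu < 0)) lr_stop("rates must be >= 0")
  term <- function(cnt, r) {
    out <- ifelse(cnt > 0, cnt * log(r), 0)  # 0 * log(0) := 0
    sum(out)
  }
  term(stats$B, lam) + term(stats$D, mu) - sum((lam + mu) * stats$S)
}

#' Birth-death log-likelihood of ranges under two rate models
#'
#' `lam` and `mu` may have different partitions; sufficient statistics are
#' computed per model (the likelihood factorizes into an origination part,
#' depending on `B` and `S` under the lambda partition, and an extinction
#' part depending on `D` and `S` under the mu partition).
#'
#' @param ranges a [lineage_ranges()] object.
#' @param lam,mu [rate_model()] objects sharing the same window.
#' @return log-likelihood (scalar).
#' @export
bd_loglik_ranges <- function(ranges, lam, mu) {
  if (!isTRUE(all.equal(lam$window, mu$window)))
    lr_stop("lam and mu must share the same window")
  sl <- sufficient_stats(ranges, lam$window, lam$shift_times)
  sm <- sufficient_stats(ranges, mu$window, mu$shift_times)
  sum(ifelse(sl$B > 0, sl$B * log(lam$rates), 0)) -
    sum(lam$rates * sl$S) +
    sum(ifelse(sm$D > 0, sm$D * log(mu$rates), 0)) -
    sum(mu$rates * sm$S)
}

#' Constant-rate maximum-likelihood estimates
#'
#' For a single-interval partition the MLEs are the event counts divided
#' by the total lineage-time: `lam_hat = B/S`, `mu_hat = D/S`.
#'
#' @param stats a [sufficient_stats()] result (any partition; counts and
#'   exposure are pooled).
#' @return named numeric `c(lam = B/S, mu = D/S)`. Boundary MLEs (zero
#'   counts) are returned with a warning.
#' @export
mle_constant_rates <- function(stats) {
  B <- sum(stats$B); D <- sum(stats$D); S <- sum(stats$S)
  if (S <= 0) lr_stop("total lineage-time S is zero; rates not estimable")
  if (B == 0 || D == 0)
    warning("zero event count: boundary MLE of 0", call. = FALSE)
  c(lam = B / S, mu = D / S)
}

#' Net diversification rate through time
#'
#' @param lam,mu [rate_model()] objects sharing the same window.
#' @param grid times before reference at which to evaluate.
#' @return numeric vector `rate_at(lam, grid) - rate_at(mu, grid)`.
#' @export
net_diversification <- function(lam, mu, grid) {
  if (!isTRUE(all.equal(lam$window, mu$window)))
    lr_stop("lam and mu must share the same window")
  rate_at(lam, grid) - rate_at(mu, grid)
}
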