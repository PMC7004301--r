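# Posterior summarization: rates through time with highest-posterior-
# density bands, per-bin shift frequencies, and Bayes-factor support for
# shifts against the prior expectation.

#' Highest-posterior-density interval
#'
#' Shortest contiguous interval containing the target posterior mass
#' (sorted sliding-window method).
#'
#' @param samples numeric vector of posterior draws (at least 1).
#' @param mass target mass (default 0.95).
#' @return numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n == 0) lr_stop("no samples")
  if (mass <= 0 || mass > 1) lr_stop("mass must be in (0, 1]")
  x <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1)
  widths <- x[starts + m - 1] - x[starts]
  i <- starts[which.min(widths)]
  c(x[i], x[i + m - 1])
}

# pooled post-burn-in samples across one or many logs
#' @noRd
pool_samples <- function(logs, burn_in) {
  if (inherits(logs, "posterior_log")) logs <- list(logs)
  if (burn_in < 0 || burn_in >= 1) lr_stop("burn_in must be in [0, 1)")
  wins <- lapply(logs, function(l) l$window)
  w0 <- wins[[1]]
  for (w in wins) if (!isTRUE(all.equal(w, w0)))
    lr_stop("logs have disjoint or mismatched windows")
  rows <- lapply(logs, function(l) {
    s <- l$samples
    drop <- floor(burn_in * nrow(s))
    if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
    s
  })
  list(samples = do.call(rbind, rows), window = w0)
}

#' Rates-through-time posterior summary
#'
#' Evaluates each posterior sample's piecewise-constant origination and
#' extinction rate functions on a time grid, pools samples across
#' replicate logs (equal weight per replicate), and reports the
#' pointwise posterior mean and 95% HPD interval for the origination
#' rate, the extinction rate, and the net diversification rate (computed
#' per sample, not as a difference of summaries).
#'
#' @param logs one `posterior_log` or a list of them (replicates sharing
#'   a window).
#' @param grid times before reference; `NULL` uses a unit-step grid over
#'   the window.
#' @param burn_in fraction of each log discarded from the front
#'   (default 0.1).
#' @param mass HPD mass (default 0.95).
#' @return `data.frame` of class `"rtt_summary"`: columns `time`,
#'   `lam_mean`, `lam_lo`, `lam_hi`, `mu_mean`, `mu_lo`, `mu_hi`,
#'   `r_mean`, `r_lo`, `r_hi`.
#' @export
rtt_summary <- function(logs, grid = NULL, burn_in = 0.1, mass = 0.95) {
  pool <- pool_samples(logs, burn_in)
  s <- pool$samples
  if (!nrow(s)) lr_stop("no post-burn-in samples")
  if (is.null(grid))
    grid <- seq(pool$window[1], pool$window[2], by = -1)
  lam_r <- parse_semi(s$lam_rates); lam_s <- parse_semi(s$lam_shifts)
  mu_r <- parse_semi(s$mu_rates); mu_s <- parse_semi(s$mu_shifts)
  n <- nrow(s); g <- length(grid)
  lam_m <- matrix(0, n, g); mu_m <- matrix(0, n, g)
  for (i in seq_len(n)) {
    lam_m[i, ] <- lam_r[[i]][interval_index(grid, lam_s[[i]])]
    mu_m[i, ] <- mu_r[[i]][interval_index(grid, mu_s[[i]])]
  }
  r_m <- lam_m - mu_m
  smry <- function(mat) {
    lo <- hi <- numeric(g)
    for (j in seq_len(g)) {
      h <- hpd_interval(mat[, j], mass)
      lo[j] <- h[1]; hi[j] <- h[2]
    }
    list(mean = colMeans(mat), lo = lo, hi = hi)
  }
  a <- smry(lam_m); b <- smry(mu_m); r <- smry(r_m)
  out <- data.frame(time = grid,
                    lam_mean = a$mean, lam_lo = a$lo, lam_hi = a$hi,
                    mu_mean = b$mean, mu_lo = b$lo, mu_hi = b$hi,
                    r_mean = r$mean, r_lo = r$lo, r_hi = r$hi)
  class(out) <- c("rtt_summary", "data.frame")
  out
}

# bins partitioning the window: data.frame(old, young), oldest first
#' @noRd
make_bins <- function(window, bin_width) {
  if (bin_width <= 0) lr_stop("bin width must be > 0")
  edges <- seq(window[1], window[2], by = -bin_width)
  if (utils::tail(edges, 1) > window[2]) edges <- c(edges, window[2])
  data.frame(old = edges[-length(edges)], young = edges[-1])
}

#' Posterior frequency of rate shifts per time bin
#'
#' For each bin, the fraction of post-burn-in posterior samples
#' containing at least one rate shift inside the bin (bins are
#' `(young, old]` half-open intervals partitioning the window).
#'
#' @param logs one `posterior_log` or a list of replicates.
#' @param bin_width bin width in time units (default 1).
#' @param burn_in burn-in fraction (default 0.1).
#' @param which `"lam"` or `"mu"`: which rate model's shifts to count.
#' @return `data.frame` with columns `old`, `young`, `mid`, `freq`, and
#'   attribute `n_samples`.
#' @export
shift_frequency <- function(logs, bin_width = 1, burn_in = 0.1,
                            which = c("lam", "mu")) {
  which <- match.arg(which)
  pool <- pool_samples(logs, burn_in)
  s <- pool$samples
  bins <- make_bins(pool$window, bin_width)
  col <- if (which == "lam") s$lam_shifts else s$mu_shifts
  shifts <- parse_semi(col)
  freq <- numeric(nrow(bins))
  for (b in seq_len(nrow(bins))) {
    freq[b] <- mean(vapply(shifts, function(sh)
      any(sh <= bins$old[b] & sh > bins$young[b]), logical(1)))
  }
  out <- data.frame(old = bins$old, young = bins$young,
                    mid = (bins$old + bins$young) / 2, freq = freq)
  attr(out, "n_samples") <- nrow(s)
  out
}

#' Prior frequency of rate shifts per time bin
#'
#' Direct simulation from the prior: shift counts are Poisson with the
#' prior mean, shift times uniform over the window; reports the per-bin
#' frequency of at least one shift. (Closed form: with a Poisson(`nu`)
#' shift count and uniform times, the count in a bin of width `w` is
#' Poisson(`nu w / W`), so the frequency is `1 - exp(-nu w / W)`.)
#'
#' @param priors a [bd_priors()] object (uses `shift_rate`).
#' @param window `c(t_old, t_young)`.
#' @param bin_width bin width (default 1).
#' @param n_sim number of prior simulations (default 1e4).
#' @return `data.frame` as in [shift_frequency()], with attribute
#'   `n_samples = n_sim`.
#' @export
prior_shift_frequency <- function(priors, window, bin_width = 1,
                                  n_sim = 1e4) {
  if (n_sim < 1) lr_stop("n_sim must be >= 1")
  check_window(window)
  bins <- make_bins(window, bin_width)
  counts <- numeric(nrow(bins))
  m <- stats::rpois(n_sim, priors$shift_rate)
  times <- stats::runif(sum(m), window[2], window[1])
  grp <- rep.int(seq_len(n_sim), m)
  for (b in seq_len(nrow(bins))) {
    inbin <- times <= bins$old[b] & times > bins$young[b]
    counts[b] <- length(unique(grp[inbin]))
  }
  out <- data.frame(old = bins$old, young = bins$young,
                    mid = (bins$old + bins$young) / 2,
                    freq = counts / n_sim)
  attr(out, "n_samples") <- n_sim
  out
}

#' Per-bin Bayes factors for rate shifts
#'
#' Compares the posterior and prior per-bin frequencies of at least one
#' shift on the log-odds scale:
#' `2logBF = 2 [ log(f_post / (1 - f_post)) - log(f_prior / (1 - f_prior)) ]`.
#' Frequencies are clamped to `[1/(n+1), 1 - 1/(n+1)]` (with `n` the
#' sample count behind each frequency) to avoid infinities. Thresholds: a
#' value of at least 2 is labeled `"positive"`, at least 6 `"strong"`.
#'
#' @param post_freq output of [shift_frequency()].
#' @param prior_freq output of [prior_shift_frequency()] on the same
#'   bins.
#' @return `data.frame` with columns `old`, `young`, `mid`,
#'   `freq_post`, `freq_prior`, `two_log_bf`, `support`.
#' @export
bayes_factor_bins <- function(post_freq, prior_freq) {
  if (nrow(post_freq) != nrow(prior_freq) ||
      !isTRUE(all.equal(post_freq$old, prior_freq$old)))
    lr_stop("posterior and prior frequencies must share the same bins")
  clamp <- function(f, n) pmin(pmax(f, 1 / (n + 1)), 1 - 1 / (n + 1))
  fp <- clamp(post_freq$freq, attr(post_freq, "n_samples") %||% 1e4)
  fq <- clamp(prior_freq$freq, attr(prior_freq, "n_samples") %||% 1e4)
  blog <- 2 * (log(fp / (1 - fp)) - log(fq / (1 - fq)))
  support <- ifelse(blog >= 6, "strong",
                    ifelse(blog >= 2, "positive", ""))
  data.frame(old = post_freq$old, young = post_freq$young,
             mid = post_freq$mid, freq_post = post_freq$freq,
             freq_prior = prior_freq$freq, two_log_bf = blog,
             support = support, stringsAsFactors = FALSE)
}

#' Write a rates-through-time summary as TSV
#'
#' @param x an [rtt_summary()] or [bayes_factor_bins()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Three-panel diversification summary plot
#'
#' Reproduces the standard layout: (A) origination and extinction rates
#' through time with HPD shading, (B) net diversification with a zero
#' line, (C) per-bin shift frequency with the 2logBF = 2 and 6 support
#' thresholds mapped back to frequency space.
#'
#' @param rtt an [rtt_summary()].
#' @param shifts output of [shift_frequency()] (optional; panel C is
#'   skipped when `NULL`).
#' @param prior_freq output of [prior_shift_frequency()] matching
#'   `shifts` (used for the threshold lines; optional).
#' @param file optional path; when given, a PDF is written.
#' @return `NULL`, invisibly.
#' @export
plot_diversification <- function(rtt, shifts = NULL, prior_freq = NULL,
                                 file = NULL) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 9)
    on.exit(grDevices::dev.off())
  }
  panels <- 2 + !is.null(shifts)
  op <- graphics::par(mfrow = c(panels, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  xl <- rev(range(rtt$time))
  band <- function(t, lo, hi, col)
    graphics::polygon(c(t, rev(t)), c(lo, rev(hi)), col = col, border = NA)
  graphics::plot(rtt$time, rtt$lam_mean, type = "n", xlim = xl,
                 ylim = range(0, rtt$lam_hi, rtt$mu_hi),
                 xlab = "time before reference", ylab = "rate",
                 main = "origination (blue) and extinction (red)")
  band(rtt$time, rtt$lam_lo, rtt$lam_hi,
       grDevices::adjustcolor("steelblue", 0.3))
  band(rtt$time, rtt$mu_lo, rtt$mu_hi,
       grDevices::adjustcolor("firebrick", 0.3))
  graphics::lines(rtt$time, rtt$lam_mean, col = "steelblue", lwd = 2)
  graphics::lines(rtt$time, rtt$mu_mean, col = "firebrick", lwd = 2)
  graphics::plot(rtt$time, rtt$r_mean, type = "n", xlim = xl,
                 ylim = range(rtt$r_lo, rtt$r_hi, 0),
                 xlab = "time before reference",
                 ylab = "net diversification", main = "net diversification")
  band(rtt$time, rtt$r_lo, rtt$r_hi, grDevices::adjustcolor("grey40", 0.3))
  graphics::lines(rtt$time, rtt$r_mean, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  if (!is.null(shifts)) {
    graphics::plot(shifts$mid, shifts$freq, type = "h", xlim = xl,
                   ylim = c(0, max(shifts$freq, 0.1)), lwd = 2,
                   xlab = "time before reference",
                   ylab = "shift frequency", main = "rate-shift support")
    if (!is.null(prior_freq)) {
      # frequency giving 2logBF = 2 and 6 against the mean prior odds
      fq <- mean(prior_freq$freq)
      odds <- fq / (1 - fq)
      thr <- function(b) { o <- odds * exp(b / 2); o / (1 + o) }
      graphics::abline(h = thr(2), lty = 3)
      graphics::abline(h = thr(6), lty = 3)
    }
  }
  invisible(NULL)
}
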