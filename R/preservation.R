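# Preservation models: the sampled occurrences of a lineage alive on
# [te, ts] are modeled as a Poisson process with intensity q(t)
# (occurrences per lineage per time unit). All likelihoods condition on
# the lineage being observed at least once (the -log(1 - exp(-Lambda))
# term), since never-sampled lineages cannot enter the data, and treat
# occurrence times as ordered (no k! term; constant in the parameters).
#
# Three intensity shapes:
#   HPP  - q(t) = q, constant through the lifespan;
#   NHPP - q(t) = q * dbeta((ts - t)/s; a, b), a bell over the lifespan
#          (lower near origination and extinction for a, b > 1), with
#          integral q * s over the lifespan s = ts - te;
#   TPP  - q(t) piecewise constant across fixed epochs.

#' Homogeneous-Poisson preservation log-likelihood
#'
#' One lineage with `k >= 1` occurrences over lifespan `s` under constant
#' preservation rate `q`, conditioned on at least one occurrence:
#' `k log(q) - q s - log(1 - exp(-q s))`.
#'
#' @param k number of occurrences (>= 1); vectorized.
#' @param s lifespan (> 0); vectorized.
#' @param q preservation rate (> 0).
#' @return log-likelihood, summed over the supplied lineages.
#' @export
hpp_loglik <- function(k, s, q) {
  if (any(k < 1)) lr_stop("k must be >= 1 (unobserved lineages carry no term)")
  if (any(s <= 0) || q <= 0) lr_stop("need s > 0 and q > 0")
  sum(k * log(q) - q * s - log1mexp(q * s))
}

# log(1 - exp(-x)) for x > 0, stable near both ends
#' @noRd
log1mexp <- function(x) {
  ifelse(x > log(2), log1p(-exp(-x)), log(-expm1(-x)))
}

#' Bell-shaped (extended-beta) preservation log-likelihood
#'
#' Non-homogeneous Poisson process over a lineage's lifespan with
#' intensity `q(t) = q * dbeta(u; shape_a, shape_b)` where
#' `u = (ts - t)/s` is the relative position in the lifespan
#' `s = ts - te` (u = 0 at origination). The integrated intensity over the
#' lifespan is `q * s`. Reduces exactly to [hpp_loglik()] at
#' `shape_a = shape_b = 1`.
#'
#' @param occ_ages occurrence ages (times before reference) within
#'   `[te, ts]`.
#' @param ts,te origination and extinction times, `ts > te`.
#' @param q base preservation rate (> 0).
#' @param shape_a,shape_b beta shape parameters (> 0); `a = b = 2` is a
#'   symmetric bell.
#' @return log-likelihood (scalar, one lineage).
#' @export
nhpp_loglik <- function(occ_ages, ts, te, q, shape_a = 2, shape_b = 2) {
  if (ts <= te) lr_stop("need ts > te")
  if (q <= 0 || shape_a <= 0 || shape_b <= 0)
    lr_stop("need q, shape_a, shape_b > 0")
  bad <- which(occ_ages > ts | occ_ages < te)
  if (length(bad))
    lr_stop("occurrence(s) outside [te, ts] at position(s): ",
            paste(bad, collapse = ", "))
  s <- ts - te
  u <- (ts - occ_ages) / s
  sum(log(q) + stats::dbeta(u, shape_a, shape_b, log = TRUE)) -
    q * s - log1mexp(q * s)
}

#' Epoch-piecewise (time-variable) preservation log-likelihood
#'
#' Preservation rate is piecewise constant across fixed epochs: rate
#' `q_vec[i]` applies in epoch i, where epochs are delimited by the
#' strictly decreasing `epoch_bounds` (times before reference; epoch 1 is
#' everything older than `epoch_bounds[1]`). The integrated intensity is
#' `Lambda = sum_i q_i * overlap(lifespan, epoch i)`.
#'
#' @param occ_ages occurrence ages within `[te, ts]`.
#' @param ts,te origination and extinction times, `ts > te`.
#' @param q_vec positive rates, one per epoch
#'   (`length(q_vec) == length(epoch_bounds) + 1`).
#' @param epoch_bounds strictly decreasing interior epoch boundaries (may
#'   be empty: single epoch, identical to [hpp_loglik()]).
#' @return log-likelihood (scalar, one lineage).
#' @export
tpp_loglik <- function(occ_ages, ts, te, q_vec, epoch_bounds = numeric(0)) {
  if (ts <= te) lr_stop("need ts > te")
  if (length(q_vec) != length(epoch_bounds) + 1L)
    lr_stop("need one rate per epoch")
  if (any(q_vec <= 0)) lr_stop("rates must be > 0")
  if (length(epoch_bounds) && is.unsorted(rev(epoch_bounds), strictly = TRUE))
    lr_stop("epoch_bounds must be strictly decreasing")
  bad <- which(occ_ages > ts | occ_ages < te)
  if (length(bad))
    lr_stop("occurrence(s) outside [te, ts] at position(s): ",
            paste(bad, collapse = ", "))
  old <- c(Inf, epoch_bounds)
  yng <- c(epoch_bounds, -Inf)
  ovl <- pmax(0, pmin(ts, old) - pmax(te, yng))
  Lam <- sum(q_vec * ovl)
  idx <- interval_index(occ_ages, epoch_bounds)
  sum(log(q_vec[idx])) - Lam - log1mexp(Lam)
}

#' Mean-one discretized gamma rate multipliers
#'
#' Category means of `n_cat` equal-probability bins of a Gamma
#' distribution with shape and rate both `alpha` (mean 1). Used to model
#' preservation-rate heterogeneity across lineages.
#'
#' @param alpha gamma shape (> 0); large `alpha` collapses to 1.
#' @param n_cat number of categories (default 4).
#' @return numeric vector of `n_cat` multipliers with mean 1.
#' @export
gamma_categories <- function(alpha, n_cat = 4) {
  if (alpha <= 0 || n_cat < 1) lr_stop("need alpha > 0 and n_cat >= 1")
  if (n_cat == 1) return(1)
  p <- seq(0, 1, length.out = n_cat + 1)
  edges <- stats::qgamma(p, shape = alpha, rate = alpha)
  # E[X; bin] for Gamma(a, a): (F_{a+1}(hi) - F_{a+1}(lo)); bin prob 1/n
  up <- stats::pgamma(edges[-1], shape = alpha + 1, rate = alpha)
  lo <- stats::pgamma(edges[-length(edges)], shape = alpha + 1, rate = alpha)
  m <- n_cat * (up - lo)
  m / mean(m)  # exact mean 1 against discretization round-off
}

#' Gamma-heterogeneity mixture log-likelihood
#'
#' Averages each lineage's likelihood over the discretized gamma rate
#' multipliers and sums the per-lineage log-averages.
#'
#' @param per_lineage_loglik_fn function(multiplier) returning the vector
#'   of per-lineage log-likelihoods when every lineage's base rate is
#'   scaled by `multiplier`.
#' @param alpha gamma shape (> 0).
#' @param n_cat number of discretization categories (default 4).
#' @return total log-likelihood over lineages.
#' @export
gamma_mixture_loglik <- function(per_lineage_loglik_fn, alpha, n_cat = 4) {
  m <- gamma_categories(alpha, n_cat)
  ll <- vapply(m, per_lineage_loglik_fn,
               numeric(length(per_lineage_loglik_fn(1))))
  if (is.null(dim(ll))) ll <- matrix(ll, nrow = 1)
  sum(apply(ll, 1, logmeanexp))
}

# per-lineage working arrays used by fitting and by the sampler:
# k (count), s (lifespan), and, for NHPP, the summed log-beta term
#' @noRd
pres_lineage_data <- function(occ, ts, te) {
  ages <- ages_by_lineage(occ)
  ids <- names(ages)
  if (is.null(names(ts))) names(ts) <- ids
  if (is.null(names(te))) names(te) <- ids
  list(ids = ids, ages = ages,
       k = vapply(ages, length, integer(1)),
       ts = ts[ids], te = te[ids])
}

#' Maximum-likelihood fit of a preservation model
#'
#' Fits one of the three preservation models to an occurrence set with
#' assigned per-lineage origination/extinction times, by numerical
#' maximization on the log-parameter scale from multiple start points.
#' When `ts`/`te` are not supplied, the observed occurrence span of each
#' lineage is used as a plug-in lifespan (appropriate for the model-test
#' step of the workflow; the joint treatment of latent times lives in
#' [run_chain()]).
#'
#' @param occ an [occurrence_set()] with calendar ages.
#' @param kind `"HPP"`, `"NHPP"` or `"TPP"`.
#' @param ts,te optional named vectors of per-lineage origination and
#'   extinction times; default: observed span (with a small symmetric pad
#'   of half the mean occurrence gap so that point spans have positive
#'   length).
#' @param epoch_bounds fixed epoch boundaries (TPP only), strictly
#'   decreasing times before reference.
#' @param estimate_shapes if `TRUE` (NHPP) the bell shapes are estimated;
#'   otherwise fixed at `shapes`.
#' @param shapes fixed NHPP shape parameters (default `c(2, 2)`).
#' @param gamma if `TRUE`, estimate a gamma heterogeneity shape `alpha`
#'   (discretized, `n_cat` categories).
#' @param n_cat gamma discretization categories (default 4).
#' @return list of class `"preservation_fit"`: `kind`, `q` (or `q_vec`),
#'   `shapes`, `alpha`, `loglik`, `n_params`, `n_lineages`, `aicc`.
#' @export
fit_preservation_ml <- function(occ, kind = c("HPP", "NHPP", "TPP"),
                                ts = NULL, te = NULL,
                                epoch_bounds = numeric(0),
                                estimate_shapes = FALSE, shapes = c(2, 2),
                                gamma = FALSE, n_cat = 4) {
  kind <- match.arg(kind)
  ages <- ages_by_lineage(occ)
  if (is.null(ts) || is.null(te)) {
    # plug-in lifespan: observed span padded per side by span/(k - 1),
    # the expected overshoot of the true endpoints beyond the extreme
    # order statistics of k uniform occurrence times
    ts <- vapply(ages, max, numeric(1))
    te <- vapply(ages, min, numeric(1))
    k <- vapply(ages, length, integer(1))
    pad <- ifelse(k > 1, (ts - te) / pmax(k - 1, 1),
                  stats::median((ts - te)[k > 1] /
                                  pmax(k[k > 1] - 1, 1), na.rm = TRUE))
    if (all(k <= 1)) pad <- rep(0.5, length(k))
    ts <- ts + pad
    te <- pmax(0, te - pad)
  }
  ld <- pres_lineage_data(occ, ts, te)
  n <- length(ld$ids)
  s <- as.numeric(ld$ts - ld$te)
  if (any(s <= 0)) lr_stop("each lineage needs ts > te")

  per_lineage_ll <- function(q, a = NULL, b = NULL, q_vec = NULL) {
    switch(kind,
      HPP = ld$k * log(q) - q * s - log1mexp(q * s),
      NHPP = {
        u <- mapply(function(ag, tsi, tei) {
          (tsi - ag) / (tsi - tei)
        }, ld$ages, ld$ts, ld$te, SIMPLIFY = FALSE)
        bsum <- vapply(u, function(ui)
          sum(stats::dbeta(pmin(pmax(ui, 0), 1), a, b, log = TRUE)),
          numeric(1))
        ld$k * log(q) + bsum - q * s - log1mexp(q * s)
      },
      TPP = {
        old <- c(Inf, epoch_bounds)
        yng <- c(epoch_bounds, -Inf)
        vapply(seq_len(n), function(i) {
          ovl <- pmax(0, pmin(ld$ts[i], old) - pmax(ld$te[i], yng))
          Lam <- sum(q_vec * ovl)
          idx <- interval_index(ld$ages[[i]], epoch_bounds)
          sum(log(q_vec[idx])) - Lam - log1mexp(Lam)
        }, numeric(1))
      })
  }

  n_epoch <- length(epoch_bounds) + 1L
  q0 <- sum(ld$k) / sum(s)  # moment start
  obj <- function(par) {
    # par on log scale: q (or q_vec), then shapes, then alpha
    i <- 0L
    if (kind == "TPP") {
      q_vec <- exp(par[seq_len(n_epoch)]); i <- n_epoch
      base <- function(m) per_lineage_ll(q_vec = q_vec * m)
    } else if (kind == "NHPP") {
      q <- exp(par[1]); i <- 1L
      if (estimate_shapes) {
        a <- exp(par[2]); b <- exp(par[3]); i <- 3L
      } else { a <- shapes[1]; b <- shapes[2] }
      base <- function(m) per_lineage_ll(q * m, a, b)
    } else {
      q <- exp(par[1]); i <- 1L
      base <- function(m) per_lineage_ll(q * m)
    }
    ll <- if (gamma) {
      alpha <- exp(par[i + 1L])
      gamma_mixture_loglik(base, alpha, n_cat)
    } else sum(base(1))
    if (!is.finite(ll)) ll <- -1e300
    -ll
  }

  n_par <- switch(kind, HPP = 1L, NHPP = if (estimate_shapes) 3L else 1L,
                  TPP = n_epoch) + as.integer(gamma)
  starts <- lapply(c(0.3, 1, 3), function(f) {
    p <- log(rep(q0 * f, if (kind == "TPP") n_epoch else 1))
    if (kind == "NHPP" && estimate_shapes) p <- c(p, log(2), log(2))
    if (gamma) p <- c(p, log(2))
    p
  })
  fits <- lapply(starts, function(p0) {
    tryCatch(
      if (length(p0) == 1L)
        stats::optim(p0, obj, method = "Brent",
                     lower = p0 - 15, upper = p0 + 15)
      else stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10)),
      error = function(e) NULL)
  })
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) lr_stop("preservation ML fit failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  par <- best$par
  out <- list(kind = kind, n_params = n_par, n_lineages = n,
              loglik = -best$value, epoch_bounds = epoch_bounds,
              alpha = NULL, shapes = NULL)
  if (kind == "TPP") {
    out$q_vec <- exp(par[seq_len(n_epoch)]); i <- n_epoch
  } else {
    out$q <- exp(par[1]); i <- 1L
    if (kind == "NHPP") {
      if (estimate_shapes) {
        out$shapes <- exp(par[2:3]); i <- 3L
      } else out$shapes <- shapes
    }
  }
  if (gamma) out$alpha <- exp(par[i + 1L])
  out$aicc <- if (n > n_par + 1) aicc(out$loglik, n_par, n) else NA_real_
  class(out) <- "preservation_fit"
  out
}

#' @export
print.preservation_fit <- function(x, ...) {
  rates <- if (!is.null(x$q_vec)) paste(signif(x$q_vec, 5), collapse = ", ")
           else signif(x$q, 5)
  cat(sprintf("%s preservation fit: lnL = %.3f, rate(s) = %s, AICc = %.2f\n",
              x$kind, x$loglik, rates, x$aicc))
  invisible(x)
}

#' Small-sample-corrected Akaike Information Criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k + 1)/(n - k - 1)`, with `n` the number of
#' analyzed lineages.
#'
#' @param lnL maximized log-likelihood.
#' @param k_params number of free parameters.
#' @param n number of lineages; must exceed `k_params + 1`.
#' @return AICc value.
#' @export
aicc <- function(lnL, k_params, n) {
  if (n <= k_params + 1) lr_stop("AICc needs n > k_params + 1")
  -2 * lnL + 2 * k_params + 2 * k_params * (k_params + 1) / (n - k_params - 1)
}

#' Preservation model-selection report
#'
#' Ranks fitted preservation models by AICc and reports the AICc
#' difference to the best model with significance flags at differences of
#' 2 (`*`), 6 (`**`) and 10 (`***`).
#'
#' @param fits either a list of [fit_preservation_ml()] results, or a
#'   `data.frame` with columns `model` and `aicc` (and optionally `lnL`
#'   and `rates`).
#' @return `data.frame` with columns `model`, `lnL`, `rates`, `aicc`,
#'   `daicc`, `support`, sorted ascending by AICc (ties broken by model
#'   name).
#' @export
model_selection_report <- function(fits) {
  if (is.data.frame(fits)) {
    tab <- fits
    if (is.null(tab$model) || is.null(tab$aicc))
      lr_stop("data.frame input needs columns model and aicc")
    if (is.null(tab$lnL)) tab$lnL <- NA_real_
    if (is.null(tab$rates)) tab$rates <- NA_character_
  } else {
    if (length(fits) < 2) lr_stop("need at least 2 fits to compare")
    tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(model = f$kind, lnL = f$loglik,
                 rates = if (!is.null(f$q_vec))
                   paste(signif(f$q_vec, 6), collapse = ",")
                 else as.character(signif(f$q, 6)),
                 aicc = f$aicc, stringsAsFactors = FALSE)
    }))
  }
  tab <- tab[order(tab$aicc, tab$model), , drop = FALSE]
  tab$daicc <- tab$aicc - tab$aicc[1]
  tab$support <- cut(tab$daicc, c(-Inf, 2, 6, 10, Inf),
                     labels = c("", "*", "**", "***"), right = FALSE)
  tab$support <- as.character(tab$support)
  tab$support[1] <- "-"
  rownames(tab) <- NULL
  tab[, c("model", "lnL", "rates", "aicc", "daicc", "support")]
}

#' Write a model-selection report as TSV
#'
#' Columns mirror the standard preservation-test table: Model, Maximum
#' Likelihood, Preservation Rate(s), AICc, dAICc.
#'
#' @param report output of [model_selection_report()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_selection_report <- function(report, path) {
  out <- data.frame(Model = report$model,
                    `Maximum Likelihood` = report$lnL,
                    `Preservation Rate(s)` = report$rates,
                    AICc = report$aicc,
                    dAICc = paste0(ifelse(report$support == "-", "-",
                                          report$daicc),
                                   ifelse(report$support %in% c("-", ""),
                                          "", report$support)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
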