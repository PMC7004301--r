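# internal numeric helpers

#' @importFrom stats runif rnorm rexp dnorm dpois dexp rpois rgamma rbeta
#'   dbeta dgamma qgamma pgamma approx optim setNames median
NULL

#' @noRd
logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

# fold x into [lo, hi] by reflection at both edges; symmetric as a
# proposal kernel
#' @noRd
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  if (w <= 0) return(rep(lo, length(x)))
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a consistent prefix, no call
#' @noRd
lr_stop <- function(...) stop(..., call. = FALSE)
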