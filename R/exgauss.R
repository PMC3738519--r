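#' The ex-Gaussian distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the ex-Gaussian distribution: the sum of a Gaussian component with
#' mean `mu` and standard deviation `sigma` and an independent exponential
#' component with mean `tau`. The ex-Gaussian is the standard descriptive
#' family for simple reaction-time distributions: the Gaussian part captures
#' transduction/motor latency, the exponential tail captures decision time.
#'
#' All parameters are in milliseconds here, but the functions are
#' scale-agnostic. `qexgauss()` inverts the CDF by monotone bisection
#' (Brent via [stats::uniroot()]) since no closed form exists.
#'
#' @param x,q vector of quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu mean of the Gaussian component.
#' @param sigma standard deviation of the Gaussian component (> 0).
#' @param tau mean of the exponential component (> 0).
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @return `dexgauss` the density, `pexgauss` the CDF, `qexgauss` the
#'   quantile function, `rexgauss` random deviates.
#' @examples
#' pexgauss(qexgauss(0.25, 300, 30, 60), 300, 30, 60)
#' mean(rexgauss(1e4, 300, 30, 60)) # ~ mu + tau
#' @name exgauss
NULL

#' @rdname exgauss
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma
  # log f(x) = -log tau + (mu - x)/tau + sigma^2/(2 tau^2) + log Phi(z - sigma/tau)
  lf <- -log(tau) + (mu - x) / tau + sigma^2 / (2 * tau^2) +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname exgauss
#' @export
pexgauss <- function(q, mu, sigma, tau, log.p = FALSE) {
  stopifnot(sigma > 0, tau > 0)
  z <- (q - mu) / sigma
  # F(x) = Phi(z) - exp(sigma^2/(2 tau^2) - (x - mu)/tau + log Phi(z - sigma/tau))
  corr <- exp(sigma^2 / (2 * tau^2) - (q - mu) / tau +
                stats::pnorm(z - sigma / tau, log.p = TRUE))
  val <- stats::pnorm(z) - corr
  val <- pmin(pmax(val, 0), 1) # guard against roundoff at the tails
  if (log.p) log(val) else val
}

#' @rdname exgauss
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0, all(p > 0 & p < 1))
  # moment-matched normal start, then safeguarded Newton on the CDF
  x <- mu + tau + sqrt(sigma^2 + tau^2) * stats::qnorm(p)
  cap <- 4 * (sigma + tau)
  for (it in 1:60) {
    f <- pexgauss(x, mu, sigma, tau) - p
    if (max(abs(f)) < 1e-13) break
    step <- f / pmax(dexgauss(x, mu, sigma, tau), 1e-300)
    x <- x - pmin(pmax(step, -cap), cap)
  }
  bad <- which(abs(pexgauss(x, mu, sigma, tau) - p) > 1e-9)
  for (i in bad) { # bisection fallback for pathological tails
    lo <- mu + sigma * stats::qnorm(p[i])
    hi <- lo + tau * stats::qexp(p[i]) + tau
    while (pexgauss(hi, mu, sigma, tau) < p[i]) hi <- hi + tau
    x[i] <- stats::uniroot(function(z) pexgauss(z, mu, sigma, tau) - p[i],
                           lower = lo - 1e-9, upper = hi, tol = 1e-10)$root
  }
  x
}

#' @rdname exgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}
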