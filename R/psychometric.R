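#' Lapse-contaminated logistic psychometric function
#'
#' Probability of a "visual-first" response as a function of the SOA x:
#' \deqn{\Psi(x) = \lambda_A + (1 - \lambda_A - \lambda_V)\,F(x;\mu,\sigma)}
#' where F is the logistic CDF with location `mu` and shape `sigma`,
#' `lambda_a` is the lapse rate at large auditory-leading (negative) SOAs
#' and `lambda_v` the lapse rate at large visual-leading (positive) SOAs.
#' Lapses are stimulus-independent errors (attention slips, response
#' errors): they pin the asymptotes at `lambda_a` and `1 - lambda_v`
#' instead of 0 and 1.
#'
#' @param x SOA in ms (vectorized).
#' @param params list/vector with `mu`, `sigma` (> 0), `lambda_a`,
#'   `lambda_v` (each in \[0, 1) with `lambda_a + lambda_v < 1`).
#' @return Probabilities in `(lambda_a, 1 - lambda_v)`.
#' @export
psi <- function(x, params) {
  p <- as.list(params)
  stopifnot(p$sigma > 0, p$lambda_a >= 0, p$lambda_v >= 0,
            p$lambda_a + p$lambda_v < 1)
  p$lambda_a + (1 - p$lambda_a - p$lambda_v) *
    stats::plogis(x, location = p$mu, scale = p$sigma)
}

#' Prior specification for the psychometric parameters
#'
#' Defaults encode weak, generally accepted assumptions: lapse rates are
#' small but rarely exactly zero (Beta(2, 20), mode 0.05); the location is
#' roughly centred on physical simultaneity but varies widely across
#' observers (Normal(0, 200) ms); the shape is positive and otherwise
#' nearly unconstrained (Gamma with shape 1.05 and scale 1000, a nearly
#' flat density with mode at 50 ms).
#'
#' @param lapse_shape1,lapse_shape2 Beta shape parameters for both lapse
#'   rates.
#' @param mu_mean,mu_sd Normal prior on the location, ms.
#' @param sigma_shape,sigma_scale Gamma prior on the shape parameter
#'   (shape-scale parameterization), ms.
#' @return List of class `prior_spec`.
#' @export
prior_spec <- function(lapse_shape1 = 2, lapse_shape2 = 20,
                       mu_mean = 0, mu_sd = 200,
                       sigma_shape = 1.05, sigma_scale = 1000) {
  structure(list(lapse_shape1 = lapse_shape1, lapse_shape2 = lapse_shape2,
                 mu_mean = mu_mean, mu_sd = mu_sd,
                 sigma_shape = sigma_shape, sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' Unnormalized log posterior of the psychometric parameters
#'
#' Binomial likelihood over the TOJ count table plus the log prior
#' densities. Rows with `n = 0` contribute nothing. Returns `-Inf` outside
#' the parameter domain (`sigma <= 0`, lapse rates outside \[0, 1) or
#' summing to 1 or more), so samplers can treat the domain by rejection.
#'
#' @param params named vector/list with `mu`, `sigma`, `lambda_a`,
#'   `lambda_v`.
#' @param toj a [toj_table()].
#' @param priors a [prior_spec()].
#' @param include_binom_coef include the (constant) log binomial
#'   coefficients (default TRUE; irrelevant to sampling).
#' @return Scalar log density up to an additive constant.
#' @export
log_posterior_unnorm <- function(params, toj, priors = prior_spec(),
                                 include_binom_coef = TRUE) {
  p <- as.list(params)
  if (!is.finite(p$mu) || !is.finite(p$sigma) || p$sigma <= 0 ||
      p$lambda_a < 0 || p$lambda_v < 0 || p$lambda_a >= 1 || p$lambda_v >= 1 ||
      p$lambda_a + p$lambda_v >= 1) return(-Inf)
  prob <- p$lambda_a + (1 - p$lambda_a - p$lambda_v) *
    stats::plogis(toj$soa, location = p$mu, scale = p$sigma)
  ll <- sum(toj$visual_first * log(prob) + (toj$n - toj$visual_first) * log1p(-prob))
  if (include_binom_coef)
    ll <- ll + sum(lchoose(toj$n, toj$visual_first))
  lp <- stats::dnorm(p$mu, priors$mu_mean, priors$mu_sd, log = TRUE) +
    stats::dgamma(p$sigma, shape = priors$sigma_shape,
                  scale = priors$sigma_scale, log = TRUE) +
    stats::dbeta(p$lambda_a, priors$lapse_shape1, priors$lapse_shape2, log = TRUE) +
    stats::dbeta(p$lambda_v, priors$lapse_shape1, priors$lapse_shape2, log = TRUE)
  ll + lp
}

#' Slice-sample the posterior of the psychometric parameters
#'
#' Coordinate-wise univariate slice sampling over (mu, sigma, lambda_a,
#' lambda_v). Each raw iteration updates every coordinate once with a
#' stepping-out slice sampler (Neal 2003: step out until the interval
#' brackets the slice, then shrink on rejection) whose initial width is the
#' coordinate's prior standard deviation. The first `burn_in` raw
#' iterations are discarded and the chain is thinned by `thin`, so
#' `burn_in + thin * n_samples` raw iterations produce `n_samples` retained
#' draws. The inner loop runs in compiled code against the same
#' unnormalized posterior as [log_posterior_unnorm()] and uses R's RNG, so
#' the run is deterministic given the RNG state (set a seed beforehand).
#'
#' @param toj a [toj_table()] with at least two rows with `n > 0`.
#' @param priors a [prior_spec()].
#' @param n_samples retained posterior draws (default 2000).
#' @param burn_in discarded initial iterations (default 100).
#' @param thin keep every `thin`-th iteration after burn-in (default 10).
#' @param init initial parameter values (default: the prior modes,
#'   mu = 0, sigma = 50, lapse rates 0.05).
#' @return Object of class `posterior_samples`: list with `draws`
#'   (n_samples x 4 matrix, columns mu/sigma/lambda_a/lambda_v) and
#'   `diagnostics` (lag-1 autocorrelation per parameter, schedule).
#' @export
slice_sample_posterior <- function(toj, priors = prior_spec(),
                                   n_samples = 2000, burn_in = 100, thin = 10,
                                   init = c(mu = 0, sigma = 50,
                                            lambda_a = 0.05, lambda_v = 0.05)) {
  stopifnot(inherits(toj, "toj_table"))
  if (sum(toj$n > 0) < 2L)
    stop("need at least two SOAs with trials to fit the psychometric function")
  lshape1 <- priors$lapse_shape1; lshape2 <- priors$lapse_shape2
  # slice widths: prior standard deviations
  beta_sd <- sqrt(lshape1 * lshape2 /
                    ((lshape1 + lshape2)^2 * (lshape1 + lshape2 + 1)))
  w <- c(priors$mu_sd, sqrt(priors$sigma_shape) * priors$sigma_scale,
         beta_sd, beta_sd)
  draws <- cpp_slice_sample(
    as.numeric(toj$soa), as.numeric(toj$visual_first), as.numeric(toj$n),
    priors$mu_mean, priors$mu_sd, priors$sigma_shape, priors$sigma_scale,
    lshape1, lshape2,
    as.integer(n_samples), as.integer(burn_in), as.integer(thin),
    as.numeric(init[c("mu", "sigma", "lambda_a", "lambda_v")]), w)
  ac1 <- apply(draws, 2, function(v) {
    if (stats::sd(v) == 0) return(0)
    stats::cor(v[-1], v[-length(v)])
  })
  structure(list(draws = draws,
                 diagnostics = list(lag1_autocorrelation = ac1,
                                    burn_in = burn_in, thin = thin,
                                    n_raw_iterations = burn_in + thin * n_samples)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  med <- apply(x$draws, 2, stats::median)
  cat(sprintf("<posterior_samples> %d draws; medians: mu=%.1f sigma=%.1f la=%.3f lv=%.3f\n",
              nrow(x$draws), med["mu"], med["sigma"],
              med["lambda_a"], med["lambda_v"]))
  invisible(x)
}

#' Above-chance performance thresholds of the psychometric function
#'
#' The auditory-first threshold is the SOA where performance is halfway
#' between the auditory-side lapse rate and 0.5, i.e.
#' \eqn{\Psi = (\lambda_A + 0.5)/2}; the visual-first threshold is halfway
#' between 0.5 and the visual-side asymptote, \eqn{\Psi = (1.5 - \lambda_V)/2}.
#' With no lapses these are the 25% and 75% points. Solved in closed form
#' through the logistic inverse \eqn{x = \mu + \sigma \log(q/(1-q))} with
#' \eqn{q = (\mathrm{target} - \lambda_A)/(1 - \lambda_A - \lambda_V)}.
#'
#' @param params psychometric parameters (as in [psi()]).
#' @return Named numeric vector `c(auditory = thr_A, visual = thr_V)` in ms.
#' @export
thresholds <- function(params) {
  p <- lapply(as.list(params), unname)
  targets <- c(auditory = (p$lambda_a + 0.5) / 2,
               visual = (0.5 + 1 - p$lambda_v) / 2)
  q <- (targets - p$lambda_a) / (1 - p$lambda_a - p$lambda_v)
  p$mu + p$sigma * log(q / (1 - q))
}

# thresholds for every posterior draw: n x 2 matrix (closed form, vectorized)
thresholds_draws <- function(samples) {
  d <- samples$draws
  la <- d[, "lambda_a"]; lv <- d[, "lambda_v"]
  denom <- 1 - la - lv
  qa <- ((la + 0.5) / 2 - la) / denom
  qv <- ((1.5 - lv) / 2 - la) / denom
  cbind(auditory = d[, "mu"] + d[, "sigma"] * log(qa / (1 - qa)),
        visual = d[, "mu"] + d[, "sigma"] * log(qv / (1 - qv)))
}

#' TOJ-defined temporal window of integration
#'
#' Thresholds are computed for every posterior draw; the auditory-first
#' boundary is estimated as the 5th percentile of the auditory-threshold
#' draws (the true threshold has probability 0.05 of being more negative)
#' and the visual-first boundary as the 95th percentile of the
#' visual-threshold draws. These are deliberately conservative (widest)
#' boundaries. Percentiles use linear-interpolation order statistics
#' ([stats::quantile()] type 7).
#'
#' @param samples a `posterior_samples` object.
#' @return Object of class `toj_twi`: list with `threshold_a`,
#'   `threshold_v`, `width`.
#' @export
toj_twi <- function(samples) {
  thr <- thresholds_draws(samples)
  a <- unname(stats::quantile(thr[, "auditory"], 0.05, type = 7))
  v <- unname(stats::quantile(thr[, "visual"], 0.95, type = 7))
  structure(list(threshold_a = a, threshold_v = v, width = v - a),
            class = "toj_twi")
}

#' @export
print.toj_twi <- function(x, ...) {
  cat(sprintf("<toj_twi> [%.1f, %.1f] ms (width %.1f)\n",
              x$threshold_a, x$threshold_v, x$width))
  invisible(x)
}

#' Exclude participants who never reach threshold performance
#'
#' A participant whose fitted auditory-first boundary lies below the most
#' negative tested SOA, or whose visual-first boundary lies above the most
#' positive one, never reached the threshold level of performance on that
#' side within the tested range and cannot contribute a TOJ-defined window.
#'
#' @param twi a [toj_twi()].
#' @param soa_range tested SOA range in ms (default c(-400, 400)).
#' @return List with `keep` (logical) and `reason` (`NA` or which side
#'   failed).
#' @export
exclude_nonperformers <- function(twi, soa_range = c(-400, 400)) {
  fail_a <- twi$threshold_a < soa_range[1]
  fail_v <- twi$threshold_v > soa_range[2]
  reason <- if (fail_a && fail_v) "both sides"
    else if (fail_a) "auditory-first side"
    else if (fail_v) "visual-first side"
    else NA_character_
  list(keep = !(fail_a || fail_v), reason = reason)
}

#' Group psychometric function from per-participant posteriors
#'
#' Each participant is summarized by the per-parameter medians of their
#' posterior draws; the group curve is the psychometric function at the
#' arithmetic mean of those medians, and the group thresholds are the
#' thresholds of that mean curve. Intended as an illustrative group
#' summary; inference is at the individual level.
#'
#' @param per_participant nonempty list of `posterior_samples`.
#' @return List with `params` (group-mean parameters), `thresholds`, and
#'   `participant_medians` (matrix, one row per participant).
#' @export
group_psychometric <- function(per_participant) {
  if (!length(per_participant)) stop("no participants supplied")
  med <- t(vapply(per_participant,
                  function(s) apply(s$draws, 2, stats::median),
                  numeric(4)))
  m <- colMeans(med)
  params <- list(mu = m[["mu"]], sigma = m[["sigma"]],
                 lambda_a = m[["lambda_a"]], lambda_v = m[["lambda_v"]])
  list(params = params, thresholds = thresholds(params),
       participant_medians = med)
}
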