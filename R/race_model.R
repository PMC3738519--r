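#' Empirical quantile function of an RT sample
#'
#' Builds the continuous piecewise-linear empirical CDF/quantile function of
#' a reaction-time sample under the (i - 0.5)/n plotting-position
#' convention: the i-th order statistic of the n total trials carries
#' cumulative probability (i - 0.5)/n. Infinite latencies (misses, killed
#' twins) count toward n but never appear among the finite order statistics,
#' so they load the upper tail only: the largest attainable cumulative
#' probability is (m - 0.5)/n with m the number of finite latencies.
#'
#' @param rts a [condition_rts()] or bare numeric vector of latencies
#'   (finite positive and/or `Inf`); at least one finite latency required.
#' @return An object of class `quantile_fun`.
#' @export
empirical_quantile_function <- function(rts) {
  lat <- if (inherits(rts, "condition_rts")) rts$latencies else as.numeric(rts)
  n <- length(lat)
  fin <- sort(lat[is.finite(lat)])
  m <- length(fin)
  if (m == 0L) stop("no finite latencies: quantile function undefined")
  pos <- (seq_len(m) - 0.5) / n
  # CDF knots must have unique abscissae; ties collapse to the largest position
  ux <- unique(fin)
  uy <- pos[!duplicated(fin, fromLast = TRUE)]
  structure(list(lat = fin, pos = pos, cdf_x = ux, cdf_y = uy,
                 n_total = n, n_finite = m),
            class = "quantile_fun")
}

#' Evaluate an empirical quantile function
#'
#' Quantiles are obtained by linear interpolation between adjacent plotting
#' positions. Probabilities below the first plotting position clamp to the
#' minimum latency; probabilities above the last finite plotting position
#' are beyond the finite support (the mass held by infinite latencies).
#'
#' @param qf a `quantile_fun`.
#' @param p probabilities in (0, 1].
#' @param beyond_support what to do for `p` above the last finite plotting
#'   position: `"error"` (default) or `"inf"` (return `Inf`, used when
#'   resampling under the race-model null, where such draws are misses).
#' @return Numeric vector of latencies in ms.
#' @export
quantile_qf <- function(qf, p, beyond_support = c("error", "inf")) {
  beyond_support <- match.arg(beyond_support)
  out <- numeric(length(p))
  pmax_fin <- qf$pos[qf$n_finite]
  over <- p > pmax_fin
  if (any(over)) {
    if (beyond_support == "error")
      stop(sprintf("percentile %.3f beyond finite support (max attainable %.3f)",
                   max(p), pmax_fin))
    out[over] <- Inf
  }
  ok <- !over
  if (any(ok)) {
    pp <- pmax(p[ok], qf$pos[1]) # clamp below the first position
    out[ok] <- if (qf$n_finite == 1L) qf$lat[1] else
      stats::approx(qf$pos, qf$lat, xout = pp, ties = "ordered")$y
  }
  out
}

#' Evaluate the empirical CDF (optionally onset-shifted)
#'
#' Piecewise-linear interpolation through the plotting positions; 0 below
#' the smallest latency, constant at the last finite position above the
#' largest.
#'
#' @param qf a `quantile_fun`.
#' @param t times in ms.
#' @param shift onset delay in ms added to all latencies before evaluation
#'   (used to express a delayed stimulus on the first-onset clock).
#' @return Cumulative probabilities.
#' @export
cdf_qf <- function(qf, t, shift = 0) {
  if (length(qf$cdf_x) == 1L) {
    return(ifelse(t >= qf$cdf_x + shift, qf$cdf_y, 0))
  }
  stats::approx(qf$cdf_x + shift, qf$cdf_y, xout = t,
                yleft = 0, yright = qf$cdf_y[length(qf$cdf_y)],
                ties = "ordered")$y
}

# Onset delays on the first-stimulus clock for a signed SOA
# (negative = auditory first): the trailing stimulus is delayed by |soa|.
soa_delays <- function(soa) {
  c(auditory = max(soa, 0), visual = max(-soa, 0))
}

#' Quantiles of the race-model bound
#'
#' The race-model inequality bounds the multisensory response probability at
#' every latency t (clocked from first-stimulus onset) by the sum of the
#' onset-shifted unisensory response probabilities. This function constructs
#' the bound CDF
#' \deqn{B(t) = \min\{1, P_A(t - \delta_A) + P_V(t - \delta_V)\}}
#' with onset delays \eqn{\delta_A = \max(soa, 0)},
#' \eqn{\delta_V = \max(-soa, 0)}, and returns the earliest time at which B
#' reaches each requested percentile. B is piecewise linear between the
#' merged shifted latencies, so the crossing time is exact linear
#' interpolation on that grid.
#'
#' @param aud,vis `quantile_fun` objects for the auditory-only and
#'   visual-only conditions.
#' @param soa signed SOA in ms (negative = auditory first).
#' @param percentiles probabilities in (0, 0.5].
#' @return Named numeric vector: time in ms at which the bound reaches each
#'   percentile.
#' @export
race_bound_quantiles <- function(aud, vis, soa,
                                 percentiles = c(0.10, 0.15, 0.20, 0.25)) {
  d <- soa_delays(soa)
  grid <- sort(unique(c(aud$cdf_x + d[["auditory"]], vis$cdf_x + d[["visual"]])))
  B <- pmin(1, cdf_qf(aud, grid, d[["auditory"]]) + cdf_qf(vis, grid, d[["visual"]]))
  out <- vapply(percentiles, function(p) {
    i <- which(B >= p)[1]
    if (is.na(i))
      stop(sprintf("race bound never reaches percentile %.2f (too much miss mass)", p))
    if (i == 1L) return(grid[1])
    grid[i - 1] + (p - B[i - 1]) * (grid[i] - grid[i - 1]) / (B[i] - B[i - 1])
  }, numeric(1))
  stats::setNames(out, format(percentiles))
}

#' The summed quantile-difference statistic D
#'
#' Collapses the difference between the multisensory quantiles and the
#' race-bound quantiles at the tested percentiles (by default 10, 15, 20
#' and 25) into one number:
#' \deqn{D = \sum_p [Q_{AV}(p) - Q_{bound}(p)].}
#' D below zero means the multisensory distribution is faster than the race
#' bound at those percentiles, i.e. the race model is violated. Collapsing
#' over percentiles avoids accumulating type-I error from testing each
#' percentile separately.
#'
#' @param av `quantile_fun` of the audiovisual condition.
#' @param bound vector from [race_bound_quantiles()], in the same percentile
#'   order as `percentiles`.
#' @param percentiles percentiles at which to compare (must be evaluable on
#'   both arguments).
#' @return D in ms.
#' @export
d_statistic <- function(av, bound, percentiles = c(0.10, 0.15, 0.20, 0.25)) {
  stopifnot(length(bound) == length(percentiles))
  q_av <- quantile_qf(av, percentiles)
  sum(q_av - as.numeric(bound))
}

#' Simulate a multisensory sample under the race-model null
#'
#' Draws `n_out` reaction times from the fastest race compatible with the
#' unisensory marginals: for each draw, a uniform u pairs the auditory
#' quantile at u with the visual quantile at 1 - u (maximal negative
#' dependence), both onset-shifted to the first-stimulus clock, and the
#' minimum is taken. Maximal negative dependence makes the simulated null as
#' fast as a race can be, so the test that uses it is conservative. The
#' progressive kill-the-twin correction is then applied with the
#' participant's catch responses, mirroring the correction carried by the
#' observed data. A u beyond a modality's finite support yields `Inf` for
#' that modality (a miss); if both draws are infinite the simulated trial is
#' a miss.
#'
#' @param aud,vis `quantile_fun` objects of the unisensory conditions.
#' @param soa signed SOA in ms.
#' @param n_out number of simulated trials (match the observed multisensory
#'   trial count so the simulated statistic carries the same estimation
#'   noise).
#' @param catch catch-trial latencies ([condition_rts()] or numeric);
#'   finite entries trigger progressive twin-killing.
#' @return Numeric vector of simulated latencies (may contain `Inf`).
#' @export
simulate_null_av <- function(aud, vis, soa, n_out, catch = numeric(0)) {
  d <- soa_delays(soa)
  u <- stats::runif(n_out)
  qa <- quantile_qf(aud, u, beyond_support = "inf") + d[["auditory"]]
  qv <- quantile_qf(vis, 1 - u, beyond_support = "inf") + d[["visual"]]
  sim <- pmin(qa, qv)
  guesses <- if (inherits(catch, "condition_rts")) catch$latencies else as.numeric(catch)
  if (any(is.finite(guesses)) && any(is.finite(sim)))
    sim <- kill_the_twin(sim, guesses, mode = "progressive")
  sim
}

# Vectorized null distribution of D*: n_iter resampled race-model samples
# at once. Consumes the RNG exactly like a loop of simulate_null_av()
# (uniforms drawn per iteration, row-wise), and applies the same
# progressive kill-the-twin and the same (i - 0.5)/n quantile convention,
# so with regen_bound = FALSE a single row reproduces simulate_null_av()
# under the same seed. With regen_bound = TRUE each iteration additionally
# rebuilds the race bound from with-replacement resamples of the two
# unisensory samples, so D* carries the bound's sampling noise as D does
# (required for a calibrated test; a bound shared across iterations makes
# the null distribution too narrow). Iterations whose sample cannot
# support the highest percentile yield -Inf (which can only inflate the
# p-value).
race_null_ds <- function(aud, vis, soa, n_out, catch, n_iter,
                         bound, percentiles, regen_bound = TRUE) {
  d <- soa_delays(soa)
  u <- matrix(stats::runif(n_iter * n_out), n_iter, n_out, byrow = TRUE)
  qa <- matrix(quantile_qf(aud, u, beyond_support = "inf"), n_iter, n_out) +
    d[["auditory"]]
  qv <- matrix(quantile_qf(vis, 1 - u, beyond_support = "inf"), n_iter, n_out) +
    d[["visual"]]
  sim <- pmin(qa, qv)

  guesses <- if (inherits(catch, "condition_rts")) catch$latencies else
    as.numeric(catch)
  guesses <- sort(guesses[is.finite(guesses)])
  cols <- seq_len(n_out)
  for (g in guesses) {
    dist <- abs(sim - g) # Inf entries give Inf distance
    dmin <- do.call(pmin, lapply(cols, function(j) dist[, j]))
    # among nearest, kill the lower latency (progressive tie-break)
    latc <- sim
    latc[dist > dmin] <- Inf
    lmin <- do.call(pmin, lapply(cols, function(j) latc[, j]))
    alive <- is.finite(lmin) # rows with a finite latency left
    if (!any(alive)) break
    kill_col <- max.col(-abs(latc[alive, , drop = FALSE] -
                               lmin[alive]), ties.method = "first")
    sim[cbind(which(alive), kill_col)] <- Inf
  }

  # per-row quantiles under the (i - 0.5)/n convention on the sorted rows
  o <- order(row(sim), sim)
  sorted <- matrix(sim[o], n_iter, n_out, byrow = TRUE)
  pos <- (cols - 0.5) / n_out
  qsum <- numeric(n_iter)
  for (k in seq_along(percentiles)) {
    p <- percentiles[k]
    if (p <= pos[1]) {
      q <- sorted[, 1]
    } else {
      i <- findInterval(p, pos)
      frac <- (p - pos[i]) / (pos[i + 1] - pos[i])
      q <- sorted[, i] + frac * (sorted[, i + 1] - sorted[, i])
    }
    qsum <- qsum + q
  }

  if (regen_bound) {
    # full multisets (finite latencies plus the infinite-mass entries)
    full_a <- c(aud$lat, rep(Inf, aud$n_total - aud$n_finite))
    full_v <- c(vis$lat, rep(Inf, vis$n_total - vis$n_finite))
    bsum <- vapply(seq_len(n_iter), function(k) {
      tryCatch({
        qa <- empirical_quantile_function(sample(full_a, replace = TRUE))
        qv <- empirical_quantile_function(sample(full_v, replace = TRUE))
        sum(race_bound_quantiles(qa, qv, soa, percentiles))
      }, error = function(e) Inf)
    }, numeric(1))
  } else {
    bsum <- rep(sum(as.numeric(bound)), n_iter)
  }
  ds <- qsum - bsum
  ds[!is.finite(ds)] <- -Inf
  ds
}

#' Per-SOA resampling test of the race-model inequality
#'
#' Computes the observed D statistic at one SOA and its null distribution
#' D* from `n_iter` resampled race-model samples ([simulate_null_av()]),
#' each compared against the same observed race bound. The one-sided
#' p-value uses the add-one convention
#' p = (#\{D* <= D\} + 1) / (n_iter + 1), so a finite resample never
#' reports exactly zero. An SOA whose samples cannot support the highest
#' tested percentile (too many misses) is flagged `untestable` and treated
#' as non-significant. Resampled sets that cannot support the percentile
#' count as D* = -Inf (i.e. below D), which can only inflate p.
#'
#' @param participant a [participant_data()].
#' @param soa SOA in ms, on the design grid.
#' @param n_iter number of resampling iterations (default 1000).
#' @param alpha one-sided significance level (default 0.05).
#' @param percentiles percentiles entering D.
#' @param kill_twin_observed apply the conservative kill-the-twin
#'   correction to the observed visual-only and audiovisual samples before
#'   testing (default TRUE, for raw data). Set FALSE for data that already
#'   carry the correction at source. The correction must affect the
#'   observed multisensory sample and the resampled null symmetrically
#'   (both lose one latency per catch response); correcting only one side
#'   miscalibrates the test.
#' @param regenerate_bound rebuild the race bound in every null iteration
#'   from with-replacement resamples of the unisensory samples (default
#'   TRUE). This propagates the bound's own estimation noise into D*;
#'   comparing D against null draws that all share the one observed bound
#'   understates the null variance and inflates the rejection rate.
#' @param engine `"cpp"` (default, compiled null-distribution kernel) or
#'   `"R"` (reference implementation); both apply the identical procedure
#'   and are cross-validated in the tests.
#' @param keep_null keep the vector of D* draws in the result (default TRUE).
#' @return An object of class `race_test_result`: list with `soa`, `d`,
#'   `p`, `significant`, `untestable`, `borderline` (p within 2 Monte-Carlo
#'   standard errors of `alpha`), `n_av` and optionally `null_draws`.
#' @export
race_test <- function(participant, soa, n_iter = 1000, alpha = 0.05,
                      percentiles = c(0.10, 0.15, 0.20, 0.25),
                      kill_twin_observed = TRUE, regenerate_bound = TRUE,
                      engine = c("cpp", "R"), keep_null = TRUE) {
  engine <- match.arg(engine)
  av <- get_condition(participant, "av", soa)
  catch <- get_condition(participant, "catch")
  vis <- get_condition(participant, "visual_only")
  if (kill_twin_observed && any(is.finite(catch$latencies))) {
    av <- kill_the_twin(av, catch, mode = "conservative")
    vis <- kill_the_twin(vis, catch, mode = "conservative")
  }
  res <- list(soa = soa, d = NA_real_, p = NA_real_, significant = FALSE,
              untestable = TRUE, borderline = FALSE,
              n_av = length(av$latencies))
  class(res) <- "race_test_result"
  ok <- try({
    aud_qf <- empirical_quantile_function(get_condition(participant, "auditory_only"))
    vis_qf <- empirical_quantile_function(vis)
    av_qf <- empirical_quantile_function(av)
    bound <- race_bound_quantiles(aud_qf, vis_qf, soa, percentiles)
    d_obs <- d_statistic(av_qf, bound, percentiles)
    list(aud_qf = aud_qf, vis_qf = vis_qf, bound = bound, d_obs = d_obs)
  }, silent = TRUE)
  if (inherits(ok, "try-error")) return(res)

  n_out <- length(av$latencies)
  d_star <- if (engine == "cpp") {
    d <- soa_delays(soa)
    cpp_race_null_ds(ok$aud_qf$lat, ok$aud_qf$n_total,
                     ok$vis_qf$lat, ok$vis_qf$n_total,
                     d[["auditory"]], d[["visual"]], n_out,
                     catch$latencies[is.finite(catch$latencies)],
                     n_iter, percentiles, regenerate_bound,
                     sum(as.numeric(ok$bound)))
  } else {
    race_null_ds(ok$aud_qf, ok$vis_qf, soa, n_out, catch,
                 n_iter, ok$bound, percentiles,
                 regen_bound = regenerate_bound)
  }
  p <- (sum(d_star <= ok$d_obs) + 1) / (n_iter + 1)
  mc_se <- sqrt(alpha * (1 - alpha) / n_iter)
  res$d <- ok$d_obs
  res$p <- p
  res$significant <- p < alpha
  res$untestable <- FALSE
  res$borderline <- abs(p - alpha) <= 2 * mc_se
  if (keep_null) res$null_draws <- d_star
  res
}

#' @export
print.race_test_result <- function(x, ...) {
  if (x$untestable) {
    cat(sprintf("<race_test> soa=%+d: untestable (insufficient finite RTs)\n", x$soa))
  } else {
    cat(sprintf("<race_test> soa=%+d: D=%.1f ms, p=%.4f%s\n", x$soa, x$d, x$p,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' Race-model tests over the full SOA grid
#'
#' Runs [race_test()] at every SOA with a deterministic RNG substream per
#' SOA derived from `seed`.
#'
#' @inheritParams race_test
#' @param soas SOAs to test (default the full design grid).
#' @param seed integer seed; substreams are derived per SOA.
#' @return List of `race_test_result`, named by SOA.
#' @export
race_test_grid <- function(participant, soas = soa_grid(), n_iter = 1000,
                           alpha = 0.05, seed = 1,
                           percentiles = c(0.10, 0.15, 0.20, 0.25),
                           kill_twin_observed = TRUE, regenerate_bound = TRUE,
                           keep_null = FALSE) {
  res <- lapply(seq_along(soas), function(i) {
    set.seed(substream_seed(seed, 7L, i))
    race_test(participant, soas[i], n_iter = n_iter, alpha = alpha,
              percentiles = percentiles,
              kill_twin_observed = kill_twin_observed,
              regenerate_bound = regenerate_bound, keep_null = keep_null)
  })
  stats::setNames(res, sprintf("%+d", soas))
}

#' RT-defined temporal window of integration (contiguity rule)
#'
#' Among maximal contiguous runs of SOAs with significant race-model
#' violation, selects the run containing physical simultaneity (SOA 0), or
#' failing that the run whose nearest endpoint is closest to 0 (ties go to
#' the positive, visual-leading side). Untestable SOAs count as
#' non-significant. Restricting the window to one contiguous run partly
#' compensates for testing many SOAs.
#'
#' @param results list of `race_test_result` covering the tested grid
#'   (as returned by [race_test_grid()]).
#' @return An object of class `rt_twi` (list with `lower`, `upper`, `soas`,
#'   `rule`), or `NULL` if no SOA is significant.
#' @export
rt_twi <- function(results) {
  soas <- vapply(results, function(r) r$soa, numeric(1))
  sig <- vapply(results, function(r) isTRUE(r$significant), logical(1))
  o <- order(soas)
  soas <- soas[o]; sig <- sig[o]
  if (!any(sig)) return(NULL)
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  pick <- NULL
  for (k in runs) {
    if (soas[starts[k]] <= 0 && soas[ends[k]] >= 0) { pick <- k; break }
  }
  if (is.null(pick)) {
    dist0 <- vapply(runs, function(k) min(abs(soas[starts[k]]), abs(soas[ends[k]])),
                    numeric(1))
    cand <- runs[dist0 == min(dist0)]
    if (length(cand) > 1L) # tie: prefer the run on the positive side
      cand <- cand[vapply(cand, function(k) soas[starts[k]] > 0, logical(1))]
    pick <- cand[1]
  }
  member <- soas[starts[pick]:ends[pick]]
  structure(list(lower = min(member), upper = max(member), soas = member,
                 rule = "contiguity"),
            class = "rt_twi")
}

#' Exact group-level sign-permutation test on D
#'
#' Under the null hypothesis that the race model holds for everyone, each
#' participant's D is symmetric around zero, so its sign is exchangeable.
#' The observed sum of D values is compared with the sums over all 2^n sign
#' assignments (the observed assignment included); the one-sided p-value is
#' the fraction of permutation sums at or below the observed sum.
#'
#' @param d numeric vector of per-participant D values at one SOA; all must
#'   be finite; length at most 20 (exhaustive enumeration).
#' @return List with `sum_d`, `p` and `n_permutations`.
#' @export
group_sign_permutation <- function(d) {
  if (any(!is.finite(d))) stop("all D values must be finite")
  n <- length(d)
  if (n < 1L || n > 20L) stop("sign permutation supports 1 to 20 participants")
  sums <- 0
  for (di in d) sums <- c(sums + di, sums - di)
  obs <- sum(d)
  # tolerance so that exact sign-sum ties are counted regardless of
  # floating-point summation order
  tol <- 1e-9 * max(1, sum(abs(d)))
  list(sum_d = obs, p = mean(sums <= obs + tol), n_permutations = length(sums))
}
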