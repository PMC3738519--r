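test_that("empirical quantiles interpolate between plotting positions", {
  qf <- empirical_quantile_function(c(200, 250, 300, 350))
  # positions 0.125, 0.375: p = 0.25 sits halfway -> 225 ms
  expect_equal(quantile_qf(qf, 0.25), 225)
  # clamp below the first position
  expect_equal(quantile_qf(qf, 0.01), 200)
  # degenerate sample: every attainable percentile is the common value
  qfd <- empirical_quantile_function(rep(300, 8))
  for (p in c(0.05, 0.25, 0.5, 0.9)) expect_equal(quantile_qf(qfd, p), 300)
  # infinite mass: 60 trials, 30 infinite
  qfi <- empirical_quantile_function(c(seq(200, 490, by = 10), rep(Inf, 30)))
  expect_true(is.finite(quantile_qf(qfi, 0.25)))
  expect_error(quantile_qf(qfi, 0.60), "beyond finite support")
  expect_error(empirical_quantile_function(rep(Inf, 5)), "no finite")
})

test_that("empirical quantiles match the hand-interpolation oracle", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(3:40, 1)
    lat <- round(runif(n, 150, 700), 1)
    lat[runif(n) < 0.15] <- Inf
    if (!any(is.finite(lat))) lat[1] <- 300
    qf <- empirical_quantile_function(lat)
    m <- sum(is.finite(lat))
    pmax_fin <- (m - 0.5) / n
    ps <- runif(6, 0.01, pmax_fin)
    expect_equal(quantile_qf(qf, ps), oracle_quantile(lat, ps),
                 tolerance = 1e-10)
  }
})

test_that("race bound handles point masses, capping, and onset shifts", {
  pm <- empirical_quantile_function(rep(300, 60))
  # identical point masses at SOA 0: the bound reaches any percentile at 300
  b <- race_bound_quantiles(pm, pm, 0, c(0.10, 0.25, 0.5))
  expect_equal(unname(b), rep(300, 3))
  # capping: the summed CDF exceeds 1 but the bound is still reached at 300
  expect_equal(unname(race_bound_quantiles(pm, pm, 0, 0.9)), 300)

  # with a visual lead of +300 or +400 and all visual RTs below 300,
  # low percentiles of the bound are set by the visual stimulus alone
  set.seed(405)
  vis <- empirical_quantile_function(runif(60, 150, 290))
  aud <- empirical_quantile_function(runif(60, 180, 400))
  b300 <- race_bound_quantiles(aud, vis, 300)
  b400 <- race_bound_quantiles(aud, vis, 400)
  expect_equal(b300, b400)
  expect_equal(unname(b300), unname(quantile_qf(vis, c(0.10, 0.15, 0.20, 0.25))),
               tolerance = 1e-9)
})

test_that("the D statistic is a sum of percentile differences", {
  set.seed(406)
  av <- runif(40, 200, 500)
  aud <- runif(40, 220, 520)
  vis <- runif(40, 260, 560)
  aq <- empirical_quantile_function(aud)
  vq <- empirical_quantile_function(vis)
  avq <- empirical_quantile_function(av)
  pct <- c(0.10, 0.15, 0.20, 0.25)
  bound <- race_bound_quantiles(aq, vq, 0, pct)
  d <- d_statistic(avq, bound, pct)
  # independent recomputation with the oracle quantiles
  d_oracle <- sum(oracle_quantile(av, pct) - bound)
  expect_equal(d, d_oracle, tolerance = 1e-9)
  # identity: av equal to the bound at the four percentiles -> D = 0
  expect_equal(d_statistic(avq, quantile_qf(avq, pct), pct), 0)
  # shifting every AV latency by +c shifts D by 4c
  avq2 <- empirical_quantile_function(av + 17)
  expect_equal(d_statistic(avq2, bound, pct), d + 4 * 17, tolerance = 1e-9)
  # av exactly 10 ms faster at each percentile -> D = -40
  expect_equal(d_statistic(avq, quantile_qf(avq, pct) + 10, pct), -40)
})

test_that("the null simulation pairs antithetic quantiles and kills twins", {
  pm <- empirical_quantile_function(rep(300, 30))
  set.seed(407)
  sim <- simulate_null_av(pm, pm, 0, 30)
  expect_equal(sim, rep(300, 30))
  # one catch response leaves exactly one infinite entry
  set.seed(408)
  sim2 <- simulate_null_av(pm, pm, 0, 30, catch = 250)
  expect_equal(sum(is.infinite(sim2)), 1L)
  expect_length(sim2, 30L)

  # antithetic pairing makes the minima stochastically as fast as a race
  # can be: mean simulated minimum below the independent-pairing mean
  set.seed(409)
  aud <- empirical_quantile_function(rexgauss(60, 190, 30, 60))
  vis <- empirical_quantile_function(rexgauss(60, 230, 35, 60))
  anti <- replicate(300, mean(simulate_null_av(aud, vis, 0, 60)))
  indep <- replicate(300, {
    u1 <- runif(60); u2 <- runif(60)
    mean(pmin(quantile_qf(aud, u1, "inf"), quantile_qf(vis, u2, "inf")))
  })
  expect_lt(mean(anti), mean(indep))
})

test_that("the race test is one-sided and flags untestable SOAs", {
  # AV uniformly 200 ms slower than both unisensory conditions
  p <- make_tiny_participant(av0 = seq(430, 560, length.out = 12),
                             aud = seq(230, 360, length.out = 12),
                             vis = seq(260, 390, length.out = 12))
  set.seed(410)
  r <- race_test(p, 0, n_iter = 300)
  expect_false(r$significant)
  expect_gt(r$p, 0.9)
  expect_true(r$p <= 1 && r$p > 0)

  # too many misses to evaluate the 25th percentile -> untestable
  p2 <- make_tiny_participant(av0 = c(250, 260, rep(Inf, 18)))
  set.seed(411)
  r2 <- race_test(p2, 0, n_iter = 50)
  expect_true(r2$untestable)
  expect_false(r2$significant)
})

test_that("the compiled and reference null engines implement the same procedure", {
  set.seed(430)
  st <- make_study(synth_config(n_participants = 1, gamma = 30, seed = 11))
  p <- st$participants[[1]]
  for (soa in c(-120, 0, 60)) {
    set.seed(431)
    rc <- race_test(p, soa, n_iter = 800, engine = "cpp")
    set.seed(431)
    rr <- race_test(p, soa, n_iter = 800, engine = "R")
    # identical observed statistic, same procedure on both paths
    expect_equal(rc$d, rr$d, tolerance = 1e-10)
    a <- rc$null_draws[is.finite(rc$null_draws)]
    b <- rr$null_draws[is.finite(rr$null_draws)]
    # the two engines draw from the same null distribution
    expect_lt(abs(mean(a) - mean(b)), 3 * sqrt(var(a) / length(a) + var(b) / length(b)))
    expect_gt(suppressWarnings(ks.test(a, b)$p.value), 0.001)
  }
})

test_that("the contiguity rule picks the run around or closest to simultaneity", {
  mk <- function(soa, sig) structure(list(soa = soa, significant = sig,
                                          untestable = FALSE),
                                     class = "race_test_result")
  grid <- soa_grid()
  # violation from -40 to +80, a gap at +100, violation again at +120
  sig <- grid %in% c(-40, -20, 0, 20, 40, 60, 80, 120)
  res <- Map(mk, grid, sig)
  w <- rt_twi(res)
  expect_equal(c(w$lower, w$upper), c(-40, 80))
  # no significant SOA -> no window
  expect_null(rt_twi(Map(mk, grid, rep(FALSE, 23))))
  # only a run off simultaneity -> closest run is the window
  sig2 <- grid %in% c(100, 120)
  w2 <- rt_twi(Map(mk, grid, sig2))
  expect_equal(c(w2$lower, w2$upper), c(100, 120))
  # equidistant runs: the visual-leading (positive) side wins
  sig3 <- grid %in% c(-60, -40, 40, 60)
  w3 <- rt_twi(Map(mk, grid, sig3))
  expect_equal(c(w3$lower, w3$upper), c(40, 60))
})

test_that("group sign permutation is exact, invariant to order, and bounded", {
  # all 11 participants violating: the most extreme of 2^11 assignments
  expect_equal(group_sign_permutation(rep(-5, 11))$p, 1 / 2048)
  # a single participant: half the assignments are at or below
  expect_equal(group_sign_permutation(-3)$p, 0.5)
  set.seed(412)
  for (rep in 1:10) {
    d <- round(rnorm(sample(3:10, 1), sd = 20), 2)
    gp <- group_sign_permutation(d)
    expect_equal(gp$p, oracle_sign_permutation_p(d))
    expect_equal(group_sign_permutation(sample(d))$p, gp$p)
  }
  expect_error(group_sign_permutation(c(-2, Inf)), "finite")
  expect_error(group_sign_permutation(numeric(0)), "1 to 20")
})
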