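test_that("the lapse-contaminated logistic has the documented anatomy", {
  p0 <- list(mu = 0, sigma = 50, lambda_a = 0, lambda_v = 0)
  expect_equal(psi(0, p0), 0.5)
  expect_equal(psi(50 * log(3), p0), 0.75)
  pl <- list(mu = 10, sigma = 40, lambda_a = 0.06, lambda_v = 0.09)
  expect_equal(psi(-1e9, pl), 0.06, tolerance = 1e-12)
  expect_equal(psi(1e9, pl), 1 - 0.09, tolerance = 1e-12)
  # monotone and bounded for random valid parameters
  set.seed(413)
  for (rep in 1:20) {
    par <- list(mu = runif(1, -100, 100), sigma = runif(1, 5, 300),
                lambda_a = runif(1, 0, 0.4), lambda_v = runif(1, 0, 0.4))
    x <- seq(-500, 500, by = 25)
    y <- psi(x, par)
    expect_true(all(diff(y) > 0))
    expect_true(all(y > par$lambda_a & y < 1 - par$lambda_v))
  }
})

test_that("the unnormalized log posterior matches direct arithmetic", {
  pr <- prior_spec()
  toj <- toj_table(0, 5, 10)
  par <- list(mu = 0, sigma = 60, lambda_a = 0.01, lambda_v = 0.02)
  prob <- 0.01 + (1 - 0.03) * 0.5
  by_hand <- lchoose(10, 5) + 5 * log(prob) + 5 * log(1 - prob) +
    dnorm(0, 0, 200, log = TRUE) +
    dgamma(60, shape = 1.05, scale = 1000, log = TRUE) +
    dbeta(0.01, 2, 20, log = TRUE) + dbeta(0.02, 2, 20, log = TRUE)
  expect_equal(log_posterior_unnorm(par, toj, pr), by_hand, tolerance = 1e-12)
  # n = 0 rows contribute nothing
  toj2 <- toj_table(c(-20, 0), c(0, 5), c(0, 10))
  expect_equal(log_posterior_unnorm(par, toj2, pr), by_hand, tolerance = 1e-12)
  # out-of-domain parameters
  expect_identical(log_posterior_unnorm(list(mu = 0, sigma = -1,
                                             lambda_a = 0, lambda_v = 0),
                                        toj, pr), -Inf)
  expect_identical(log_posterior_unnorm(list(mu = 0, sigma = 50,
                                             lambda_a = 0.6, lambda_v = 0.5),
                                        toj, pr), -Inf)
  # the compiled density used by the sampler agrees with the R reference
  set.seed(414)
  toj3 <- toj_table(soa_grid(), rbinom(23, 60, 0.5), rep(60, 23))
  for (rep in 1:10) {
    th <- c(runif(1, -80, 80), runif(1, 10, 300), runif(1, 0, 0.3),
            runif(1, 0, 0.3))
    r_val <- log_posterior_unnorm(list(mu = th[1], sigma = th[2],
                                       lambda_a = th[3], lambda_v = th[4]),
                                  toj3, pr, include_binom_coef = FALSE)
    cpp_val <- mtwi:::cpp_log_posterior(th, toj3$soa, toj3$visual_first,
                                        toj3$n, pr$mu_mean, pr$mu_sd,
                                        pr$sigma_shape, pr$sigma_scale,
                                        pr$lapse_shape1, pr$lapse_shape2)
    expect_equal(r_val, cpp_val, tolerance = 1e-10)
  }
  # priors are proper densities
  expect_equal(integrate(dgamma, 0, Inf, shape = 1.05, scale = 1000)$value, 1,
               tolerance = 1e-6)
  expect_equal(integrate(dbeta, 0, 1, shape1 = 2, shape2 = 20)$value, 1,
               tolerance = 1e-6)
})

test_that("the slice sampler is deterministic, validated, and schedule-faithful", {
  set.seed(415)
  toj <- simulate_toj_participant(synth_config(n_participants = 1),
                                  list(mu = 10, sigma = 60,
                                       lambda_a = 0.05, lambda_v = 0.05))
  set.seed(416)
  a <- slice_sample_posterior(toj, n_samples = 200)
  set.seed(416)
  b <- slice_sample_posterior(toj, n_samples = 200)
  expect_identical(a$draws, b$draws)
  expect_equal(nrow(a$draws), 200L)
  expect_equal(a$diagnostics$n_raw_iterations, 100 + 10 * 200)
  # every retained draw satisfies the parameter invariants
  expect_true(all(a$draws[, "sigma"] > 0))
  expect_true(all(a$draws[, "lambda_a"] >= 0 & a$draws[, "lambda_v"] >= 0))
  expect_true(all(a$draws[, "lambda_a"] + a$draws[, "lambda_v"] < 1))
  # zero-trial table is rejected up front
  expect_error(slice_sample_posterior(toj_table(c(-20, 20), c(0, 0), c(0, 0))),
               "at least two SOAs")
})

test_that("sharply informative data pin the posterior near the truth", {
  truth <- list(mu = 25, sigma = 70, lambda_a = 0.04, lambda_v = 0.08)
  cfg <- synth_config(n_participants = 1, n_trials = 1e4)
  set.seed(417)
  toj <- simulate_toj_participant(cfg, truth)
  set.seed(418)
  post <- slice_sample_posterior(toj)
  med <- apply(post$draws, 2, median)
  expect_lt(abs(med[["mu"]] - truth$mu), 3)
  expect_lt(abs(med[["sigma"]] - truth$sigma) / truth$sigma, 0.05)
  expect_lt(abs(med[["lambda_a"]] - truth$lambda_a), 0.02)
  expect_lt(abs(med[["lambda_v"]] - truth$lambda_v), 0.02)
})

test_that("thresholds invert the psychometric function in closed form", {
  thr <- thresholds(list(mu = 0, sigma = 50, lambda_a = 0, lambda_v = 0))
  expect_equal(unname(thr), c(-50 * log(3), 50 * log(3)), tolerance = 1e-12)
  # at the thresholds the curve passes 25% and 75% when there are no lapses
  expect_equal(psi(thr[["auditory"]],
                   list(mu = 0, sigma = 50, lambda_a = 0, lambda_v = 0)), 0.25)
  expect_equal(psi(thr[["visual"]],
                   list(mu = 0, sigma = 50, lambda_a = 0, lambda_v = 0)), 0.75)
  # location equivariance
  t1 <- thresholds(list(mu = 0, sigma = 40, lambda_a = 0.1, lambda_v = 0.05))
  t2 <- thresholds(list(mu = 20, sigma = 40, lambda_a = 0.1, lambda_v = 0.05))
  expect_equal(t2, t1 + 20)
})

test_that("closed-form thresholds agree with numeric root-finding", {
  set.seed(419)
  for (rep in 1:25) {
    par <- list(mu = runif(1, -100, 100), sigma = runif(1, 5, 300),
                lambda_a = runif(1, 0, 0.35), lambda_v = runif(1, 0, 0.35))
    thr <- thresholds(par)
    targets <- c((par$lambda_a + 0.5) / 2, (1.5 - par$lambda_v) / 2)
    for (j in 1:2) {
      root <- uniroot(function(x) psi(x, par) - targets[j],
                      lower = -1e6, upper = 1e6, tol = 1e-12)$root
      expect_lt(abs(thr[j] - root), 1e-9)
    }
  }
})

test_that("the TOJ window takes conservative posterior percentiles", {
  # degenerate posterior: the window is that draw's thresholds
  post <- fake_posterior(rep(10, 100), rep(50, 100), rep(0.02, 100),
                         rep(0.02, 100))
  w <- toj_twi(post)
  thr <- thresholds(list(mu = 10, sigma = 50, lambda_a = 0.02,
                         lambda_v = 0.02))
  expect_equal(w$threshold_a, thr[["auditory"]])
  expect_equal(w$threshold_v, thr[["visual"]])
  expect_equal(w$width, thr[["visual"]] - thr[["auditory"]])

  # widening the posterior spread never narrows the window
  set.seed(420)
  mu <- rnorm(500, 0, 10)
  narrow <- fake_posterior(mu, rep(50, 500), rep(0.02, 500), rep(0.02, 500))
  wide <- fake_posterior(mean(mu) + 3 * (mu - mean(mu)), rep(50, 500),
                         rep(0.02, 500), rep(0.02, 500))
  wn <- toj_twi(narrow); ww <- toj_twi(wide)
  expect_lte(wn$width, ww$width)
  expect_lte(ww$threshold_a, wn$threshold_a)
  expect_gte(ww$threshold_v, wn$threshold_v)
})

test_that("non-performers are excluded with the failing side named", {
  w <- structure(list(threshold_a = -120, threshold_v = 500, width = 620),
                 class = "toj_twi")
  out <- exclude_nonperformers(w)
  expect_false(out$keep)
  expect_equal(out$reason, "visual-first side")
  w2 <- structure(list(threshold_a = -100, threshold_v = 60, width = 160),
                  class = "toj_twi")
  expect_true(exclude_nonperformers(w2)$keep)
  w3 <- structure(list(threshold_a = -450, threshold_v = 60, width = 510),
                  class = "toj_twi")
  expect_equal(exclude_nonperformers(w3)$reason, "auditory-first side")
})

test_that("a study with four near-flat performers excludes exactly those four", {
  # 15 observers: 11 with ordinary windows, 4 whose discrimination is so
  # poor (flat curves) that they never reach threshold inside +-400 ms
  cfg <- synth_config(n_participants = 1)
  flat <- list(mu = 0, sigma = 700, lambda_a = 0.05, lambda_v = 0.05)
  ok <- list(mu = 0, sigma = 60, lambda_a = 0.04, lambda_v = 0.04)
  truth <- c(rep(list(ok), 11), rep(list(flat), 4))
  kept <- logical(15)
  for (i in 1:15) {
    set.seed(500 + i)
    toj <- simulate_toj_participant(cfg, truth[[i]])
    set.seed(600 + i)
    post <- slice_sample_posterior(toj, n_samples = 500)
    kept[i] <- exclude_nonperformers(toj_twi(post))$keep
  }
  expect_equal(kept, c(rep(TRUE, 11), rep(FALSE, 4)))
})

test_that("the group curve averages per-participant posterior medians", {
  p1 <- fake_posterior(rep(-20, 50), rep(40, 50), rep(0, 50), rep(0, 50))
  p2 <- fake_posterior(rep(20, 50), rep(40, 50), rep(0, 50), rep(0, 50))
  g <- group_psychometric(list(p1, p2))
  expect_equal(g$params$mu, 0)
  expect_equal(g$params$sigma, 40)
  expect_equal(unname(g$thresholds), c(-40 * log(3), 40 * log(3)))
  # a single participant: the group equals that participant's medians
  g1 <- group_psychometric(list(p1))
  expect_equal(g1$params$mu, -20)
  expect_error(group_psychometric(list()), "no participants")
})
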