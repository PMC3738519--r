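#' Configuration for a synthetic study
#'
#' Defines the generative model of a complete synthetic study with the
#' structure the analysis assumes, with known ground truth. Defaults mirror
#' the study design: 11 participants, the 23-SOA grid, 60 trials per
#' condition, a 3.94% catch-trial guess rate and a 0.7% miss rate (the
#' study's observed averages).
#'
#' Unisensory reaction times are ex-Gaussian ([rexgauss()]); within an
#' audiovisual trial the two unisensory draws are coupled through a
#' Gaussian copula with correlation `rho` (`rho = -1` gives maximal
#' negative dependence, the regime in which the race bound is tight).
#' Coactivation is modelled as a constant gain `gamma` (ms) subtracted from
#' the race minimum, applied only at SOAs within `gamma_soa_window` ms of
#' simultaneity — with `gamma = 0` the race model holds everywhere.
#' Temporal-order responses are binomial draws from the lapse-contaminated
#' logistic [psi()] at each participant's true parameters.
#'
#' @param n_participants number of participants (default 11).
#' @param soas bisensory SOA grid (default [soa_grid()]).
#' @param n_trials trials per condition (default 60).
#' @param aud,vis ex-Gaussian parameters `c(mu, sigma, tau)` in ms for the
#'   auditory-only and visual-only RT distributions. Defaults give mean
#'   simple RTs of ~250 ms (auditory) and ~290 ms (visual), auditory faster
#'   as is typical.
#' @param rho Gaussian-copula correlation between the unisensory draws
#'   within an AV trial, in \[-1, 1\].
#' @param gamma coactivation gain in ms subtracted from the race minimum
#'   (0 = race model holds).
#' @param gamma_soa_window half-width in ms of the SOA band around
#'   simultaneity in which the gain applies (default 100).
#' @param guess_rate per-catch-trial probability of an anticipatory guess.
#' @param miss_prob per-draw probability of a miss (infinite RT).
#' @param toj_params either one set of psychometric parameters (list with
#'   `mu`, `sigma`, `lambda_a`, `lambda_v`) used for every participant, or
#'   a list of such sets, one per participant.
#' @param seed master RNG seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_participants = 11, soas = soa_grid(), n_trials = 60,
                         aud = c(mu = 190, sigma = 30, tau = 60),
                         vis = c(mu = 230, sigma = 35, tau = 60),
                         rho = 0, gamma = 0, gamma_soa_window = 100,
                         guess_rate = 0.0394, miss_prob = 0.007,
                         toj_params = list(mu = 0, sigma = 50,
                                           lambda_a = 0.05, lambda_v = 0.05),
                         seed = 1) {
  stopifnot(n_participants >= 0, n_trials >= 1,
            all(aud > 0), all(vis > 0),
            rho >= -1, rho <= 1, gamma >= 0, gamma_soa_window >= 0,
            guess_rate >= 0, guess_rate <= 1, miss_prob >= 0, miss_prob <= 1)
  if (!is.null(names(toj_params)) && "mu" %in% names(toj_params))
    toj_params <- rep(list(toj_params), n_participants)
  if (n_participants > 0 && length(toj_params) != n_participants)
    stop("toj_params must have one entry per participant")
  structure(list(n_participants = n_participants, soas = as.integer(soas),
                 n_trials = n_trials, aud = aud, vis = vis, rho = rho,
                 gamma = gamma, gamma_soa_window = gamma_soa_window,
                 guess_rate = guess_rate, miss_prob = miss_prob,
                 toj_params = toj_params, seed = seed),
            class = "synth_config")
}

#' Study-conditions synthetic configuration
#'
#' A [synth_config()] emulating the structure of the study sample as
#' published: 11 retained participants, 5 of whom ("malleable") have narrow
#' temporal-order windows (true psychometric shape 20 ms, so their order
#' judgments are reliable well inside the range where their reaction times
#' show multisensory facilitation) and 6 of whom have wide windows (shape
#' 150 ms). All participants share a coactivation gain of 50 ms confined to
#' SOAs within 100 ms of simultaneity, the observed 3.94% catch-trial guess
#' rate, and the observed 0.7% miss rate. True locations are jittered a few
#' ms around simultaneity as real observers' are. With this configuration
#' the first five participants are malleable by construction: their
#' TOJ-defined window excludes SOAs at which their RT task shows race-model
#' violation.
#'
#' @param seed master RNG seed.
#' @return A `synth_config` whose first 5 participants are constructed to
#'   be malleable.
#' @export
synth_config_study <- function(seed = 1) {
  mus <- c(-10, 5, 0, 15, -5, 10, -15, 0, 5, -10, 20)
  sigmas <- c(rep(20, 5), rep(150, 6))
  tp <- lapply(1:11, function(i)
    list(mu = mus[i], sigma = sigmas[i], lambda_a = 0.04, lambda_v = 0.04))
  synth_config(n_participants = 11, gamma = 50, gamma_soa_window = 100,
               rho = 0, guess_rate = 0.0394, miss_prob = 0.007,
               toj_params = tp, seed = seed)
}

# correlated uniforms via a Gaussian copula; rho = -1/1 are the
# counter-/co-monotone limits
copula_uniforms <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  list(u1 = stats::pnorm(z1), u2 = stats::pnorm(z2))
}

#' Simulate one participant's 26 RT conditions
#'
#' @param cfg a [synth_config()]. The caller controls the RNG state
#'   ([make_study()] seeds a substream per participant).
#' @return Named list of 26 [condition_rts()].
#' @export
simulate_rt_participant <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- cfg$n_trials
  miss <- function(x) { x[stats::runif(length(x)) < cfg$miss_prob] <- Inf; x }
  # the anticipatory-guess process runs on every trial, not just catch
  # trials: with prob guess_rate a guess is prepared at a uniform latency
  # on [100, 1000] ms and preempts the stimulus-driven response if earlier.
  # On catch trials there is no stimulus-driven response, so the guess (if
  # any) is the only response - which is exactly why the catch distribution
  # estimates the guessing process that the kill-the-twin correction and
  # the twin-killed resampling null both assume contaminates the stimulus
  # conditions.
  guess <- function(x) {
    g <- stats::runif(length(x)) < cfg$guess_rate
    x[g] <- pmin(x[g], stats::runif(sum(g), 100, 1000))
    x
  }
  floor1 <- function(x) ifelse(is.finite(x), pmax(x, 1), x)

  out <- list()
  out$catch <- condition_rts("catch", guess(rep(Inf, n)))
  out$auditory_only <- condition_rts(
    "auditory_only",
    floor1(guess(miss(rexgauss(n, cfg$aud[["mu"]], cfg$aud[["sigma"]],
                               cfg$aud[["tau"]])))))
  for (s in cfg$soas) {
    u <- copula_uniforms(n, cfg$rho)
    a <- qexgauss(u$u1, cfg$aud[["mu"]], cfg$aud[["sigma"]], cfg$aud[["tau"]])
    v <- qexgauss(u$u2, cfg$vis[["mu"]], cfg$vis[["sigma"]], cfg$vis[["tau"]])
    a <- miss(a); v <- miss(v)
    d <- soa_delays(s)
    gain <- if (abs(s) <= cfg$gamma_soa_window) cfg$gamma else 0
    rt <- pmin(a + d[["auditory"]], v + d[["visual"]]) - gain
    out[[condition_key("av", s)]] <- condition_rts("av", floor1(guess(rt)), soa = s)
  }
  out$visual_only <- condition_rts(
    "visual_only",
    floor1(guess(miss(rexgauss(n, cfg$vis[["mu"]], cfg$vis[["sigma"]],
                               cfg$vis[["tau"]])))))
  out[all_condition_keys()]
}

#' Simulate one participant's TOJ count table
#'
#' Per-SOA counts are independent binomial draws with success probability
#' [psi()] at the participant's true parameters. There are no misses in the
#' TOJ task, so every trial yields a response.
#'
#' @param cfg a [synth_config()].
#' @param params the participant's true psychometric parameters.
#' @return A [toj_table()].
#' @export
simulate_toj_participant <- function(cfg, params) {
  pr <- psi(cfg$soas, params)
  toj_table(cfg$soas, stats::rbinom(length(cfg$soas), cfg$n_trials, pr),
            rep(cfg$n_trials, length(cfg$soas)))
}

#' Generate a complete synthetic study
#'
#' Composes the RT and TOJ simulators over participants, seeding a
#' deterministic RNG substream per participant from the master seed. All
#' ground-truth parameters and the seed are stored in the dataset metadata.
#'
#' @param cfg a [synth_config()].
#' @return A [study_dataset()]; `metadata$ground_truth` holds the config
#'   and per-participant psychometric parameters.
#' @export
make_study <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  participants <- lapply(seq_len(cfg$n_participants), function(i) {
    set.seed(substream_seed(cfg$seed, 1L, i))
    rt <- simulate_rt_participant(cfg)
    set.seed(substream_seed(cfg$seed, 2L, i))
    toj <- simulate_toj_participant(cfg, cfg$toj_params[[i]])
    participant_data(as.character(i), rt, toj)
  })
  study_dataset(participants,
                metadata = list(source = "synthetic", seed = cfg$seed,
                                kill_the_twin_already_applied = FALSE,
                                ground_truth = list(
                                  config = unclass(cfg[setdiff(names(cfg), "toj_params")]),
                                  toj_params = cfg$toj_params)))
}
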