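# Shared fixtures and independent oracles, built in code.

# a minimal participant: deterministic latencies for the unit tests
make_tiny_participant <- function(av0 = c(220, 240, 260, 280, 300, 320),
                                  aud = c(230, 250, 270, 290, 310, 330),
                                  vis = c(260, 280, 300, 320, 340, 360),
                                  catch = numeric(0),
                                  id = "t1") {
  conds <- stats::setNames(vector("list", 26L), all_condition_keys())
  for (key in names(conds)) {
    if (key == "catch") conds[[key]] <- condition_rts("catch", catch)
    else if (key == "auditory_only") conds[[key]] <- condition_rts("auditory_only", aud)
    else if (key == "visual_only") conds[[key]] <- condition_rts("visual_only", vis)
    else {
      s <- as.integer(sub("^av_", "", key))
      conds[[key]] <- condition_rts("av", if (s == 0L) av0 else aud + abs(s) / 10,
                                    soa = s)
    }
  }
  toj <- toj_table(soa_grid(), round(seq(2, 58, length.out = 23)), rep(60L, 23))
  participant_data(id, conds, toj)
}

# independent quantile oracle: hand linear interpolation between order
# statistics at plotting positions (i - 0.5)/n, clamped at the minimum
oracle_quantile <- function(latencies, p) {
  n <- length(latencies)
  fin <- sort(latencies[is.finite(latencies)])
  m <- length(fin)
  pos <- (seq_len(m) - 0.5) / n
  vapply(p, function(pp) {
    if (pp > pos[m]) stop("beyond finite support")
    if (pp <= pos[1]) return(fin[1])
    i <- max(which(pos <= pp))
    if (pos[i] == pp) return(fin[i])
    fin[i] + (pp - pos[i]) / (pos[i + 1] - pos[i]) * (fin[i + 1] - fin[i])
  }, numeric(1))
}

# independent sign-permutation oracle: explicit enumeration over the full
# sign grid via expand.grid
oracle_sign_permutation_p <- function(d) {
  signs <- as.matrix(expand.grid(rep(list(c(1, -1)), length(d))))
  sums <- signs %*% d
  mean(sums <= sum(d) + 1e-9 * max(1, sum(abs(d))))
}

# a posterior_samples object with given draws (for threshold/TWI tests)
fake_posterior <- function(mu, sigma, lambda_a, lambda_v) {
  draws <- cbind(mu = mu, sigma = sigma, lambda_a = lambda_a,
                 lambda_v = lambda_v)
  structure(list(draws = draws,
                 diagnostics = list(lag1_autocorrelation = rep(0, 4))),
            class = "posterior_samples")
}
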