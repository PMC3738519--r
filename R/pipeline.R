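#' Analysis configuration for [run_study()]
#'
#' @param n_iter race-model resampling iterations per SOA (default 1000).
#' @param alpha one-sided significance level for the race test (default
#'   0.05).
#' @param percentiles percentiles entering the D statistic.
#' @param n_samples,burn_in,thin slice-sampler schedule (defaults
#'   2000/100/10).
#' @param priors a [prior_spec()].
#' @param soa_range tested SOA range for the non-performer exclusion rule.
#' @param seed master seed; every stochastic stage derives a substream
#'   from it.
#' @return List of class `study_config`.
#' @export
study_config <- function(n_iter = 1000, alpha = 0.05,
                         percentiles = c(0.10, 0.15, 0.20, 0.25),
                         n_samples = 2000, burn_in = 100, thin = 10,
                         priors = prior_spec(), soa_range = c(-400, 400),
                         seed = 1) {
  structure(list(n_iter = n_iter, alpha = alpha, percentiles = percentiles,
                 n_samples = n_samples, burn_in = burn_in, thin = thin,
                 priors = priors, soa_range = soa_range, seed = seed),
            class = "study_config")
}

#' Run the full cross-task analysis on a study
#'
#' End-to-end orchestration: per participant, the catch-trial guess rate,
#' the kill-the-twin correction of the visual-only distribution (skipped
#' when the dataset metadata records that it was already applied at
#' source), race-model tests over the SOA grid with the contiguity-rule
#' RT window, the slice-sampled psychometric posterior with its 5th/95th
#' percentile TOJ window, the non-performer exclusion, and the dissociation
#' classification; at the group level, the exact sign-permutation test on D
#' per SOA, the group psychometric curve, and the malleable vs.
#' non-malleable comparison. The group-level analyses are illustrative;
#' inference is per participant.
#'
#' Deterministic given `config$seed`; the result serializes to JSON via
#' [report_json()].
#'
#' @param dataset a [study_dataset()].
#' @param config a [study_config()].
#' @param quiet suppress per-stage progress messages (default TRUE).
#' @return Object of class `study_report`.
#' @export
run_study <- function(dataset, config = study_config(), quiet = TRUE) {
  stopifnot(inherits(dataset, "study_dataset"))
  say <- function(...) if (!quiet) message(sprintf(...))
  soas <- soa_grid()
  twin_done <- isTRUE(dataset$metadata$kill_the_twin_already_applied)

  per <- lapply(seq_along(dataset$participants), function(i) {
    p <- dataset$participants[[i]]
    say("participant %s: race-model tests", p$id)
    catch <- get_condition(p, "catch")
    gr <- guess_rate(catch)
    pseed <- substream_seed(config$seed, 11L, i)
    race <- race_test_grid(p, soas = soas, n_iter = config$n_iter,
                           alpha = config$alpha, seed = pseed,
                           percentiles = config$percentiles,
                           kill_twin_observed = !twin_done)
    rt_win <- rt_twi(race)
    say("participant %s: psychometric fit", p$id)
    set.seed(substream_seed(config$seed, 12L, i))
    post <- slice_sample_posterior(p$toj, priors = config$priors,
                                   n_samples = config$n_samples,
                                   burn_in = config$burn_in,
                                   thin = config$thin)
    toj_win <- toj_twi(post)
    excl <- exclude_nonperformers(toj_win, config$soa_range)
    cls <- detect_dissociation(race, rt_win, toj_win, p$toj, id = p$id)
    list(id = p$id, guess_rate = gr, race = race, rt_twi = rt_win,
         posterior_medians = apply(post$draws, 2, stats::median),
         diagnostics = post$diagnostics, posterior = post,
         toj_twi = toj_win, retained = excl$keep,
         exclusion_reason = excl$reason, classification = cls)
  })

  say("group-level analyses")
  # sign-permutation per SOA over participants with a testable D
  group_race <- lapply(seq_along(soas), function(j) {
    d <- vapply(per, function(pp) pp$race[[j]]$d, numeric(1))
    ok <- is.finite(d)
    if (sum(ok) < 1L)
      return(list(soa = soas[j], n = 0L, sum_d = NA_real_, p = NA_real_))
    gp <- group_sign_permutation(d[ok])
    list(soa = soas[j], n = sum(ok), sum_d = gp$sum_d, p = gp$p)
  })

  retained <- per[vapply(per, function(pp) isTRUE(pp$retained), logical(1))]
  group_psy <- if (length(retained))
    group_psychometric(lapply(retained, `[[`, "posterior")) else NULL

  # group RT window from the group-level sign-permutation results
  group_rt_results <- lapply(group_race, function(g) {
    structure(list(soa = g$soa, d = g$sum_d, p = g$p,
                   significant = is.finite(g$p) && g$p < config$alpha,
                   untestable = !is.finite(g$p)),
              class = "race_test_result")
  })
  group_rt_win <- rt_twi(group_rt_results)

  cls_df <- do.call(rbind, lapply(retained, function(pp) {
    data.frame(id = pp$id, malleable = pp$classification$malleable,
               rt_lower = if (is.null(pp$rt_twi)) NA_real_ else pp$rt_twi$lower,
               rt_upper = if (is.null(pp$rt_twi)) NA_real_ else pp$rt_twi$upper,
               rt_width = if (is.null(pp$rt_twi)) NA_real_ else
                 pp$rt_twi$upper - pp$rt_twi$lower,
               toj_lower = pp$toj_twi$threshold_a,
               toj_upper = pp$toj_twi$threshold_v,
               toj_width = pp$toj_twi$width,
               mean_toj_accuracy = pp$classification$mean_toj_accuracy,
               stringsAsFactors = FALSE)
  }))
  comparison <- if (!is.null(cls_df) && nrow(cls_df)) compare_groups(cls_df) else NULL

  structure(list(
    participants = per,
    classifications = cls_df,
    group = list(race_sign_permutation = group_race,
                 rt_twi = group_rt_win,
                 psychometric = group_psy,
                 comparison = comparison,
                 note = "group-level analyses are illustrative; inference is per participant"),
    provenance = list(seed = config$seed,
                      n_iter = config$n_iter, alpha = config$alpha,
                      n_samples = config$n_samples, burn_in = config$burn_in,
                      thin = config$thin,
                      source = dataset$metadata$source,
                      kill_the_twin_already_applied = twin_done)),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  n <- length(x$participants)
  n_ret <- sum(vapply(x$participants, function(p) isTRUE(p$retained), logical(1)))
  n_mall <- if (is.null(x$classifications)) 0L else sum(x$classifications$malleable)
  cat(sprintf("<study_report> %d participants (%d retained for TOJ), %d malleable\n",
              n, n_ret, n_mall))
  if (!is.null(x$group$rt_twi))
    cat(sprintf("  group RT TWI: [%+d, %+d] ms\n",
                x$group$rt_twi$lower, x$group$rt_twi$upper))
  if (!is.null(x$group$psychometric)) {
    thr <- x$group$psychometric$thresholds
    cat(sprintf("  group TOJ thresholds: [%.0f, %.0f] ms\n",
                thr[["auditory"]], thr[["visual"]]))
  }
  invisible(x)
}

#' Serialize a study report to JSON
#'
#' Produces a machine-readable summary of the report: per-participant race
#' results (D, p, significance, borderline flag), windows, posterior
#' medians, classifications, and all group-level statistics, plus
#' provenance. Posterior draws and null-distribution draws are omitted
#' (summaries only). Byte-identical for identical seeds and inputs.
#'
#' @param report a `study_report`.
#' @param path optional file path; if supplied the JSON is written there.
#' @return The JSON string (invisibly when `path` is given).
#' @export
report_json <- function(report, path = NULL) {
  per <- lapply(report$participants, function(pp) {
    list(id = pp$id,
         guess_rate = pp$guess_rate,
         race = lapply(pp$race, function(r)
           list(soa = r$soa, d = r$d, p = r$p, significant = r$significant,
                untestable = r$untestable, borderline = r$borderline)),
         rt_twi = if (is.null(pp$rt_twi)) NULL else
           list(lower = pp$rt_twi$lower, upper = pp$rt_twi$upper),
         posterior_medians = as.list(pp$posterior_medians),
         toj_twi = list(threshold_a = pp$toj_twi$threshold_a,
                        threshold_v = pp$toj_twi$threshold_v,
                        width = pp$toj_twi$width),
         retained = pp$retained,
         exclusion_reason = pp$exclusion_reason,
         malleable = pp$classification$malleable,
         dissociation_soas = pp$classification$dissociation_soas,
         mean_toj_accuracy = pp$classification$mean_toj_accuracy)
  })
  grp <- list(
    race_sign_permutation = report$group$race_sign_permutation,
    rt_twi = if (is.null(report$group$rt_twi)) NULL else
      list(lower = report$group$rt_twi$lower, upper = report$group$rt_twi$upper),
    psychometric = if (is.null(report$group$psychometric)) NULL else
      list(params = report$group$psychometric$params,
           thresholds = as.list(report$group$psychometric$thresholds)),
    comparison = report$group$comparison,
    note = report$group$note)
  out <- list(participants = per, group = grp, provenance = report$provenance)
  js <- jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
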