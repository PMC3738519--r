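#' Exclude trials with uncertain stimulus/response timing
#'
#' Trials whose logged timing uncertainty exceeds the threshold (strictly
#' greater) are removed; a trial at exactly the threshold is kept.
#'
#' @param trials data.frame with at least columns `latency` and
#'   `uncertainty` (nonnegative, ms).
#' @param threshold exclusion threshold in ms (default 5).
#' @return List with `trials` (the retained rows) and `n_excluded`.
#' @export
exclude_uncertain_trials <- function(trials, threshold = 5) {
  if (!nrow(trials)) return(list(trials = trials, n_excluded = 0L))
  stopifnot(all(trials$uncertainty >= 0))
  keep <- trials$uncertainty <= threshold
  list(trials = trials[keep, , drop = FALSE], n_excluded = sum(!keep))
}

#' Filter temporal-order-judgment false alarms and aggregate to counts
#'
#' Responses given earlier than 100 ms after the onset of the first stimulus
#' cannot reflect the order of both stimuli and are treated as false alarms.
#' Trials at exactly 100 ms are kept. The surviving trials are aggregated
#' into per-SOA (visual_first, n) counts; an SOA left with no trials keeps a
#' row with `n = 0` (it contributes a factor of one to the likelihood).
#'
#' @param trials data.frame with columns `soa` (ms), `latency` (ms from
#'   first-stimulus onset) and `visual_first` (logical response).
#' @param min_latency false-alarm cutoff in ms (default 100).
#' @return List with `toj` (a [toj_table()]) and `n_false_alarms`.
#' @export
filter_toj_false_alarms <- function(trials, min_latency = 100) {
  keep <- trials$latency >= min_latency
  kept <- trials[keep, , drop = FALSE]
  soas <- sort(unique(trials$soa))
  c_i <- vapply(soas, function(s) sum(kept$visual_first[kept$soa == s]), numeric(1))
  n_i <- vapply(soas, function(s) sum(kept$soa == s), numeric(1))
  list(toj = toj_table(soas, c_i, n_i), n_false_alarms = sum(!keep))
}

#' Kill-the-twin catch-trial correction
#'
#' Fast guesses inflate the apparent speed of stimulus-driven responses.
#' The catch (no-stimulus) condition measures the guessing process directly:
#' for each response observed on a catch trial, one response of similar
#' latency is removed from the target distribution and replaced by an
#' infinitely long reaction time, so the multiset size is preserved while
#' the guess's contribution to the fast tail is cancelled.
#'
#' "Similar latency" is operationalized by nearest-neighbour matching, with
#' catch responses processed in ascending latency order so the outcome is
#' deterministic:
#' * `"conservative"` (for observed data): removes the nearest finite target
#'   latency that is less than or equal to the catch latency, falling back
#'   to the overall nearest if no target latency lies at or below it.
#'   Preferentially cancelling fast responses makes race-model violation
#'   harder to declare.
#' * `"progressive"` (for resampled null data): removes the overall nearest
#'   finite latency; ties at equal distance remove the lower latency.
#'
#' If no finite latencies remain, leftover catch responses are ignored with
#' a warning.
#'
#' @param target a [condition_rts()] (or bare numeric vector) to correct;
#'   must be nonempty.
#' @param catch a [condition_rts()] (or numeric vector) of catch-trial
#'   latencies; only its finite entries (actual guesses) are used.
#' @param mode `"conservative"` or `"progressive"`.
#' @return Same type as `target`, with one latency per catch response
#'   replaced by `Inf`.
#' @export
kill_the_twin <- function(target, catch, mode = c("conservative", "progressive")) {
  mode <- match.arg(mode)
  as_cond <- inherits(target, "condition_rts")
  lat <- if (as_cond) target$latencies else as.numeric(target)
  if (!length(lat)) stop("kill_the_twin: target distribution is empty")
  guesses <- if (inherits(catch, "condition_rts")) catch$latencies else as.numeric(catch)
  guesses <- sort(guesses[is.finite(guesses)])
  for (g in guesses) {
    fin <- which(is.finite(lat))
    if (!length(fin)) {
      warning("kill_the_twin: no finite latencies left; ignoring remaining catch responses")
      break
    }
    cand <- if (mode == "conservative") fin[lat[fin] <= g] else integer(0)
    if (!length(cand)) cand <- fin
    d <- abs(lat[cand] - g)
    nearest <- cand[d == min(d)]
    # tie at equal distance: remove the lower latency
    kill <- nearest[which.min(lat[nearest])]
    lat[kill] <- Inf
  }
  if (as_cond) {
    target$latencies <- lat
    target
  } else lat
}

#' Catch-trial guess rate
#'
#' Fraction of catch trials on which the participant responded (guessed).
#'
#' @param catch a [condition_rts()] for the catch condition. Non-response
#'   catch trials may be stored as `Inf` entries or omitted, in which case
#'   `n_trials` supplies the denominator.
#' @param n_trials total number of catch trials presented (default: the
#'   number of entries stored, else 60).
#' @return Proportion in `[0, 1]`.
#' @export
guess_rate <- function(catch, n_trials = NULL) {
  lat <- if (inherits(catch, "condition_rts")) catch$latencies else as.numeric(catch)
  if (is.null(n_trials)) n_trials <- if (length(lat)) length(lat) else 60L
  sum(is.finite(lat)) / n_trials
}
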