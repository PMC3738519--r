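#' The bisensory SOA grid of the study design
#'
#' Stimulus onset asynchronies (SOAs) in ms at which audiovisual pairs are
#' presented: 0, +/-20, 40, 60, 80, 100, 120, 150, 200, 250, 300, 400.
#' Negative SOAs mean the auditory stimulus led the visual one; positive
#' SOAs mean the visual stimulus led. This sign convention is used
#' throughout the package.
#'
#' @return Integer vector of the 23 SOAs, sorted ascending.
#' @export
soa_grid <- function() {
  half <- c(20L, 40L, 60L, 80L, 100L, 120L, 150L, 200L, 250L, 300L, 400L)
  c(-rev(half), 0L, half)
}

#' Condition labels of the reaction-time task
#'
#' The 26 RT conditions: catch (no stimulus), the two unisensory conditions,
#' and the 23 audiovisual SOAs.
#' @param label one of `"catch"`, `"auditory_only"`, `"visual_only"`, `"av"`.
#' @param soa SOA in ms, required when `label == "av"`.
#' @return A character key, e.g. `"av_-40"`.
#' @export
condition_key <- function(label, soa = NULL) {
  if (identical(label, "av")) {
    stopifnot(!is.null(soa))
    sprintf("av_%d", as.integer(soa))
  } else {
    match.arg(label, c("catch", "auditory_only", "visual_only"))
  }
}

#' All 26 condition keys in canonical (dataset legend) order
#' @return Character vector, length 26: catch, auditory_only, the 23 SOAs
#'   ascending, visual_only.
#' @export
all_condition_keys <- function() {
  c("catch", "auditory_only", sprintf("av_%d", soa_grid()), "visual_only")
}

#' Construct the RT sample for one participant x condition
#'
#' A `condition_rts` holds the response latencies observed in one condition:
#' finite positive latencies in ms plus `Inf` entries coding misses (no
#' response) or latencies removed by the kill-the-twin correction.
#'
#' @param label condition label: `"catch"`, `"auditory_only"`,
#'   `"visual_only"` or `"av"`.
#' @param latencies numeric vector of latencies in ms; entries are finite
#'   positive or `Inf`.
#' @param soa SOA in ms for `"av"` conditions; must lie on [soa_grid()].
#'   `NA` for the other conditions.
#' @return An object of class `condition_rts`.
#' @export
condition_rts <- function(label, latencies = numeric(0), soa = NA_integer_) {
  label <- match.arg(label, c("catch", "auditory_only", "visual_only", "av"))
  latencies <- as.numeric(latencies)
  if (anyNA(latencies)) stop("latencies must not contain NA")
  fin <- latencies[is.finite(latencies)]
  if (any(fin <= 0)) stop("all finite latencies must be > 0")
  if (identical(label, "av")) {
    soa <- as.integer(soa)
    if (is.na(soa) || !soa %in% soa_grid())
      stop("av condition requires an SOA on the design grid; got ", soa)
  } else {
    soa <- NA_integer_
  }
  structure(list(label = label, soa = soa, latencies = latencies),
            class = "condition_rts")
}

#' @export
print.condition_rts <- function(x, ...) {
  n_inf <- sum(is.infinite(x$latencies))
  cat(sprintf("<condition_rts> %s%s: %d trials (%d finite, %d infinite)\n",
              x$label, if (!is.na(x$soa)) sprintf(" soa=%+d", x$soa) else "",
              length(x$latencies), length(x$latencies) - n_inf, n_inf))
  invisible(x)
}

#' Number of finite (responded) latencies in a condition
#' @param x a `condition_rts`.
#' @return Integer count.
#' @export
n_finite <- function(x) sum(is.finite(x$latencies))

#' Construct a temporal-order-judgment count table
#'
#' One row per SOA: `n` trials presented, `visual_first` of them answered
#' "visual came first". Unisensory trials do not appear in this table.
#'
#' @param soa integer SOAs in ms, strictly increasing.
#' @param visual_first counts of "visual-first" responses, `0 <= c <= n`.
#' @param n total trial counts per SOA (`n = 0` rows are allowed; they
#'   contribute nothing to the likelihood).
#' @return A `data.frame` of class `toj_table` with columns
#'   `soa`, `visual_first`, `n`.
#' @export
toj_table <- function(soa, visual_first, n) {
  soa <- as.integer(soa); visual_first <- as.integer(visual_first); n <- as.integer(n)
  stopifnot(length(soa) == length(visual_first), length(soa) == length(n))
  if (is.unsorted(soa, strictly = TRUE))
    stop("SOAs must be strictly increasing")
  bad <- which(visual_first < 0 | n < 0 | visual_first > n)
  if (length(bad))
    stop("invalid counts (need 0 <= visual_first <= n) at rows: ",
         paste(bad, collapse = ", "))
  structure(data.frame(soa = soa, visual_first = visual_first, n = n),
            class = c("toj_table", "data.frame"))
}

#' Assemble one participant's data
#'
#' @param id participant identifier (coerced to character).
#' @param rt named list of 26 [condition_rts()], one per key in
#'   [all_condition_keys()].
#' @param toj a [toj_table()].
#' @return An object of class `participant_data`.
#' @export
participant_data <- function(id, rt, toj) {
  keys <- all_condition_keys()
  missing <- setdiff(keys, names(rt))
  if (length(missing))
    stop("participant ", id, ": missing RT conditions: ",
         paste(missing, collapse = ", "))
  if (!inherits(toj, "toj_table")) stop("toj must be a toj_table")
  structure(list(id = as.character(id), rt = rt[keys], toj = toj),
            class = "participant_data")
}

#' Extract one RT condition from a participant
#' @param participant a `participant_data`.
#' @param label,soa as in [condition_key()].
#' @return A `condition_rts`.
#' @export
get_condition <- function(participant, label, soa = NULL) {
  participant$rt[[condition_key(label, soa)]]
}

#' Assemble a study dataset
#'
#' @param participants list of [participant_data()] objects with unique ids.
#' @param metadata named list of provenance: at least `source`; for synthetic
#'   studies also the RNG seed and ground-truth parameters; for the original
#'   dataset the flag `kill_the_twin_already_applied`.
#' @return An object of class `study_dataset`.
#' @export
study_dataset <- function(participants, metadata = list(source = "unknown")) {
  ids <- vapply(participants, function(p) p$id, character(1))
  if (anyDuplicated(ids)) stop("participant ids must be unique")
  structure(list(participants = participants, metadata = metadata),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d participants (source: %s)\n",
              length(x$participants),
              if (is.null(x$metadata$source)) "unknown" else x$metadata$source))
  invisible(x)
}
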