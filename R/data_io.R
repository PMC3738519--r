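#' Write a study to the native plain-text format
#'
#' The native dialect is two comma-separated UTF-8 tables with header rows.
#' `rt.csv` has one row per trial: `participant,condition,soa,latency`,
#' where `condition` is `catch` / `auditory_only` / `visual_only` / `av`,
#' `soa` is the signed SOA in ms for `av` rows (empty otherwise) and
#' `latency` is the latency in ms or the literal token `inf` for an
#' infinitely long reaction time (miss or killed twin). `toj.csv` has one
#' row per participant x SOA: `participant,soa,visual_first,n`. Conditions
#' with zero trials produce no rows and are reconstructed as empty on read,
#' so the round trip is lossless. If the dataset carries metadata it is
#' written alongside as `metadata.json`.
#'
#' @param dataset a [study_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths of the files written.
#' @seealso [read_native()]
#' @export
write_native <- function(dataset, dir) {
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rt_rows <- do.call(rbind, lapply(dataset$participants, function(p) {
    do.call(rbind, lapply(p$rt, function(cond) {
      if (!length(cond$latencies)) return(NULL)
      data.frame(participant = p$id, condition = cond$label,
                 soa = ifelse(is.na(cond$soa), "", as.character(cond$soa)),
                 latency = ifelse(is.finite(cond$latencies),
                                  format(cond$latencies, digits = 15,
                                         scientific = FALSE, trim = TRUE),
                                  "inf"),
                 stringsAsFactors = FALSE)
    }))
  }))
  toj_rows <- do.call(rbind, lapply(dataset$participants, function(p) {
    cbind(participant = p$id, as.data.frame(p$toj))
  }))
  rt_path <- file.path(dir, "rt.csv")
  toj_path <- file.path(dir, "toj.csv")
  utils::write.csv(rt_rows, rt_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(toj_rows, toj_path, row.names = FALSE, quote = FALSE)
  paths <- c(rt = rt_path, toj = toj_path)
  if (length(dataset$metadata)) {
    meta_path <- file.path(dir, "metadata.json")
    jsonlite::write_json(dataset$metadata, meta_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths <- c(paths, metadata = meta_path)
  }
  invisible(paths)
}

#' Read a study from the native plain-text format
#'
#' Inverse of [write_native()]. Every participant is given all 26 RT
#' conditions; conditions absent from the file come back empty. Validation
#' errors name the offending rows.
#'
#' @param rt_path path to the trial-level RT table.
#' @param toj_path path to the TOJ count table.
#' @param metadata_path optional path to a JSON metadata file.
#' @return A [study_dataset()].
#' @export
read_native <- function(rt_path, toj_path, metadata_path = NULL) {
  rt <- utils::read.csv(rt_path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       condition = "character",
                                       soa = "character",
                                       latency = "character"))
  toj <- utils::read.csv(toj_path, stringsAsFactors = FALSE,
                         colClasses = c(participant = "character"))
  lat <- suppressWarnings(ifelse(tolower(trimws(rt$latency)) == "inf", Inf,
                                 as.numeric(rt$latency)))
  bad <- which(is.na(lat) | lat <= 0)
  if (length(bad))
    stop("rt table: non-positive or unparseable latencies at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  soa_num <- suppressWarnings(as.integer(rt$soa))
  bad <- which(rt$condition == "av" & !(soa_num %in% soa_grid()))
  if (length(bad))
    stop("rt table: av rows with SOA off the design grid at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  bad <- which(toj$visual_first < 0 | toj$n < 0 | toj$visual_first > toj$n)
  if (length(bad))
    stop("toj table: invalid counts (need 0 <= visual_first <= n) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))

  ids <- unique(c(rt$participant, toj$participant))
  participants <- lapply(ids, function(id) {
    r <- rt[rt$participant == id, , drop = FALSE]
    l <- lat[rt$participant == id]
    conds <- stats::setNames(vector("list", 26L), all_condition_keys())
    for (key in names(conds)) {
      if (startsWith(key, "av_")) {
        s <- as.integer(sub("^av_", "", key))
        sel <- r$condition == "av" & soa_num[rt$participant == id] == s
        conds[[key]] <- condition_rts("av", l[sel], soa = s)
      } else {
        sel <- r$condition == key
        conds[[key]] <- condition_rts(key, l[sel])
      }
    }
    tt <- toj[toj$participant == id, , drop = FALSE]
    tt <- tt[order(tt$soa), , drop = FALSE]
    participant_data(id, conds, toj_table(tt$soa, tt$visual_first, tt$n))
  })
  metadata <- if (!is.null(metadata_path) && file.exists(metadata_path)) {
    jsonlite::read_json(metadata_path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE)
  } else list(source = "native_csv")
  study_dataset(participants, metadata)
}

#' Read the original MAT-container study layout
#'
#' Reads the published study dataset: one MAT (v5) file holding a structure
#' with one substructure per participant, each containing a 26 x 60 cell
#' array of reaction times (condition order: catch, auditory-only, the 23
#' SOAs from -400 to +400 ms ascending, visual-only; misses coded `Inf`) and
#' a 23 x 3 temporal-order-judgment array (SOA, visual-first count, total).
#' The MAT container is decoded by a bundled Python helper (scipy.io) into
#' the native CSV dialect, which is then read by [read_native()].
#'
#' The RT data in this layout have already undergone the kill-the-twin
#' correction, and the TOJ counts already exclude sub-100 ms false alarms;
#' both facts are recorded in the returned metadata
#' (`kill_the_twin_already_applied`, `toj_false_alarms_already_excluded`)
#' so the pipeline does not reapply the corrections.
#'
#' @param path path to the `.mat` file.
#' @param python name/path of the Python interpreter with scipy available.
#' @return A [study_dataset()].
#' @export
read_dataset_s1 <- function(path, python = "python") {
  if (!file.exists(path)) stop("no such file: ", path)
  script <- system.file("py", "mat_to_native.py", package = "mtwi")
  if (!nzchar(script)) stop("bundled converter inst/py/mat_to_native.py not found")
  out_dir <- tempfile("mat_native_")
  dir.create(out_dir)
  res <- suppressWarnings(
    system2(python, c(shQuote(script), shQuote(path), shQuote(out_dir)),
            stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0)
    stop("MAT conversion failed: ", paste(res, collapse = "\n"))
  ds <- read_native(file.path(out_dir, "rt.csv"), file.path(out_dir, "toj.csv"))
  ds$metadata <- list(source = paste0("mat:", basename(path)),
                      kill_the_twin_already_applied = TRUE,
                      toj_false_alarms_already_excluded = TRUE)
  ds
}
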