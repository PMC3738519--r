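#!/usr/bin/env Rscript
# Stage 4: cross-task comparison and malleability classification.
#
# Joins the RT-defined and TOJ-defined windows from stages 2-3, finds the
# dissociation SOAs (significant race-model violation inside the RT window
# but outside the TOJ window), classifies each participant as malleable or
# not, and runs the group statistics: pooled-variance t-tests on widths and
# boundaries, and the two-factor (task x group) ANOVA on window widths.
# Writes results/classifications.csv and results/group_comparison.json.

library(mtwi)

race <- read.csv(file.path("results", "race_results.csv"),
                 colClasses = c(participant = "character"))
twi <- read.csv(file.path("results", "rt_twi.csv"),
                colClasses = c(participant = "character"))
toj <- read.csv(file.path("results", "toj_results.csv"),
                colClasses = c(participant = "character"))
study <- read_native(file.path("results", "data", "rt.csv"),
                     file.path("results", "data", "toj.csv"),
                     file.path("results", "data", "metadata.json"))

cls_rows <- list()
for (i in seq_along(study$participants)) {
  p <- study$participants[[i]]
  if (!toj$retained[toj$participant == p$id]) next
  r <- race[race$participant == p$id, ]
  race_res <- lapply(seq_len(nrow(r)), function(j)
    structure(list(soa = r$soa[j], significant = r$significant[j],
                   untestable = r$untestable[j]), class = "race_test_result"))
  tw <- twi[twi$participant == p$id, ]
  rt_win <- if (is.na(tw$lower)) NULL else
    structure(list(lower = tw$lower, upper = tw$upper), class = "rt_twi")
  tj <- toj[toj$participant == p$id, ]
  toj_win <- structure(list(threshold_a = tj$threshold_a,
                            threshold_v = tj$threshold_v,
                            width = tj$width), class = "toj_twi")
  cls <- detect_dissociation(race_res, rt_win, toj_win, p$toj, id = p$id)
  cls_rows[[length(cls_rows) + 1L]] <- data.frame(
    id = p$id, malleable = cls$malleable,
    dissociation_soas = paste(cls$dissociation_soas, collapse = ";"),
    mean_toj_accuracy = cls$mean_toj_accuracy,
    rt_lower = tw$lower, rt_upper = tw$upper,
    rt_width = tw$upper - tw$lower,
    toj_lower = tj$threshold_a, toj_upper = tj$threshold_v,
    toj_width = tj$width)
  cat(sprintf("participant %s: %s%s\n", p$id,
              if (cls$malleable) "malleable" else "not malleable",
              if (cls$malleable)
                sprintf(" (dissociation at %s; mean TOJ accuracy %.1f%%)",
                        paste(sprintf("%+d", cls$dissociation_soas),
                              collapse = ", "),
                        100 * cls$mean_toj_accuracy) else ""))
}
cls_df <- do.call(rbind, cls_rows)
write.csv(cls_df, file.path("results", "classifications.csv"),
          row.names = FALSE)

cmp <- compare_groups(cls_df)
print(cmp)
jsonlite::write_json(cmp, file.path("results", "group_comparison.json"),
                     auto_unbox = TRUE, digits = NA, force = TRUE,
                     pretty = TRUE)
if (!is.null(study$metadata$ground_truth)) {
  truth_narrow <- vapply(study$metadata$ground_truth$toj_params,
                         function(tp) tp$sigma, numeric(1)) <= 50
  hit <- all(cls_df$malleable == truth_narrow[as.integer(cls_df$id)])
  cat(sprintf("classification matches the generator's ground truth: %s\n", hit))
}
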