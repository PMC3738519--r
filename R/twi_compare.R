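#' Detect task-demand dissociation for one participant
#'
#' A dissociation SOA is one where the RT task shows integration
#' (significant race-model violation, inside the RT-defined window) while
#' the TOJ task shows segregation (the SOA lies strictly outside the
#' TOJ-defined window, i.e. order judgment is above threshold there).
#' A participant with at least one dissociation SOA is classified as having
#' a malleable window. The reverse pattern (chance TOJ without race
#' violation) is never counted: absence of evidence for violation is not
#' evidence of its absence.
#'
#' TOJ accuracy at a dissociation SOA is the proportion of correct order
#' reports: `visual_first/n` at positive SOAs, `(n - visual_first)/n` at
#' negative SOAs (at SOA 0 the larger of the two, though SOA 0 can only
#' dissociate if the TOJ window excludes 0).
#'
#' @param race_results list of `race_test_result` (from [race_test_grid()]).
#' @param rt_win an [rt_twi()] or `NULL`.
#' @param toj_win a [toj_twi()].
#' @param toj the participant's [toj_table()].
#' @param id participant identifier.
#' @return Object of class `participant_classification`: list with `id`,
#'   `dissociation_soas`, `malleable`, `mean_toj_accuracy` (`NA` if none).
#' @export
detect_dissociation <- function(race_results, rt_win, toj_win, toj, id = NA) {
  dis <- integer(0)
  if (!is.null(rt_win)) {
    sig <- vapply(race_results, function(r) isTRUE(r$significant), logical(1))
    soas <- vapply(race_results, function(r) r$soa, numeric(1))
    inside_rt <- soas >= rt_win$lower & soas <= rt_win$upper
    outside_toj <- soas < toj_win$threshold_a | soas > toj_win$threshold_v
    dis <- sort(soas[sig & inside_rt & outside_toj])
  }
  acc <- NA_real_
  if (length(dis)) {
    acc <- mean(vapply(dis, function(s) {
      row <- toj[toj$soa == s, , drop = FALSE]
      if (!nrow(row) || row$n == 0) return(NA_real_)
      if (s > 0) row$visual_first / row$n
      else if (s < 0) (row$n - row$visual_first) / row$n
      else max(row$visual_first, row$n - row$visual_first) / row$n
    }, numeric(1)), na.rm = TRUE)
  }
  structure(list(id = id, dissociation_soas = dis,
                 malleable = length(dis) > 0L, mean_toj_accuracy = acc),
            class = "participant_classification")
}

#' Group comparison of window widths and boundaries
#'
#' Compares participants classified as malleable vs. non-malleable on the
#' widths and boundaries of the two windows with pooled-variance two-sample
#' t-tests, and fits a two-factor between-subjects ANOVA on window width
#' with factors task (RT vs. TOJ) and group (malleable vs. not), using
#' Type II sums of squares (appropriate for the unbalanced design; the
#' interaction F is identical across SS types here).
#'
#' @param classifications data.frame with one row per participant and
#'   columns `id`, `malleable` (logical), `rt_lower`, `rt_upper`,
#'   `rt_width`, `toj_lower`, `toj_upper`, `toj_width` (ms; `NA` allowed
#'   for participants without an RT window).
#' @param anova_type sums-of-squares type for [car::Anova()] (default 2).
#' @return List of class `group_comparison`: per-measure group means/SDs,
#'   t-tests (`t`, `df`, `p`), and the ANOVA table (`F`, `p` for task,
#'   group, interaction), or a marker that the comparison is not applicable
#'   when a group is empty.
#' @export
compare_groups <- function(classifications, anova_type = 2) {
  cls <- classifications
  g1 <- cls[cls$malleable, , drop = FALSE]
  g2 <- cls[!cls$malleable, , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g2) < 2L) {
    return(structure(list(applicable = FALSE,
                          n_malleable = nrow(g1), n_other = nrow(g2)),
                     class = "group_comparison"))
  }
  measures <- c(toj_width = "toj_width", rt_width = "rt_width",
                toj_boundary_visual = "toj_upper",
                toj_boundary_auditory = "toj_lower",
                rt_boundary_lower = "rt_lower", rt_boundary_upper = "rt_upper")
  ttests <- lapply(measures, function(col) {
    a <- g1[[col]]; b <- g2[[col]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) < 2L || length(b) < 2L)
      return(list(applicable = FALSE))
    df <- length(a) + length(b) - 2
    pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) / df
    if (pooled > 0) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tval <- unname(tt$statistic); pval <- tt$p.value
    } else { # degenerate: both groups constant
      tval <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      pval <- if (tval == 0) 1 else 0
    }
    list(applicable = TRUE,
         mean_malleable = mean(a), sd_malleable = stats::sd(a),
         mean_other = mean(b), sd_other = stats::sd(b),
         t = tval, df = df, p = pval)
  })
  long <- rbind(
    data.frame(width = cls$rt_width, task = "RT",
               group = ifelse(cls$malleable, "malleable", "non_malleable")),
    data.frame(width = cls$toj_width, task = "TOJ",
               group = ifelse(cls$malleable, "malleable", "non_malleable")))
  long <- long[is.finite(long$width), , drop = FALSE]
  long$task <- factor(long$task); long$group <- factor(long$group)
  fit <- stats::lm(width ~ task * group, data = long)
  tab <- car::Anova(fit, type = anova_type)
  rn <- rownames(tab)
  pick <- function(term) {
    i <- match(term, rn)
    list(F = tab[i, "F value"], p = tab[i, "Pr(>F)"])
  }
  task_means <- tapply(long$width, long$task, mean)
  task_sds <- tapply(long$width, long$task, stats::sd)
  group_means <- tapply(long$width, long$group, mean)
  group_sds <- tapply(long$width, long$group, stats::sd)
  structure(list(
    applicable = TRUE,
    n_malleable = nrow(g1), n_other = nrow(g2),
    t_tests = ttests,
    anova = list(task = pick("task"), group = pick("group"),
                 interaction = pick("task:group"),
                 table = as.data.frame(tab)),
    width_by_task = list(mean = as.list(task_means), sd = as.list(task_sds)),
    width_by_group = list(mean = as.list(group_means), sd = as.list(group_sds))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (!isTRUE(x$applicable)) {
    cat("<group_comparison> not applicable (a group has fewer than 2 participants)\n")
    return(invisible(x))
  }
  cat(sprintf("<group_comparison> %d malleable vs %d non-malleable\n",
              x$n_malleable, x$n_other))
  tw <- x$t_tests$toj_width
  if (isTRUE(tw$applicable))
    cat(sprintf("  TOJ width: %.0f (%.0f) vs %.0f (%.0f) ms, t=%.3f, p=%.4f\n",
                tw$mean_malleable, tw$sd_malleable, tw$mean_other, tw$sd_other,
                tw$t, tw$p))
  cat(sprintf("  ANOVA width ~ task*group: F_task=%.2f (p=%.4f), F_int=%.2f (p=%.4f)\n",
              x$anova$task$F, x$anova$task$p,
              x$anova$interaction$F, x$anova$interaction$p))
  invisible(x)
}
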