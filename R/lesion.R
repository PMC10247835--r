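# Lesion-level aggregation (volumes over the 1-mm frame stack) and the
# cohort-level four-group classification with post-procedural finding
# cross-tabulation.

#' Integrate per-frame areas into lesion volumes
#'
#' Volumes are the per-frame areas times the frame spacing, summed over the
#' included (non-excluded) frames of one lesion and one prediction mode:
#' the 1-mm-interval analogue of a rectangle rule.  \%Correct volume is
#' 100 O-vol / P-vol and \%Error volume 100 (A-vol - O-vol) / A-vol; note the
#' volume percentages are P-(or A-)area-weighted, not means of the per-frame
#' percentages.  Mean angles and mean percentages are arithmetic means over
#' included frames.
#'
#' @param frames Per-frame metrics `data.frame` (one lesion, one mode) as
#'   produced by [compute_frame_metrics()], sorted or sortable by `z_mm`.
#' @param spacing Frame spacing (mm, default 1).
#' @param lesion_id Optional identifier copied into the result.
#' @return One-row `data.frame` of lesion metrics.
#' @export
integrate_volumes <- function(frames, spacing = 1.0, lesion_id = NA) {
  if (is.null(frames) || nrow(frames) == 0L) stop("no frames to integrate")
  if (length(unique(frames$mode)) > 1L)
    stop("frames mix prediction modes; integrate one mode at a time")
  frames <- frames[order(frames$z_mm), , drop = FALSE]
  if (nrow(frames) > 1L) {
    dz <- diff(frames$z_mm)
    if (any(abs(dz - spacing) > 1e-6))
      stop("non-uniform frame spacing: expected ", spacing, " mm")
  }
  inc <- frames[!frames$excluded, , drop = FALSE]
  if (nrow(inc) == 0L) stop("all frames excluded; lesion has no analyzable frames")
  p_vol <- sum(inc$p_area) * spacing
  a_vol <- sum(inc$a_area) * spacing
  o_vol <- sum(inc$o_area) * spacing
  data.frame(
    lesion_id = lesion_id, mode = inc$mode[1], n_frames = nrow(inc),
    p_volume = p_vol, a_volume = a_vol, o_volume = o_vol,
    pct_correct_volume = if (p_vol > 0) 100 * o_vol / p_vol else NA_real_,
    pct_error_volume = if (a_vol > 0) 100 * (a_vol - o_vol) / a_vol else NA_real_,
    mean_p_angle = mean(inc$p_angle), mean_a_angle = mean(inc$a_angle),
    mean_o_angle = mean(inc$o_angle),
    mean_pct_correct_angle = mean(inc$pct_correct_angle),
    mean_pct_error_angle = mean(inc$pct_error_angle),
    mean_pct_correct_area = mean(inc$pct_correct_area),
    mean_pct_error_area = mean(inc$pct_error_area),
    stringsAsFactors = FALSE
  )
}

#' Lesion metrics for a whole cohort frame table
#'
#' @param frame_table Frame metrics with `lesion_id` and `mode` columns.
#' @param spacing Frame spacing (mm).
#' @return `data.frame`, one row per lesion x mode.
#' @export
lesion_metrics <- function(frame_table, spacing = 1.0) {
  parts <- split(frame_table,
                 list(frame_table$lesion_id, frame_table$mode), drop = TRUE)
  out <- lapply(parts, function(df)
    integrate_volumes(df, spacing = spacing, lesion_id = df$lesion_id[1]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$lesion_id, out$mode), , drop = FALSE]
}

#' Four-group prediction-quality labels
#' @export
ra_group_levels <- c("good_prediction", "over_ablation",
                     "insufficient_ablation", "irrelevant_ablation")

#' Median-split four-group classification
#'
#' Splits analyzable frames at the cohort medians of the \%Correct and
#' \%Error metrics into: good prediction (high correct / low error), over
#' ablation (high / high), insufficient ablation (low / low), and irrelevant
#' ablation (low correct / high error).  "High" means at or above the median
#' (deterministic half-open split).
#'
#' @param frame_table Frame metrics (typically one prediction mode).
#' @param correct_field,error_field Column names of the split metrics.
#' @return List with `labels` (factor over [ra_group_levels] aligned to the
#'   analyzable rows), `analyzable` (logical row mask), `median_correct`,
#'   `median_error`.
#' @export
median_split_groups <- function(frame_table,
                                correct_field = "pct_correct_area",
                                error_field = "pct_error_area") {
  cv <- frame_table[[correct_field]]
  ev <- frame_table[[error_field]]
  if (is.null(cv) || is.null(ev)) stop("split fields not found in frame table")
  ok <- !is.na(cv) & !is.na(ev)
  if (sum(ok) < 2L) stop("need at least 2 analyzable frames for a median split")
  mc <- median(cv[ok]); me <- median(ev[ok])
  if (sd(cv[ok]) == 0 || sd(ev[ok]) == 0)
    warning("all-identical split metric: every frame classed 'high' by the >= rule")
  hiC <- cv[ok] >= mc; hiE <- ev[ok] >= me
  lab <- ifelse(hiC & !hiE, "good_prediction",
         ifelse(hiC & hiE, "over_ablation",
         ifelse(!hiC & !hiE, "insufficient_ablation", "irrelevant_ablation")))
  list(labels = factor(lab, levels = ra_group_levels),
       analyzable = ok, median_correct = mc, median_error = me)
}

#' Cross-tabulate a post-procedural finding against the four groups
#'
#' Builds the 4 x 2 contingency table of group label against a boolean
#' finding and tests for association with a chi-square test, falling back to
#' Fisher's exact test when any expected cell count is below 5.  A finding
#' that never (or always) occurs makes the test degenerate; this is reported
#' as no association rather than an error.
#'
#' @param labels Factor of group labels (levels [ra_group_levels]).
#' @param findings Logical vector, same length.
#' @return List with `table`, `method`, `statistic`, `p_value`, `degenerate`.
#' @export
crosstab_findings <- function(labels, findings) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(findings)) stop("labels and findings differ in length")
  labels <- factor(labels, levels = ra_group_levels)
  tab <- table(group = labels, finding = factor(findings, levels = c(FALSE, TRUE)))
  if (length(unique(findings)) < 2L)
    return(list(table = tab, method = "degenerate", statistic = 0,
                p_value = NA_real_, degenerate = TRUE))
  tab_test <- tab[rowSums(tab) > 0, , drop = FALSE]  # empty groups carry no information
  ct <- suppressWarnings(chisq.test(tab_test))
  if (any(ct$expected < 5)) {
    ft <- fisher.test(tab_test)
    list(table = tab, method = "fisher", statistic = NA_real_,
         p_value = ft$p.value, degenerate = FALSE)
  } else {
    list(table = tab, method = "chi-square",
         statistic = unname(ct$statistic), p_value = ct$p.value,
         degenerate = FALSE)
  }
}
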