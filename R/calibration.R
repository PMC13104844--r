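# ROC analysis, FPR-based threshold calibration and classification over
# benchmark score tables.
#
# A benchmark table has one row per protein pair: `pair_id`, `set_label`
# (e.g. PRS-yeast / PRS-fly / PRS-human / ELM for positives; RRS / GFP / Wg
# for controls), `class` ("positive" / "control"), a pLDDT subgroup and one
# numeric column per metric and model choice, named `<metric>_<choice>`
# (e.g. `ilis_best`, `iptm_avg`).

# metrics where a LOWER value means a better interface; these are negated
# before ranking so all ROC/threshold logic is higher-is-better
LOWER_IS_BETTER <- c("ifpae", "ifpae_d8")

#' Direction of a metric
#' @param metric Metric name (with or without a `_best`/`_avg` suffix).
#' @return `"higher"` or `"lower"` (better).
#' @export
metric_direction <- function(metric) {
  base <- sub("_(best|avg)$", "", metric)
  if (base %in% LOWER_IS_BETTER) "lower" else "higher"
}

#' ROC curve and AUC
#'
#' Ties are grouped (one ROC vertex per distinct score); AUC by the
#' trapezoidal rule, which equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.  Lower-is-better metrics must be negated by the caller
#' (see [metric_direction()]); [calibrate()] does this automatically.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param labels Logical or `"positive"`/`"control"` vector.
#' @return List with `fpr`, `tpr` (stepwise, starting at (0, 0)),
#'   `thresholds` and `auc`.
#' @export
roc <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) labels <- as.character(labels) == "positive"
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present for ROC analysis")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  last <- cumsum(rle(s)$lengths)            # last index of each tie group
  tpr <- c(0, cumsum(l)[last] / n_pos)
  fpr <- c(0, cumsum(!l)[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = c(Inf, s[last]), auc = auc)
}

#' Score threshold at a target false-positive rate
#'
#' Returns the smallest observed control score `t` such that the fraction of
#' controls with score `>= t` is at most `fpr` — the empirical analogue of
#' "the score at which `fpr` of control pairs exceed the threshold".  With
#' heavy ties no such `t` may exist; then the largest observed score is
#' returned with its (too-high) achieved FPR and a warning.
#'
#' @param control_scores Numeric scores of the control (negative) pairs;
#'   higher-is-better orientation.
#' @param fpr Target false-positive rate in (0, 1).
#' @return List with `threshold`, `achieved_fpr` (fraction of controls at or
#'   above the threshold) and `n_controls`.
#' @export
fpr_threshold <- function(control_scores, fpr) {
  if (!is.numeric(fpr) || fpr <= 0 || fpr >= 1) stop("fpr must lie in (0, 1)")
  s <- control_scores[!is.na(control_scores)]
  if (length(s) == 0) stop("no control scores")
  cand <- sort(unique(s))
  n <- length(s)
  for (t in cand) {
    achieved <- sum(s >= t) / n
    if (achieved <= fpr)
      return(list(threshold = t, achieved_fpr = achieved, n_controls = n))
  }
  t <- cand[length(cand)]
  achieved <- sum(s >= t) / n
  warning("no observed score attains FPR <= ", fpr,
          " (ties); returning the maximum with achieved FPR ", achieved)
  list(threshold = t, achieved_fpr = achieved, n_controls = n)
}

#' Calibrate classification thresholds on a benchmark table
#'
#' For every metric x model choice x pLDDT subgroup (plus the pooled
#' `"total"` stratum) x FPR level, computes the control-based threshold of
#' [fpr_threshold()].  Positives enter only the ROC/AUC summaries; the
#' thresholds are order statistics of the control scores, per the
#' FPR definition.  Lower-is-better metrics are negated internally and their
#' thresholds reported on the natural scale (classify with `<=`).
#'
#' @param table Benchmark data frame (see module header for the layout).
#' @param metrics Character vector of base metric names; default: every
#'   `<metric>_best` column present.
#' @param model_choices Subset of `c("best", "avg")`.
#' @param fpr_levels Numeric FPR levels, default `c(0.01, 0.05, 0.10)`.
#' @param positive_sets,control_sets `set_label` values used as positives
#'   (Y2H positive reference sets) and controls (random reference set plus
#'   the GFP and Wg compartment controls).
#' @param subgroups pLDDT strata; `"total"` pools everything.
#' @param boot_B Bootstrap replicates for the AUC confidence summaries
#'   (resampling pairs with replacement); 0 disables.
#' @param seed RNG seed for the bootstrap.
#' @return List with `thresholds` (data frame: metric, model_choice,
#'   subgroup, fpr_level, threshold, achieved_fpr, n_controls, direction) and
#'   `auc` (data frame with the total-set AUC and, if `boot_B > 0`,
#'   bootstrap mean/sd and percentile 95% CI).
#' @export
calibrate <- function(table,
                      metrics = NULL,
                      model_choices = c("best", "avg"),
                      fpr_levels = c(0.01, 0.05, 0.10),
                      positive_sets = c("PRS-yeast", "PRS-fly", "PRS-human"),
                      control_sets = c("RRS", "GFP", "Wg"),
                      subgroups = c("0-50", "50-70", "70-100", "total"),
                      boot_B = 0, seed = 1) {
  if (is.null(metrics)) {
    metrics <- sub("_best$", "", grep("_best$", names(table), value = TRUE))
    metrics <- setdiff(metrics, "plddt_subgroup")
  }
  is_pos <- table$class == "positive" & table$set_label %in% positive_sets
  is_ctrl <- table$class == "control" & table$set_label %in% control_sets
  sub_col <- table$plddt_subgroup

  thr_rows <- list(); auc_rows <- list()
  for (metric in metrics) for (choice in model_choices) {
    col <- paste0(metric, "_", choice)
    if (!col %in% names(table)) next
    dir <- metric_direction(metric)
    sgn <- if (dir == "lower") -1 else 1
    x <- sgn * table[[col]]
    for (sg in subgroups) {
      in_sg <- if (sg == "total") rep(TRUE, nrow(table)) else sub_col == sg
      ctrl <- x[is_ctrl & in_sg & !is.na(x)]
      for (f in fpr_levels) {
        if (length(ctrl) == 0) {
          thr_rows[[length(thr_rows) + 1L]] <- data.frame(
            metric = metric, model_choice = choice, subgroup = sg,
            fpr_level = f, threshold = NA_real_, achieved_fpr = NA_real_,
            n_controls = 0L, direction = dir, stringsAsFactors = FALSE)
        } else {
          th <- fpr_threshold(ctrl, f)
          thr_rows[[length(thr_rows) + 1L]] <- data.frame(
            metric = metric, model_choice = choice, subgroup = sg,
            fpr_level = f, threshold = sgn * th$threshold,
            achieved_fpr = th$achieved_fpr, n_controls = th$n_controls,
            direction = dir, stringsAsFactors = FALSE)
        }
      }
    }
    # total-set AUC (+ optional bootstrap over pairs)
    use <- (is_pos | is_ctrl) & !is.na(x)
    if (sum(is_pos & use) > 0 && sum(is_ctrl & use) > 0) {
      r <- roc(x[use], is_pos[use])
      row <- data.frame(metric = metric, model_choice = choice, auc = r$auc,
                        stringsAsFactors = FALSE)
      if (boot_B > 0) {
        set.seed(seed)
        xs <- x[use]; ls <- is_pos[use]; n <- length(xs)
        boots <- replicate(boot_B, {
          i <- sample.int(n, n, replace = TRUE)
          if (length(unique(ls[i])) < 2) NA_real_ else roc(xs[i], ls[i])$auc
        })
        row$boot_mean <- mean(boots, na.rm = TRUE)
        row$boot_sd <- stats::sd(boots, na.rm = TRUE)
        qs <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE)
        row$boot_lo <- qs[[1]]; row$boot_hi <- qs[[2]]
      }
      auc_rows[[length(auc_rows) + 1L]] <- row
    }
  }
  list(thresholds = do.call(rbind, thr_rows),
       auc = if (length(auc_rows)) do.call(rbind, auc_rows) else NULL)
}

#' Classify pairs against a calibrated threshold
#'
#' The boundary is inclusive: `score >= threshold` is positive for
#' higher-is-better metrics (`<=` for lower-is-better).  Missing scores are
#' classified negative and flagged.
#'
#' @param scores_table Data frame holding a `pair_id` column and the metric
#'   column named by `metric` (e.g. the output of [pair_scores_table()],
#'   columns like `best_ilis`, or a benchmark table, columns like
#'   `ilis_best`).
#' @param metric Column name to threshold.
#' @param threshold Finite numeric threshold.
#' @param direction `"higher"` or `"lower"`; default inferred from the
#'   metric name.
#' @return The input with added `label` (`"positive"`/`"negative"`) and
#'   `score_missing` columns.
#' @export
classify <- function(scores_table, metric, threshold,
                     direction = metric_direction(metric)) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  x <- scores_table[[metric]]
  if (is.null(x)) stop("column '", metric, "' not found")
  pos <- if (direction == "lower") x <= threshold else x >= threshold
  scores_table$label <- ifelse(!is.na(pos) & pos, "positive", "negative")
  scores_table$score_missing <- is.na(x)
  scores_table
}
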