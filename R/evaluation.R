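#' Welch two-sample t-test
#'
#' Two-sided t-test with Welch's correction for unequal variances
#' (Satterthwaite degrees of freedom).
#'
#' @param a,b Numeric vectors, each of length >= 2; at least one with
#'   nonzero variance.
#' @return List `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("welch_t_test: both groups need >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("welch_t_test: both groups have zero variance (degenerate data)")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Rank-based ROC area under the curve
#'
#' AUC oriented so that cases scoring LOWER than controls give values
#' above 0.5: `AUC = P(control > case) + 0.5 P(tie)`, the Mann-Whitney
#' `U/(n1*n2)` statistic.
#'
#' @param scores Numeric scores.
#' @param labels `"case"`/`"control"` per score; both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c("case", "control")))
  n_case <- sum(labels == "case"); n_ctrl <- sum(labels == "control")
  if (n_case == 0L || n_ctrl == 0L)
    stop("roc_auc: one class is empty")
  r <- rank(scores)
  (sum(r[labels == "control"]) - n_ctrl * (n_ctrl + 1) / 2) / (n_case * n_ctrl)
}

#' Compare case and control subject scores
#'
#' Bundles the Welch t-test and the rank AUC on per-subject corrected
#' complexity scores for one estimator x mask x heart-rate-band
#' combination.
#'
#' @param scores Data.frame from [subject_score()].
#' @param estimator,mask Metadata recorded in the result.
#' @param band Length-2 heart-rate band (bpm) recorded in the result.
#' @return One-row data.frame with group sizes, means, sds, Welch t, df,
#'   p and AUC.
#' @export
compare_groups <- function(scores, estimator = NA_character_,
                           mask = NA_integer_, band = c(NA_real_, NA_real_)) {
  stopifnot(all(c("label", "score") %in% names(scores)))
  a <- scores$score[scores$label == "case"]
  b <- scores$score[scores$label == "control"]
  if (length(a) < 2L || length(b) < 2L)
    stop("compare_groups: each group needs >= 2 subjects")
  wt <- welch_t_test(a, b)
  auc <- roc_auc(scores$score, scores$label)
  data.frame(estimator = estimator, mask = mask,
             hr_lo = band[1], hr_hi = band[2],
             n_cases = length(a), n_controls = length(b),
             mean_case = mean(a), sd_case = stats::sd(a),
             mean_control = mean(b), sd_control = stats::sd(b),
             t = wt$t, df = wt$df, p = wt$p, auc = auc)
}

#' Rank estimator x mask algorithms
#'
#' Orders comparison rows by ascending p-value, breaking ties by
#' descending AUC and then ascending mask code, the selection rule used
#' for picking the best-performing algorithm.
#'
#' @param comparisons Data.frame with `p`, `auc` and `mask` columns.
#' @return The data.frame sorted, with a `rank` column prepended.
#' @export
rank_algorithms <- function(comparisons) {
  stopifnot(nrow(comparisons) >= 1L)
  o <- order(comparisons$p, -comparisons$auc, comparisons$mask)
  out <- comparisons[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

.wald_ci <- function(phat, n) {
  half <- 1.96 * sqrt(phat * (1 - phat) / n)
  c(lo = max(0, phat - half), hi = min(1, phat + half))
}

#' Diagnostic test metrics with Wald intervals
#'
#' Sensitivity, specificity, positive and negative predictive values (in
#' percent) with 95% Wald (normal-approximation) confidence intervals
#' clipped to \[0, 100\]%, plus the clinical utility indices
#' `CUI+ = Se x PPV` and `CUI- = Sp x NPV` (as fractions).
#'
#' @param tp,fp,tn,fn Confusion-matrix counts; `tp+fn >= 1` and
#'   `tn+fp >= 1`.
#' @return List of class `diagnostic_metrics`; an undefined PPV (no
#'   positive predictions) is reported as `NA` with `ppv_defined = FALSE`.
#' @export
diagnostic_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("diagnostic_metrics: counts must be >= 0")
  if (tp + fn < 1L) stop("diagnostic_metrics: no positive-class subjects")
  if (tn + fp < 1L) stop("diagnostic_metrics: no negative-class subjects")
  prop <- function(num, den) {
    if (den == 0) return(list(pct = NA_real_, ci = c(lo = NA_real_, hi = NA_real_)))
    p <- num / den
    list(pct = 100 * p, ci = 100 * .wald_ci(p, den))
  }
  se <- prop(tp, tp + fn)
  sp <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp)
  npv <- prop(tn, tn + fn)
  structure(list(
    counts = counts,
    sensitivity = se$pct, sensitivity_ci = se$ci,
    specificity = sp$pct, specificity_ci = sp$ci,
    ppv = ppv$pct, ppv_ci = ppv$ci, ppv_defined = (tp + fp) > 0,
    npv = npv$pct, npv_ci = npv$ci, npv_defined = (tn + fn) > 0,
    cui_positive = if ((tp + fp) > 0) (se$pct / 100) * (ppv$pct / 100) else NA_real_,
    cui_negative = if ((tn + fn) > 0) (sp$pct / 100) * (npv$pct / 100) else NA_real_),
    class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  fmt <- function(p, ci) {
    if (is.na(p)) return("undefined")
    sprintf("%.1f%% (%.1f-%.1f%%)", p, ci[1], ci[2])
  }
  cat("Diagnostic performance (95% Wald CI):\n",
      "  sensitivity ", fmt(x$sensitivity, x$sensitivity_ci), "\n",
      "  specificity ", fmt(x$specificity, x$specificity_ci), "\n",
      "  PPV         ", fmt(x$ppv, x$ppv_ci), "\n",
      "  NPV         ", fmt(x$npv, x$npv_ci), "\n",
      sprintf("  CUI+ %.3f  CUI- %.3f\n", x$cui_positive, x$cui_negative),
      sep = "")
  invisible(x)
}

#' Confusion counts at a score threshold
#'
#' Predicts "case" when the corrected-complexity score falls BELOW the
#' threshold (cases score lower than controls) and tabulates the counts
#' against the true labels.
#'
#' @param scores Data.frame from [subject_score()].
#' @param threshold Finite decision threshold.
#' @return List `tp, fp, tn, fn`.
#' @export
classify_threshold <- function(scores, threshold) {
  if (!is.finite(threshold)) stop("classify_threshold: threshold must be finite")
  pred_case <- scores$score < threshold
  is_case <- scores$label == "case"
  list(tp = sum(pred_case & is_case), fp = sum(pred_case & !is_case),
       tn = sum(!pred_case & !is_case), fn = sum(!pred_case & is_case))
}
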