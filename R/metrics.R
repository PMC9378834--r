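#' Confusion counts against truth labels
#'
#' Tabulates predictions against truth with `case` as the positive class:
#' TP = true cases called case, FN = cases called control, TN = true
#' controls called control, FP = controls called case.
#'
#' @param predictions A tibble with columns `sample_id`, `label`
#'   (e.g. from [classify_matrix()]).
#' @param truth A tibble with columns `sample_id`, `label` holding the true
#'   classes; the sample id sets must match exactly.
#' @return A one-row tibble of class `confusion_counts` with columns `TP`,
#'   `FN`, `TN`, `FP`.
#' @export
confusion <- function(predictions, truth) {
  stopifnot(all(c("sample_id", "label") %in% names(predictions)),
            all(c("sample_id", "label") %in% names(truth)))
  if (!setequal(predictions$sample_id, truth$sample_id) ||
      anyDuplicated(predictions$sample_id) ||
      anyDuplicated(truth$sample_id)) {
    abort("prediction and truth sample id sets must match exactly")
  }
  pred <- predictions$label[match(truth$sample_id, predictions$sample_id)]
  is_case <- truth$label == "case"
  out <- tibble(TP = sum(is_case & pred == "case"),
                FN = sum(is_case & pred == "control"),
                TN = sum(!is_case & pred == "control"),
                FP = sum(!is_case & pred == "case"))
  structure(out, class = c("confusion_counts", class(out)))
}

#' Diagnostic performance metrics
#'
#' Computes sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/total, PPV TP/(TP+FP), NPV TN/(TN+FN), and the panel-selection
#' evaluation index sqrt(PPV x NPV). A quantity with a zero denominator is
#' returned as `NA` with a warning, never silently as 0.
#'
#' @param counts A `confusion_counts` tibble (or any one-row data frame /
#'   list with elements `TP`, `FN`, `TN`, `FP`).
#' @return A one-row tibble: `sensitivity`, `specificity`, `accuracy`,
#'   `ppv`, `npv`, `eval_index`.
#' @examples
#' diagnostic_metrics(list(TP = 196, FN = 4, TN = 1992, FP = 8))
#' @export
diagnostic_metrics <- function(counts) {
  tp <- as.numeric(counts$TP)
  fn <- as.numeric(counts$FN)
  tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP)
  stopifnot(length(tp) == 1, all(c(tp, fn, tn, fp) >= 0))
  ratio <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined: zero denominator"))
      return(NA_real_)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  acc <- ratio(tp + tn, tp + fn + tn + fp, "accuracy")
  ppv <- ratio(tp, tp + fp, "PPV")
  npv <- ratio(tn, tn + fn, "NPV")
  tibble(sensitivity = sens, specificity = spec, accuracy = acc,
         ppv = ppv, npv = npv, eval_index = sqrt(ppv * npv))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the closed-form Mann-Whitney rank
#' statistic with midranks for tied scores: the probability that a random
#' case scores above a random control, counting ties as one half. Exact
#' under ties and invariant to any strictly increasing transform of the
#' scores.
#'
#' @param scores A tibble with columns `sample_id`, `score` (e.g. from
#'   [classify_matrix()]), or a named numeric vector of scores.
#' @param truth A tibble with columns `sample_id`, `label`; both classes
#'   must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, truth) {
  if (is.data.frame(scores)) {
    s <- setNames(scores$score, scores$sample_id)
  } else {
    s <- scores
  }
  stopifnot(!is.null(names(s)))
  lab <- truth$label[match(names(s), truth$sample_id)]
  if (anyNA(lab)) abort("every scored sample needs a truth label")
  n_case <- sum(lab == "case")
  n_ctrl <- sum(lab == "control")
  if (n_case == 0 || n_ctrl == 0) {
    abort("AUC needs at least one case and one control")
  }
  r <- rank(s)  # midranks for ties
  (sum(r[lab == "case"]) - n_case * (n_case + 1) / 2) / (n_case * n_ctrl)
}

#' Evaluate predictions end to end
#'
#' Convenience wrapper: confusion counts, diagnostic metrics, and (when a
#' `score` column is present) the rank AUC, in one row.
#'
#' @param predictions Tibble with `sample_id`, `label`, optionally `score`.
#' @param truth Tibble with `sample_id`, `label`.
#' @return One-row tibble of all metrics plus the confusion counts.
#' @export
evaluate_predictions <- function(predictions, truth) {
  cc <- confusion(predictions, truth)
  met <- diagnostic_metrics(cc)
  if ("score" %in% names(predictions)) {
    met$auc <- auc_score(predictions, truth)
  }
  dplyr::bind_cols(met, cc)
}
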