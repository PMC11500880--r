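#' Multiclass confusion matrix
#'
#' Tallies `counts[t, p]`, the number of samples with true class `t`
#' predicted as class `p` (rows = true class, columns = predicted class).
#'
#' @param pred_labels Integer 0-based predicted class indices.
#' @param truth Integer 0-based true class indices, same length.
#' @param n_classes Number of classes `K`.
#' @param class_names Optional class identifiers for the dimnames.
#' @return A `K x K` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred_labels, truth, n_classes,
                             class_names = NULL) {
  if (length(truth) == 0L) stop("empty input")
  truth <- validate_labels(truth, n_classes)
  pred_labels <- validate_labels(pred_labels, n_classes, n_samples = length(truth))
  if (is.null(class_names)) class_names <- paste0("C", seq_len(n_classes) - 1L)
  if (length(class_names) != n_classes) stop("class_names length must equal n_classes")
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = class_names, predicted = class_names))
  for (j in seq_along(truth)) {
    cm[truth[j] + 1L, pred_labels[j] + 1L] <- cm[truth[j] + 1L, pred_labels[j] + 1L] + 1L
  }
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Computes the one-vs-rest TP/FP/TN/FN decomposition per class and from
#' it accuracy, precision, recall (sensitivity), F1 and specificity.
#' Precision, recall and F1 are aggregated by support-weighted averaging —
#' the aggregation under which overall recall equals overall accuracy
#' exactly. Specificity is aggregated by unweighted (macro) averaging,
#' since a support-weighted specificity would be dominated by the majority
#' class. Per-class values with a zero denominator are set to 0 with a
#' warning.
#'
#' @param cm A `confusion_matrix` (or any square count matrix).
#' @return A `metrics_report`: list with `accuracy`, `precision`,
#'   `recall`, `f1`, `specificity` (fractions in \eqn{[0, 1]}),
#'   `per_class` (data frame with support and the per-class metrics), and
#'   `averaging` tags. The print method shows percentages rounded
#'   half-even to 2 decimals.
#' @export
classification_report <- function(cm) {
  cm <- unclass(cm)
  if (!is.matrix(cm) || nrow(cm) != ncol(cm)) stop("cm must be a square count matrix")
  if (any(cm < 0)) stop("cm must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("cm is empty")
  k <- nrow(cm)
  cls <- rownames(cm)
  if (is.null(cls)) cls <- paste0("C", seq_len(k) - 1L)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  support <- rowSums(cm)
  safe_div <- function(num, den, what) {
    zero <- den == 0
    if (any(zero)) {
      warning(sprintf("%s undefined (zero denominator) for class(es) %s; reported as 0",
                      what, paste(cls[zero], collapse = ", ")), call. = FALSE)
    }
    ifelse(zero, 0, num / den)
  }
  precision_c <- safe_div(tp, tp + fp, "precision")
  recall_c <- safe_div(tp, tp + fn, "recall")
  f1_den <- precision_c + recall_c
  f1_c <- ifelse(f1_den == 0, 0, 2 * precision_c * recall_c / f1_den)
  specificity_c <- safe_div(tn, tn + fp, "specificity")
  wts <- support / total
  structure(
    list(
      accuracy = sum(tp) / total,
      precision = sum(wts * precision_c),
      recall = sum(wts * recall_c),
      f1 = sum(wts * f1_c),
      specificity = mean(specificity_c),
      per_class = data.frame(
        class = cls, support = as.integer(support),
        tp = as.integer(tp), fp = as.integer(fp),
        fn = as.integer(fn), tn = as.integer(tn),
        precision = precision_c, recall = recall_c, f1 = f1_c,
        specificity = specificity_c, row.names = NULL),
      averaging = c(precision = "weighted", recall = "weighted",
                    f1 = "weighted", specificity = "macro")),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) formatC(round(100 * v, 2), format = "f", digits = 2)
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy    %s%%\n", pct(x$accuracy)))
  cat(sprintf("  precision   %s%% (weighted)\n", pct(x$precision)))
  cat(sprintf("  recall      %s%% (weighted)\n", pct(x$recall)))
  cat(sprintf("  f1          %s%% (weighted)\n", pct(x$f1)))
  cat(sprintf("  specificity %s%% (macro)\n", pct(x$specificity)))
  if (!is.null(x$roc_auc_macro)) {
    cat(sprintf("  roc-auc     %.4f (macro)\n", x$roc_auc_macro))
  }
  invisible(x)
}

# Trapezoidal AUC of the one-vs-rest ROC curve for one score column.
# Equal scores are grouped so ties contribute half credit, matching the
# pairwise P(score_pos > score_neg) + 0.5 P(equal) definition.
auc_trapezoid <- function(scores, positive) {
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- positive[ord]
  # cumulative TP/FP at each distinct threshold (descending)
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(!y)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

#' One-vs-rest ROC-AUC per class
#'
#' For each class, the area under the ROC curve of that class's
#' probability column against the binary indicator `truth == class`,
#' computed by the threshold/trapezoid construction (ties grouped, so the
#' result equals the pairwise positive-over-negative ranking probability
#' with ties counted half). Classes with no positive or no negative
#' samples have undefined AUC and are returned as `NA` with a warning;
#' the macro AUC is the unweighted mean over the defined classes.
#'
#' @param preds A `prediction_matrix`.
#' @param truth Integer 0-based true labels aligned with the rows.
#' @return List with `per_class` (named numeric, `NA` where undefined)
#'   and `macro`.
#' @export
roc_auc <- function(preds, truth) {
  preds <- as_prediction_matrix(preds)
  truth <- validate_labels(truth, ncol(preds), n_samples = nrow(preds))
  if (length(unique(truth)) < 2L) {
    stop("truth contains a single class; every one-vs-rest AUC is undefined")
  }
  per <- vapply(seq_len(ncol(preds)), function(kk) {
    auc_trapezoid(unclass(preds)[, kk], truth == (kk - 1L))
  }, numeric(1L))
  names(per) <- colnames(preds)
  if (anyNA(per)) {
    warning(sprintf("AUC undefined for class(es) with no positives or no negatives: %s",
                    paste(names(per)[is.na(per)], collapse = ", ")), call. = FALSE)
  }
  list(per_class = per, macro = mean(per, na.rm = TRUE))
}

#' Full evaluation of a prediction matrix against true labels
#'
#' Convenience wrapper: hard labels via argmax, confusion matrix,
#' [classification_report()], and [roc_auc()] merged into one report.
#'
#' @inheritParams roc_auc
#' @return A `metrics_report` with additional fields `confusion`,
#'   `roc_auc` (per class) and `roc_auc_macro`.
#' @export
evaluate_predictions <- function(preds, truth) {
  preds <- as_prediction_matrix(preds)
  truth <- validate_labels(truth, ncol(preds), n_samples = nrow(preds))
  cm <- confusion_matrix(predicted_labels(preds), truth,
                         n_classes = ncol(preds), class_names = colnames(preds))
  rep <- classification_report(cm)
  auc <- tryCatch(roc_auc(preds, truth), error = function(e) NULL)
  rep$confusion <- cm
  if (!is.null(auc)) {
    rep$roc_auc <- auc$per_class
    rep$roc_auc_macro <- auc$macro
  }
  rep
}
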