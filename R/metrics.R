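# Classification metrics: confusion-matrix arithmetic, support-weighted
# aggregates, midrank AUC. Pure arithmetic; zero denominators yield NA
# ("undefined"), never 0.

#' Build a confusion matrix from labels and predictions
#'
#' @param truth,pred binary 0/1 vectors.
#' @return list with counts tn, fp, fn, tp (class `gdm_confusion`).
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  structure(list(
    tn = sum(truth == 0 & pred == 0), fp = sum(truth == 0 & pred == 1),
    fn = sum(truth == 1 & pred == 0), tp = sum(truth == 1 & pred == 1)
  ), class = "gdm_confusion")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Derived metrics from a 2x2 confusion matrix
#'
#' Computes accuracy, sensitivity (recall of the positive class),
#' specificity, PPV, NPV, per-class precision/recall/F1 with supports, and
#' support-weighted aggregates. For binary labels the support-weighted
#' recall is algebraically identical to accuracy; this identity is asserted
#' on every call.
#'
#' @param cm a `gdm_confusion` (or list with tn, fp, fn, tp).
#' @return named list of metrics; `per_class` holds the class-wise table.
#' @export
confusion_metrics <- function(cm) {
  tn <- cm$tn; fp <- cm$fp; fn <- cm$fn; tp <- cm$tp
  n <- tn + fp + fn + tp
  stopifnot(n > 0, tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  support_neg <- tn + fp
  support_pos <- tp + fn
  prec_neg <- safe_div(tn, tn + fn)   # NPV
  prec_pos <- safe_div(tp, tp + fp)   # PPV
  rec_neg <- safe_div(tn, support_neg)  # specificity
  rec_pos <- safe_div(tp, support_pos)  # sensitivity
  f1 <- function(p, r) {
    if (is.na(p) || is.na(r) || p + r == 0) return(NA_real_)
    2 * p * r / (p + r)
  }
  f1_neg <- f1(prec_neg, rec_neg)
  f1_pos <- f1(prec_pos, rec_pos)
  wavg <- function(a, b) {
    if (is.na(a) || is.na(b)) return(NA_real_)
    (support_neg * a + support_pos * b) / n
  }
  out <- list(
    accuracy = (tp + tn) / n,
    sensitivity = rec_pos, specificity = rec_neg,
    ppv = prec_pos, npv = prec_neg,
    per_class = data.frame(
      class = c(0, 1),
      precision = c(prec_neg, prec_pos),
      recall = c(rec_neg, rec_pos),
      f1 = c(f1_neg, f1_pos),
      support = c(support_neg, support_pos)
    ),
    weighted_precision = wavg(prec_neg, prec_pos),
    weighted_recall = wavg(rec_neg, rec_pos),
    weighted_f1 = wavg(f1_neg, f1_pos),
    confusion = cm
  )
  # binary support-weighted recall == accuracy, exactly
  if (!is.na(out$weighted_recall)) {
    stopifnot(abs(out$weighted_recall - out$accuracy) < 1e-12)
  }
  out
}

#' AUC-ROC by the midrank (Mann-Whitney) method
#'
#' Probability that a random positive outranks a random negative; tied
#' scores are handled by midranks, so a constant scorer yields exactly 0.5.
#'
#' @param truth binary 0/1 labels.
#' @param score positive-class scores.
#' @return AUC in `[0, 1]`; error if only one class is present.
#' @export
auc_roc <- function(truth, score) {
  n_pos <- sum(truth == 1)
  n_neg <- sum(truth == 0)
  if (n_pos == 0 || n_neg == 0) stop("AUC undefined: single-class labels")
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a fitted model on a held-out test partition
#'
#' Class predictions are taken at probability threshold 0.5; returns the
#' full metric row (class `gdm_metrics_row`).
#'
#' @param model a fitted `gdm_model` (see [fit_model()]).
#' @param test_x,test_y held-out features and labels, untouched by fitting.
#' @return list with model name, probabilities, and all metrics.
#' @export
evaluate <- function(model, test_x, test_y) {
  prob <- predict_prob(model, test_x)
  pred <- as.integer(prob >= 0.5)
  m <- confusion_metrics(confusion_matrix(test_y, pred))
  m$auc_roc <- auc_roc(test_y, prob)
  m$model <- model$name
  m$prob <- prob
  class(m) <- "gdm_metrics_row"
  m
}

#' Rank evaluated models into a leaderboard
#'
#' Descending by weighted F1; ties broken by AUC-ROC (descending), then by
#' model name. Stable under row permutation.
#'
#' @param rows list of `gdm_metrics_row` objects.
#' @return data.frame leaderboard (model, accuracy, weighted precision/
#'   recall/F1, AUC-ROC).
#' @export
rank_models <- function(rows) {
  stopifnot(length(rows) >= 1)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(model = r$model, accuracy = r$accuracy,
               precision = r$weighted_precision, recall = r$weighted_recall,
               f1 = r$weighted_f1, auc_roc = r$auc_roc,
               stringsAsFactors = FALSE)
  }))
  df <- df[order(-df$f1, -df$auc_roc, df$model), , drop = FALSE]
  rownames(df) <- NULL
  df
}
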