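# Diagnostic performance metrics: accuracy, multiclass AUROC (pROC),
# macro precision and class-frequency-weighted F1.

#' Evaluate subtype predictions
#'
#' @param truth Factor of true subtypes.
#' @param predictions A [predict_subtypes()] tibble (or any data frame with
#'   a `.pred` column and `.prob_<class>` columns).
#' @return One-row tibble with `accuracy`, `auroc`, `precision` (macro) and
#'   `f1_weighted`.
#' @export
evaluate_metrics <- function(truth, predictions) {
  truth <- factor(truth)
  pred <- factor(predictions$.pred, levels = levels(truth))
  prob_cols <- grep("^\\.prob_", names(predictions), value = TRUE)
  prob <- as.matrix(predictions[, prob_cols])
  colnames(prob) <- sub("^\\.prob_", "", prob_cols)
  acc <- mean(pred == truth)
  auroc <- tryCatch({
    as.numeric(pROC::multiclass.roc(truth, prob[, levels(truth),
                                                drop = FALSE],
                                    quiet = TRUE)$auc)
  }, error = function(e) NA_real_)
  per_class <- lapply(levels(truth), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, f1 = f1, n = sum(truth == cl))
  })
  prec_macro <- mean(vapply(per_class, `[[`, numeric(1), "precision"))
  wts <- vapply(per_class, `[[`, numeric(1), "n")
  f1_w <- sum(vapply(per_class, `[[`, numeric(1), "f1") * wts) / sum(wts)
  tibble::tibble(accuracy = acc, auroc = auroc, precision = prec_macro,
                 f1_weighted = f1_w)
}
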