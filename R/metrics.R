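#' Classification metrics per scope
#'
#' Accuracy, F1, recall and precision on the positive (stress) class and AUC
#' from the positive-class probability, computed overall and on each group's
#' subset of the supplied rows. A scope containing a single observed class
#' gets `NA` AUC (flagged undefined).
#'
#' @param probabilities numeric vector, P(stress).
#' @param predictions predicted labels (`"stress"` / `"relaxation"`).
#' @param labels true labels.
#' @param groups group membership per row; `NULL` for overall only.
#' @return data.frame with columns `scope`, `accuracy`, `f1`, `recall`,
#'   `precision`, `auc`.
#' @export
evaluate <- function(probabilities, predictions, labels, groups = NULL) {
  stopifnot(length(probabilities) == length(labels),
            length(predictions) == length(labels))
  one_scope <- function(idx, scope) {
    y <- labels[idx] == "stress"
    yhat <- predictions[idx] == "stress"
    tp <- sum(y & yhat); fp <- sum(!y & yhat)
    fn <- sum(y & !yhat); tn <- sum(!y & !yhat)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else {
      NA_real_
    }
    auc <- if (length(unique(y)) == 2L) {
      as.numeric(pROC::auc(pROC::roc(response = y,
                                     predictor = probabilities[idx],
                                     levels = c(FALSE, TRUE), direction = "<",
                                     quiet = TRUE)))
    } else {
      NA_real_
    }
    data.frame(scope = scope, accuracy = (tp + tn) / length(idx), f1 = f1,
               recall = recall, precision = precision, auc = auc,
               stringsAsFactors = FALSE)
  }
  out <- one_scope(seq_along(labels), "overall")
  if (!is.null(groups)) {
    for (g in intersect(GROUPS, unique(groups))) {
      out <- rbind(out, one_scope(which(groups == g), g))
    }
  }
  rownames(out) <- NULL
  out
}
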