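#' Rank-based AUROC
#'
#' Area under the receiver operating characteristic curve via the
#' Mann-Whitney rank-sum formulation with midranks for ties: the fraction of
#' (positive, negative) pairs whose scores are correctly ordered, counting
#' ties as one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Binary labels (1 = positive).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) {
    stop("AUROC undefined: test set contains a single class", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Threshold metrics from scores
#'
#' Computes the confusion matrix at a probability threshold and derives
#' balanced accuracy, Matthews correlation coefficient and F1, together with
#' the threshold-free AUROC. MCC is defined as 0 when any denominator factor
#' vanishes (degenerate all-one-class predictions).
#'
#' @inheritParams auroc
#' @param threshold Decision threshold (default 0.5; predicted positive when
#'   `score >= threshold`).
#' @return A one-row `amyl_eval` tibble: `auroc`, `balanced_accuracy`,
#'   `mcc`, `f1`, `threshold`, `tp`, `fp`, `fn`, `tn`.
#' @examples
#' eval_scores(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 0, 0))
#' @export
eval_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)

  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ba <- (sens + spec) / 2
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)

  out <- tibble::tibble(auroc = auroc(scores, labels),
                        balanced_accuracy = ba, mcc = mcc, f1 = f1,
                        threshold = threshold,
                        tp = tp, fp = fp, fn = fn, tn = tn)
  class(out) <- c("amyl_eval", class(out))
  out
}

#' Evaluate a trained model on a labeled test set
#'
#' @param model An `amyl_model` or `amyl_fit`.
#' @param test_data Labeled record tibble or `amyl_batch` with both classes
#'   present.
#' @param threshold Decision threshold (default 0.5).
#' @return A one-row `amyl_eval` tibble (see [eval_scores()]).
#' @export
evaluate <- function(model, test_data, threshold = 0.5) {
  preds <- predict_proba(model, test_data)
  if (anyNA(preds$label)) stop("test data must be labeled", call. = FALSE)
  eval_scores(preds$prob, preds$label, threshold = threshold)
}
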