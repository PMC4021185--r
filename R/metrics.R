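#' Confusion counts from labels and predictions
#'
#' @param truth,prediction logical vectors (TRUE = interacting).
#' @return one-row tibble: tp, tn, fp, fn.
#' @export
confusion_counts <- function(truth, prediction) {
  stopifnot(length(truth) == length(prediction))
  tibble::tibble(
    tp = sum(truth & prediction),
    tn = sum(!truth & !prediction),
    fp = sum(!truth & prediction),
    fn = sum(truth & !prediction)
  )
}

#' Classification metrics from confusion counts
#'
#' True positive rate (sensitivity/recall), true negative rate
#' (specificity), precision, Matthews correlation coefficient and F
#' measure:
#' \deqn{TPr = TP/(TP+FN),\quad TNr = TN/(TN+FP),\quad PRC = TP/(TP+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}
#' \deqn{F1 = 2 \cdot PRC \cdot TPr / (PRC + TPr)}
#' Degenerate denominators yield 0 with `degenerate = TRUE` (common for
#' per-protein scores of small proteins).
#'
#' @param counts one-row tibble/list with tp, tn, fp, fn, or the `tp` value
#'   with `tn`, `fp`, `fn` given separately.
#' @param tn,fp,fn counts when `counts` is given as a scalar tp.
#' @return one-row tibble: tpr, tnr, prc, mcc, f1, degenerate.
#' @examples
#' classification_stats(tp = 3, fp = 1, fn = 2, tn = 4) # MCC = 10/sqrt(600)
#' @export
classification_stats <- function(counts = NULL, tp = counts$tp, tn = counts$tn,
                                 fp = counts$fp, fn = counts$fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, tp + tn + fp + fn >= 1)
  degenerate <- FALSE
  rate <- function(num, den) {
    if (den == 0) {
      degenerate <<- TRUE
      0
    } else num / den
  }
  tpr <- rate(tp, tp + fn)
  tnr <- rate(tn, tn + fp)
  prc <- rate(tp, tp + fp)
  mcc_den <- prod(sqrt(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) {
    degenerate <- TRUE
    0
  } else (tp * tn - fp * fn) / mcc_den
  f1 <- rate(2 * prc * tpr, prc + tpr)
  tibble::tibble(tpr = tpr, tnr = tnr, prc = prc, mcc = mcc, f1 = f1,
                 degenerate = degenerate)
}

#' @rdname classification_stats
#' @param truth,prediction logical vectors; convenience wrapper.
#' @export
classification_stats_from_predictions <- function(truth, prediction) {
  classification_stats(confusion_counts(truth, prediction))
}
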