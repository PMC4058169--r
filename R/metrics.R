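#' Confusion-matrix counts
#'
#' Tallies true/false positives and negatives for \{+1, -1\} label vectors.
#' Which class counts as positive is configurable; the clinical convention
#' here defaults to the disease class, which the 1/2-encoded tables map to
#' `-1` ("malignant" / disease present) under the default label map.
#'
#' @param y_true,y_pred numeric vectors in \{+1, -1\}, equal length.
#' @param positive_label the class treated as positive (default `-1`).
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `fn`, `tn`, `positive_label`.
#' @export
confusion <- function(y_true, y_pred, positive_label = -1) {
  if (length(y_true) != length(y_pred)) {
    stop("length mismatch: ", length(y_true), " vs ", length(y_pred))
  }
  stopifnot(all(y_true %in% c(-1, 1)), all(y_pred %in% c(-1, 1)))
  pos_t <- y_true == positive_label
  pos_p <- y_pred == positive_label
  structure(
    list(tp = sum(pos_t & pos_p), fp = sum(!pos_t & pos_p),
         fn = sum(pos_t & !pos_p), tn = sum(!pos_t & !pos_p),
         positive_label = positive_label),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion (positive =", x$positive_label, "): tp", x$tp, "fp", x$fp,
      "fn", x$fn, "tn", x$tn, "\n")
  invisible(x)
}

#' Precision, recall and F-measure (percent)
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `F = 2 P R / (P + R)` (harmonic mean), all reported as percentages.
#' A zero denominator yields 0 with a warning -- the conventional degenerate
#' handling when no positives are predicted or present.
#'
#' @param counts a [confusion()] result.
#' @return named numeric vector `c(precision, recall, f_measure)` in percent.
#' @export
precision_recall_f <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); returning 0")
      return(0)
    }
    num / den
  }
  p <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  r <- safe_ratio(counts$tp, counts$tp + counts$fn, "recall")
  f <- if (p + r == 0) {
    warning("F-measure undefined (precision + recall = 0); returning 0")
    0
  } else 2 * p * r / (p + r)
  c(precision = 100 * p, recall = 100 * r, f_measure = 100 * f)
}

#' Classification accuracy (percent)
#'
#' `(tp + tn) / n * 100` over all evaluated samples.
#'
#' @param counts a [confusion()] result.
#' @return accuracy in percent.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  n <- counts$tp + counts$fp + counts$fn + counts$tn
  if (n == 0) stop("cannot compute accuracy of an empty evaluation")
  100 * (counts$tp + counts$tn) / n
}

#' Write a model-comparison metrics table
#'
#' Emits a delimited table with one row per algorithm and the five report
#' columns (train/test accuracy, precision, recall, F-measure), percentages
#' formatted to a fixed number of decimals.
#'
#' @param report data.frame as produced by [compare_models()].
#' @param path output file.
#' @param sep field separator.
#' @param digits decimals for the percentage columns.
#' @export
write_metrics_report <- function(report, path, sep = "\t", digits = 4) {
  out <- report
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, format = "f", digits = digits))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
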