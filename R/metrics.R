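# Confusion-matrix evaluation: per-class precision / recall / F1 (one-vs-rest
# percentages) and overall accuracy (trace/total, the binary
# (TP+TN)/(TP+FP+TN+FN) formula generalized to k classes).

#' Build a confusion matrix
#'
#' @param y_true,y_pred equal-length label vectors; every label must belong
#'   to the class set.
#' @param classes optional class ordering; defaults to the sorted union of
#'   observed labels.
#' @return object of class `confusion_matrix`: integer `counts` (rows = true
#'   class, columns = predicted) and `classes`.
#' @export
confusion_matrix <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have equal length")
  if (length(y_true) == 0) stop("empty label vectors")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown) > 0)
    stop("labels outside the class set: ", paste(unknown, collapse = ", "))
  counts <- table(factor(y_true, levels = classes),
                  factor(y_pred, levels = classes))
  structure(list(counts = unclass(counts), classes = classes),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> rows = truth, cols = prediction\n")
  print(x$counts)
  invisible(x)
}

ovr_counts <- function(cm, class_id) {
  i <- if (is.character(class_id)) match(class_id, cm$classes) else class_id
  if (is.na(i) || i < 1 || i > length(cm$classes)) stop("unknown class")
  m <- cm$counts
  tp <- m[i, i]
  fp <- sum(m[-i, i])
  fn <- sum(m[i, -i])
  tn <- sum(m) - tp - fp - fn
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' F1 score from percentage-scale precision and recall
#'
#' `F1 = 2 * precision * recall / (precision + recall)`, taking and returning
#' percentages (mathematically identical to the fraction-scale harmonic
#' mean).
#'
#' @param precision,recall percentages in \[0, 100\].
#' @return F1 in percent (`NaN` when both inputs are zero or undefined).
#' @export
f1_score <- function(precision, recall) {
  ifelse(is.nan(precision) | is.nan(recall) | precision + recall == 0,
         NaN, 2 * precision * recall / (precision + recall))
}

#' Per-class precision, recall and F1 score (percent)
#'
#' One-vs-rest: precision = TP/(TP+FP) x 100, recall = TP/(TP+FN) x 100 and
#' F1 = 2 x precision x recall / (precision + recall), computed on the
#' percentage scale. Undefined metrics (empty denominators) are returned as
#' `NaN` with a warning. Values are full precision; rounding to two decimals
#' happens only at report/printing time.
#'
#' @param cm a [confusion_matrix()].
#' @param class_id class name or index.
#' @return named numeric vector `c(precision, recall, f1)` in percent.
#' @export
precision_recall_f1 <- function(cm, class_id) {
  stopifnot(inherits(cm, "confusion_matrix"))
  k <- ovr_counts(cm, class_id)
  prec <- if (k["tp"] + k["fp"] == 0) {
    warning("precision undefined: no predictions for this class"); NaN
  } else 100 * k[["tp"]] / (k[["tp"]] + k[["fp"]])
  rec <- if (k["tp"] + k["fn"] == 0) {
    warning("recall undefined: class absent from the truth"); NaN
  } else 100 * k[["tp"]] / (k[["tp"]] + k[["fn"]])
  c(precision = prec, recall = rec, f1 = f1_score(prec, rec))
}

#' Overall accuracy (percent)
#'
#' `100 x trace/total`; for two classes this is exactly
#' (TP+TN)/(TP+FP+TN+FN) x 100, and for k classes it equals micro-averaged
#' recall.
#'
#' @param cm a [confusion_matrix()].
#' @return accuracy in percent.
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- sum(cm$counts)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm$counts)) / tot
}

#' Full evaluation report
#'
#' Per-class precision/recall/F1 plus overall accuracy, regenerated purely
#' from the confusion matrix (so a stored matrix always reproduces the same
#' report).
#'
#' @param cm a [confusion_matrix()].
#' @return object of class `metrics_report`: `per_class` data.frame
#'   (`class`, `precision`, `recall`, `f1`), `accuracy`, `confusion`.
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  per <- do.call(rbind, lapply(cm$classes, function(cl) {
    v <- precision_recall_f1(cm, cl)
    data.frame(class = cl, precision = v[["precision"]],
               recall = v[["recall"]], f1 = v[["f1"]])
  }))
  structure(list(per_class = per, accuracy = accuracy(cm), confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  per <- x$per_class
  per$precision <- round_half_up(per$precision, 2)
  per$recall <- round_half_up(per$recall, 2)
  per$f1 <- round_half_up(per$f1, 2)
  cat("<metrics_report>\n")
  print(per, row.names = FALSE)
  cat(sprintf("overall accuracy: %.2f%%\n", round_half_up(x$accuracy, 2)))
  invisible(x)
}

#' Write a report as CSV and JSON
#'
#' The CSV mirrors the per-class table (precision / recall / F1 columns in
#' percent, two decimals, half-up) with the overall accuracy repeated per
#' row; the JSON keeps full precision plus the confusion counts.
#'
#' @param report a [metrics_report()].
#' @param prefix path prefix; writes `<prefix>.csv` and `<prefix>.json`.
#' @return `prefix` invisibly.
#' @export
write_metrics_report <- function(report, prefix) {
  stopifnot(inherits(report, "metrics_report"))
  per <- report$per_class
  out <- data.frame(class = per$class,
                    precision = round_half_up(per$precision, 2),
                    recall = round_half_up(per$recall, 2),
                    f1 = round_half_up(per$f1, 2),
                    accuracy = round_half_up(report$accuracy, 2))
  utils::write.csv(out, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(per_class = report$per_class, accuracy = report$accuracy,
         confusion = list(classes = report$confusion$classes,
                          counts = report$confusion$counts)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
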