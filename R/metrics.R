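#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes:
#' `counts[i, j] = #\{t : labels_t = i, preds_t = j\}`.
#'
#' @param preds,labels Equal-length, non-empty integer class id vectors
#'   (0-based).
#' @param n_classes Number of classes; default `max(id) + 1`.
#' @param class_labels Optional class names for the dimnames.
#' @return A C x C integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(preds, labels, n_classes = NULL,
                             class_labels = NULL) {
  if (length(preds) != length(labels)) stop("preds and labels lengths differ")
  if (length(preds) == 0L) stop("empty input")
  preds <- as.integer(preds); labels <- as.integer(labels)
  if (is.null(n_classes)) n_classes <- max(preds, labels) + 1L
  if (is.null(class_labels)) class_labels <- as.character(0:(n_classes - 1L))
  lv <- 0:(n_classes - 1L)
  cm <- table(factor(labels, levels = lv), factor(preds, levels = lv))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = class_labels, predicted = class_labels))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Support-weighted multiclass metrics
#'
#' Per-class precision, recall and F1 with the `0/0 -> 0` convention, and
#' their support-weighted averages `sum_c (n_c / N) * metric_c` — the
#' appropriate summary under class imbalance. For single-label multiclass
#' data the weighted recall equals the accuracy identically.
#'
#' @param cm A [confusion_matrix()] (or any C x C count matrix with rows =
#'   true class).
#' @return An object of class `metrics_report`: `per_class` data frame
#'   (class, support, precision, recall, f1), `weighted` list (precision,
#'   recall, f1) and `accuracy`.
#' @export
weighted_metrics <- function(cm) {
  cm <- unclass(cm)
  n <- sum(cm)
  if (n <= 0) stop("confusion matrix is empty")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  precision <- safe_div(tp, predicted)
  recall <- safe_div(tp, support)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  wts <- support / n
  labs <- rownames(cm)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(cm)) - 1L)
  structure(list(
    per_class = data.frame(class = labs, support = as.integer(support),
                           precision = unname(precision),
                           recall = unname(recall), f1 = unname(f1),
                           stringsAsFactors = FALSE),
    weighted = list(precision = sum(wts * precision),
                    recall = sum(wts * recall),
                    f1 = sum(wts * f1)),
    accuracy = sum(tp) / n,
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat("Weighted metrics:\n")
  cat(sprintf("  precision %.4g  recall %.4g  F1 %.4g  accuracy %.4g\n",
              x$weighted$precision, x$weighted$recall, x$weighted$f1,
              x$accuracy))
  cat("Per class:\n")
  print(format(x$per_class, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as JSON and/or CSV
#'
#' @param report A [weighted_metrics()] result.
#' @param json_path,csv_path Output files (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "metrics_report"))
  if (!is.null(json_path))
    jsonlite::write_json(
      list(weighted = report$weighted, accuracy = report$accuracy,
           per_class = report$per_class,
           confusion = unclass(report$confusion)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) {
    wide <- data.frame(class = "weighted",
                       support = sum(report$per_class$support),
                       precision = report$weighted$precision,
                       recall = report$weighted$recall,
                       f1 = report$weighted$f1)
    data.table::fwrite(rbind(report$per_class, wide), csv_path)
  }
  invisible(report)
}
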