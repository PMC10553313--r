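#' Confusion matrix
#'
#' `counts[c, k]` is the number of samples with true class `c` predicted
#' as class `k` (0-based labels, 1-based matrix indices).
#'
#' @param true_labels,predicted_labels Integer vectors in `[0, C)`.
#' @param n_classes Number of classes `C`.
#' @return `C x C` integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, n_classes) {
  stopifnot(length(true_labels) == length(predicted_labels))
  if (length(true_labels) &&
      (min(c(true_labels, predicted_labels)) < 0 ||
       max(c(true_labels, predicted_labels)) >= n_classes))
    stop("labels must lie in [0, n_classes)")
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(true_labels))
    cm[true_labels[i] + 1, predicted_labels[i] + 1] <-
      cm[true_labels[i] + 1, predicted_labels[i] + 1] + 1L
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class and macro recall
#'
#' `Rec_c = TP_c / (TP_c + FN_c)` (row-normalised diagonal); the macro
#' recall is the unweighted mean across classes. A class with an empty row
#' contributes `Rec_c = 0` (with a warning).
#'
#' @param cm A confusion matrix (rows = true class).
#' @return List with `per_class` and `macro`.
#' @export
macro_recall <- function(cm) {
  rs <- rowSums(cm)
  if (any(rs == 0))
    warning("class(es) with no true samples: recall set to 0")
  rec <- ifelse(rs > 0, diag(cm) / rs, 0)
  list(per_class = rec, macro = mean(rec))
}

#' Per-class and macro precision
#'
#' `Pre_c = TP_c / (TP_c + FP_c)` (column-normalised diagonal); macro
#' precision is the unweighted mean. An empty column contributes 0 (with a
#' warning).
#'
#' @param cm A confusion matrix.
#' @return List with `per_class` and `macro`.
#' @export
macro_precision <- function(cm) {
  cs <- colSums(cm)
  if (any(cs == 0))
    warning("class(es) never predicted: precision set to 0")
  pre <- ifelse(cs > 0, diag(cm) / cs, 0)
  list(per_class = pre, macro = mean(pre))
}

#' Macro F1
#'
#' Harmonic mean `2 * MPre * MRec / (MPre + MRec)` of macro precision and
#' macro recall; defined as 0 when both are 0.
#'
#' @param mpre,mrec Macro precision and recall in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
mf1 <- function(mpre, mrec) {
  stopifnot(mpre >= 0, mpre <= 1, mrec >= 0, mrec <= 1)
  if (mpre + mrec == 0) return(0)
  2 * mpre * mrec / (mpre + mrec)
}

#' Overall accuracy
#'
#' Trace of the confusion matrix over the number of samples.
#'
#' @param cm A confusion matrix.
#' @return Scalar in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  n <- sum(cm)
  if (n == 0) return(NaN)
  sum(diag(cm)) / n
}

#' Geometric mean of per-class sensitivities
#'
#' `GM = (prod_c S_c)^(1/C)` with sensitivity `S_c = Rec_c`. Any zero
#' sensitivity is replaced by `floor` (default 0.001) so a single silent
#' class does not collapse the score to 0.
#'
#' @param cm A confusion matrix.
#' @param floor Replacement value for zero sensitivities.
#' @return Scalar in `(0, 1]`.
#' @export
geometric_mean <- function(cm, floor = 0.001) {
  s <- suppressWarnings(macro_recall(cm)$per_class)
  s[s == 0] <- floor
  exp(mean(log(s)))
}

#' Full metrics report
#'
#' Computes the confusion matrix and the macro evaluation suite: macro
#' precision (MPre), macro recall (MRec), macro F1 (MF1), accuracy (Acc)
#' and the geometric mean of sensitivities (GM, with the 0.001
#' substitution for zero sensitivities).
#'
#' @param true_labels,predicted_labels 0-based integer vectors.
#' @param n_classes Number of classes.
#' @return A `metrics_report` list with fields `confusion`, `per_class`
#'   (recall, precision, sensitivity), `MPre`, `MRec`, `MF1`, `Acc`,
#'   `GM`.
#' @export
metrics_report <- function(true_labels, predicted_labels, n_classes) {
  cm <- confusion(true_labels, predicted_labels, n_classes)
  rec <- suppressWarnings(macro_recall(cm))
  pre <- suppressWarnings(macro_precision(cm))
  structure(list(confusion = cm,
                 per_class = list(recall = rec$per_class,
                                  precision = pre$per_class,
                                  sensitivity = rec$per_class),
                 MPre = pre$macro, MRec = rec$macro,
                 MF1 = mf1(pre$macro, rec$macro),
                 Acc = accuracy(cm), GM = geometric_mean(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> Acc %.4f  MPre %.4f  MRec %.4f  MF1 %.4f  GM %.4f\n",
    x$Acc, x$MPre, x$MRec, x$MF1, x$GM))
  invisible(x)
}

#' Serialise a metrics report
#'
#' Writes the report as JSON and/or a one-row CSV with columns in the
#' order Acc, MPre, MRec, MF1, GM.
#'
#' @param report A `metrics_report`.
#' @param json_path,csv_path Output paths (`NULL` to skip).
#' @return Invisibly, the one-row data frame.
#' @export
write_metrics <- function(report, json_path = NULL, csv_path = NULL) {
  row <- data.frame(Acc = report$Acc, MPre = report$MPre,
                    MRec = report$MRec, MF1 = report$MF1, GM = report$GM)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(Acc = report$Acc, MPre = report$MPre, MRec = report$MRec,
           MF1 = report$MF1, GM = report$GM,
           per_class = report$per_class,
           confusion = unclass(report$confusion)),
      json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(csv_path)) write.csv(row, csv_path, row.names = FALSE)
  invisible(row)
}
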