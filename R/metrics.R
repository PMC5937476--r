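#' Confusion matrix of EC predictions
#'
#' `C(i, j)` counts samples of true class i predicted as class j.
#'
#' @param y_true,y_pred Equal-length integer vectors with entries in
#'   `1..n_classes`.
#' @param n_classes Number of classes (default 6).
#' @return An `n x n` integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, n_classes = 6L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (!all(y_true %in% seq_len(n_classes)) || !all(y_pred %in% seq_len(n_classes)))
    stop("class labels must be integers in 1..", n_classes)
  cm <- table(factor(y_true, levels = seq_len(n_classes)),
              factor(y_pred, levels = seq_len(n_classes)))
  cm <- matrix(as.integer(cm), n_classes, n_classes,
               dimnames = list(true = paste0("EC", seq_len(n_classes)),
                               predicted = paste0("EC", seq_len(n_classes))))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

check_cm <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || any(cm < 0))
    stop("need a square non-negative confusion matrix")
  if (sum(cm) == 0) stop("empty confusion matrix")
  unclass(cm)
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy` is trace over total.  Per class i, precision is
#' `C(i,i)` over column sum, recall is `C(i,i)` over row sum and F1 is
#' their harmonic mean.  Macro precision/recall are unweighted means over
#' classes, and macro F1 is the harmonic mean of macro precision and
#' macro recall (not the mean of per-class F1; `macro_f1_mode = "mean_f1"`
#' selects the alternative).  A class never predicted (empty column) has
#' undefined precision, reported as 0 and flagged in the
#' `"undefined"` attribute; likewise an empty row for recall.
#'
#' @param cm A [confusion()] matrix.
#' @return `accuracy()`: scalar. `precision_per_class()`,
#'   `recall_per_class()`, `f1_per_class()`: per-class vectors.
#'   `macro_metrics()`: named vector (precision, recall, f1).
#' @name metrics
NULL

#' @rdname metrics
#' @export
accuracy <- function(cm) {
  cm <- check_cm(cm)
  sum(diag(cm)) / sum(cm)
}

#' @rdname metrics
#' @export
precision_per_class <- function(cm) {
  cm <- check_cm(cm)
  col_tot <- colSums(cm)
  out <- ifelse(col_tot > 0, diag(cm) / col_tot, 0)
  names(out) <- colnames(cm)
  attr(out, "undefined") <- col_tot == 0
  out
}

#' @rdname metrics
#' @export
recall_per_class <- function(cm) {
  cm <- check_cm(cm)
  row_tot <- rowSums(cm)
  out <- ifelse(row_tot > 0, diag(cm) / row_tot, 0)
  names(out) <- rownames(cm)
  attr(out, "undefined") <- row_tot == 0
  out
}

#' @rdname metrics
#' @export
f1_per_class <- function(cm) {
  p <- precision_per_class(cm)
  r <- recall_per_class(cm)
  out <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  names(out) <- names(p)
  attr(out, "undefined") <- attr(p, "undefined") | attr(r, "undefined")
  out
}

#' @rdname metrics
#' @param macro_f1_mode `"harmonic"` (harmonic mean of macro precision and
#'   macro recall) or `"mean_f1"` (mean of per-class F1).
#' @export
macro_metrics <- function(cm, macro_f1_mode = c("harmonic", "mean_f1")) {
  macro_f1_mode <- match.arg(macro_f1_mode)
  p <- mean(precision_per_class(cm))
  r <- mean(recall_per_class(cm))
  f1 <- if (macro_f1_mode == "harmonic") {
    if (p + r > 0) 2 * p * r / (p + r) else 0
  } else mean(f1_per_class(cm))
  c(precision = p, recall = r, f1 = f1)
}

#' Full metric report
#'
#' Accuracy plus per-class and macro precision/recall/F1 as one tidy data
#' frame, the shape used for cross-tabulating weighting schemes against
#' decision strategies.
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame with columns `metric`, `class`, `value`.
#' @export
metric_report <- function(cm) {
  n <- nrow(cm)
  cls <- c(paste0("EC", seq_len(n)), "macro")
  mm <- macro_metrics(cm)
  data.frame(
    metric = c("accuracy",
               rep("precision", n + 1L), rep("recall", n + 1L),
               rep("f1", n + 1L)),
    class = c("all", cls, cls, cls),
    value = c(accuracy(cm),
              as.numeric(precision_per_class(cm)), mm[["precision"]],
              as.numeric(recall_per_class(cm)), mm[["recall"]],
              as.numeric(f1_per_class(cm)), mm[["f1"]]),
    stringsAsFactors = FALSE)
}
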