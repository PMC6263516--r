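#' Confusion-matrix evaluation of predicted activity labels
#'
#' Tallies a K x K confusion matrix (rows = true class, columns = predicted
#' class), per-class recall, overall (micro) accuracy — the headline
#' "average recognition accuracy" — and macro-averaged recall.
#'
#' @param true_labels,predicted_labels Equal-length label vectors; every
#'   label must appear in `class_names`.
#' @param class_names Class ordering for the report; defaults to the sorted
#'   union of the observed labels.
#' @return An object of class `eval_report`: list with `confusion`,
#'   `per_class_recall`, `overall_accuracy`, `macro_recall`, `class_names`,
#'   `n`.
#' @export
evaluate <- function(true_labels, predicted_labels, class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (is.null(class_names))
    class_names <- sort(unique(c(true_labels, predicted_labels)))
  unknown <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(unknown))
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  tf <- factor(true_labels, levels = class_names)
  pf <- factor(predicted_labels, levels = class_names)
  confusion <- unclass(table(true = tf, predicted = pf))
  n <- length(true_labels)
  recall <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion,
                 per_class_recall = recall,
                 overall_accuracy = sum(diag(confusion)) / n,
                 macro_recall = mean(recall, na.rm = TRUE),
                 class_names = class_names, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.2f%%  (n = %d)\n",
              100 * x$overall_accuracy, x$n))
  cat(sprintf("Macro recall:     %.2f%%\n", 100 * x$macro_recall))
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(x$confusion)
  cat("Per-class recall (%):\n")
  print(round(100 * x$per_class_recall, 2))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' @param report An [evaluate()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(
    list(overall_accuracy = report$overall_accuracy,
         macro_recall = report$macro_recall,
         n = report$n,
         class_names = report$class_names,
         per_class_recall = as.list(report$per_class_recall),
         confusion = apply(report$confusion, 1L, as.integer, simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Leave-one-subject-out partitions
#'
#' One partition per subject: that subject's windows form the test side and
#' every other subject's windows the training side, so no subject appears on
#' both sides of any fold.
#'
#' @param windows List of [signal_window()] objects (or any list of objects
#'   with a `subject_id` field).
#' @return Named list (one element per subject) of lists with integer index
#'   vectors `train` and `test`.
#' @export
loso_splits <- function(windows) {
  subjects <- vapply(windows, `[[`, "", "subject_id")
  uniq <- sort(unique(subjects))
  if (length(uniq) < 2L)
    stop("leave-one-subject-out requires at least 2 subjects")
  out <- lapply(uniq, function(s)
    list(train = which(subjects != s), test = which(subjects == s)))
  names(out) <- uniq
  out
}
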