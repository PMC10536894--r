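#' One-vs-rest confusion counts for one focus class
#'
#' Treats `focus_class` as positive and every other class as negative:
#' TP = predicted and true both the focus class, FP = predicted focus but
#' true other, TN = predicted other and true other, FN = predicted other
#' but true focus.  The four counts always sum to the number of evaluated
#' samples.
#'
#' @param y_true,y_pred Equal-length label vectors (values from `classes`).
#' @param focus_class The class treated as positive.
#' @param classes The full class set (for validating labels); defaults to
#'   the union of the observed values.
#' @return Named integer vector `c(TP, FP, TN, FN)`.
#' @examples
#' one_vs_rest_counts(c("L","L","R","R"), c("L","R","R","R"), "L")
#' @export
one_vs_rest_counts <- function(y_true, y_pred, focus_class, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stopf("y_true and y_pred have different lengths")
  classes <- classes %||% sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  bad <- setdiff(unique(c(y_true, y_pred, as.character(focus_class))), classes)
  if (length(bad)) stopf("unknown label(s): %s", paste(bad, collapse = ", "))
  pos_t <- y_true == focus_class
  pos_p <- y_pred == focus_class
  c(TP = sum(pos_p & pos_t), FP = sum(pos_p & !pos_t),
    TN = sum(!pos_p & !pos_t), FN = sum(!pos_p & pos_t))
}

prf_from_counts <- function(cnt, warn = TRUE) {
  precision <- if (cnt["TP"] + cnt["FP"] > 0) cnt["TP"] / (cnt["TP"] + cnt["FP"]) else {
    if (warn) warning("no positive predictions; precision set to 0")
    0
  }
  recall <- if (cnt["TP"] + cnt["FN"] > 0) cnt["TP"] / (cnt["TP"] + cnt["FN"]) else {
    if (warn) warning("no positive truths; recall set to 0")
    0
  }
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = unname(precision), recall = unname(recall), f1 = unname(f1))
}

#' Classification report with one-vs-rest per-class metrics
#'
#' Computes overall accuracy and, for every class in turn as the positive
#' one, the one-vs-rest confusion counts and precision/recall/F1.
#' Precision, recall and F1 are defined as 0 (with a warning) when their
#' denominator is 0.
#'
#' @param y_true,y_pred Label vectors over `classes`.
#' @param classes Ordered class set; defaults to the observed values.
#' @param mean_inference_time_s Optional per-sample wall-clock inference
#'   time to carry along (informational only).
#' @return An object of class `"eval_report"`: `accuracy`, `n`, `per_class`
#'   (data.frame of counts and metrics), `confusion` (K x K matrix),
#'   `mean_inference_time_s`.
#' @export
eval_report <- function(y_true, y_pred, classes = NULL,
                        mean_inference_time_s = NA_real_) {
  classes <- classes %||% sort(unique(c(as.character(y_true), as.character(y_pred))))
  y_true <- factor(as.character(y_true), levels = classes)
  y_pred <- factor(as.character(y_pred), levels = classes)
  if (anyNA(y_true) || anyNA(y_pred)) stopf("labels outside the declared class set")
  per <- lapply(classes, function(cl) {
    cnt <- one_vs_rest_counts(y_true, y_pred, cl, classes)
    c(cnt, prf_from_counts(cnt))
  })
  per <- as.data.frame(do.call(rbind, per))
  per <- cbind(class = classes, per, stringsAsFactors = FALSE)
  rownames(per) <- NULL
  structure(list(accuracy = mean(y_true == y_pred),
                 n = length(y_true),
                 per_class = per,
                 confusion = table(true = y_true, predicted = y_pred),
                 mean_inference_time_s = mean_inference_time_s),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples\n", x$n))
  cat(sprintf("  accuracy: %.1f%%\n", 100 * x$accuracy))
  tab <- x$per_class
  tab$precision <- sprintf("%.1f%%", 100 * tab$precision)
  tab$recall <- sprintf("%.1f%%", 100 * tab$recall)
  tab$f1 <- sprintf("%.1f%%", 100 * tab$f1)
  print(tab, row.names = FALSE)
  if (is.finite(x$mean_inference_time_s))
    cat(sprintf("  mean inference time: %.1f ms/sample (hardware-dependent)\n",
                1000 * x$mean_inference_time_s))
  invisible(x)
}

#' Evaluate a fitted model on a test set
#'
#' Predicts class labels (argmax of the softmax, ties to the lowest class
#' index), then builds the [eval_report()]: accuracy plus one-vs-rest
#' precision/recall/F1 per class.  Mean per-sample inference wall time is
#' reported informationally; it is hardware-dependent and never asserted
#' against.
#'
#' @param fit A fitted `eegnet_fusion` (or a `fusion_model`).
#' @param test A `windowed_dataset`, or an array with `labels` supplied.
#' @param labels Integer labels when `test` is a plain array.
#' @return An `eval_report`.
#' @export
evaluate_model <- function(fit, test = NULL, labels = NULL) {
  if (is.null(test) && inherits(fit, "eegnet_fusion")) test <- fit$test
  if (is.null(test)) stopf("no test set: supply one or fit with an internal split")
  x <- if (inherits(test, "windowed_dataset")) test$windows else test
  y <- if (inherits(test, "windowed_dataset")) test$labels else as.integer(labels)
  if (!length(y)) stopf("test set is empty")
  class_names <- if (inherits(fit, "eegnet_fusion")) fit$class_names
                 else test$class_names %||% sprintf("class%d", max(y))
  net <- if (inherits(fit, "eegnet_fusion")) fit$model$net else fit$net
  t0 <- Sys.time()
  probs <- net_forward(net, x, train = FALSE, keep_cache = FALSE)$probs
  dt <- as.numeric(difftime(Sys.time(), t0, units = "secs")) / dim(x)[1]
  pred <- max.col(probs, ties.method = "first")
  eval_report(class_names[y], class_names[pred], classes = class_names,
              mean_inference_time_s = dt)
}
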