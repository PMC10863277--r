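#' Confusion matrix
#'
#' Counts with predicted classes in rows and true classes in columns
#' (`counts[i, j]` = samples predicted as class i whose true class is j).
#'
#' @param true_labels,predicted_labels Equal-length label vectors, all
#'   values in `class_order`.
#' @param class_order Row/column ordering.
#' @return Square integer matrix with dimnames.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_order = ms_class_levels) {
  if (!length(true_labels)) abort("Empty label vectors.")
  if (length(true_labels) != length(predicted_labels)) {
    abort("Label vectors must have equal length.")
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_order)
  if (length(bad)) abort(paste0("Unknown label(s): ", paste(bad, collapse = ", ")))
  t <- table(predicted = factor(predicted_labels, class_order),
             true = factor(true_labels, class_order))
  m <- matrix(as.integer(t), nrow = length(class_order),
              dimnames = list(predicted = class_order, true = class_order))
  m
}

# Round half away from zero (report rendering only; raw values are kept).
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-class precision, recall and F1
#'
#' `precision_i = counts[i,i] / row-sum` (share of class-i predictions that
#' are correct), `recall_i = counts[i,i] / column-sum` (share of true
#' class-i samples recovered), F1 their harmonic mean; a class never
#' predicted or never present scores 0 by convention. Values are returned
#' at full precision; round for display with 2 decimals, half away from
#' zero.
#'
#' @param cm Confusion matrix from [confusion_matrix()].
#' @return Tibble: `class`, `precision`, `recall`, `f1`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  d <- diag(cm)
  rs <- rowSums(cm); cs <- colSums(cm)
  precision <- ifelse(rs > 0, d / rs, 0)
  recall <- ifelse(cs > 0, d / cs, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  tibble(class = rownames(cm), precision = unname(precision),
         recall = unname(recall), f1 = unname(f1))
}

#' Accuracy with exact binomial confidence interval
#'
#' Clopper-Pearson interval via Beta quantiles:
#' `lower = qbeta(a/2, correct, total - correct + 1)` (0 when `correct` is
#' 0) and `upper = qbeta(1 - a/2, correct + 1, total - correct)` (1 when
#' `correct == total`).
#'
#' @param correct Number of correct predictions.
#' @param total Number of predictions (>= 1).
#' @param level Confidence level in (0,1), default 0.95.
#' @return List: `accuracy`, `lower`, `upper`.
#' @export
accuracy_with_ci <- function(correct, total, level = 0.95) {
  if (level <= 0 || level >= 1) abort("level must be in (0,1).")
  stopifnot(total >= 1L, correct >= 0L, correct <= total)
  a <- 1 - level
  lower <- if (correct == 0) 0 else qbeta(a / 2, correct, total - correct + 1)
  upper <- if (correct == total) 1 else qbeta(1 - a / 2, correct + 1, total - correct)
  list(accuracy = correct / total, lower = lower, upper = upper)
}

#' Evaluate predictions
#'
#' Builds the confusion matrix, per-class metrics, and overall accuracy
#' with its exact binomial confidence interval.
#'
#' @param true_labels,predicted_labels Label vectors.
#' @param class_order Class ordering for the report.
#' @param level Confidence level.
#' @return Object of class `"ms_eval"` with elements `confusion`,
#'   `metrics`, `accuracy`, `ci_lower`, `ci_upper`, `n`.
#' @export
evaluate_predictions <- function(true_labels, predicted_labels,
                                 class_order = ms_class_levels,
                                 level = 0.95) {
  cm <- confusion_matrix(true_labels, predicted_labels, class_order)
  ci <- accuracy_with_ci(sum(diag(cm)), sum(cm), level)
  structure(
    list(confusion = cm, metrics = per_class_metrics(cm),
         accuracy = ci$accuracy, ci_lower = ci$lower, ci_upper = ci$upper,
         n = sum(cm), level = level),
    class = "ms_eval"
  )
}

#' @export
print.ms_eval <- function(x, ...) {
  cat("Classification evaluation (", x$n, " samples)\n\n", sep = "")
  m <- x$metrics
  disp <- cbind(x$confusion,
                Precision = sprintf("%.2f", round_half_up(m$precision)),
                Recall = sprintf("%.2f", round_half_up(m$recall)),
                `F1 Score` = sprintf("%.2f", round_half_up(m$f1)))
  print(disp, quote = FALSE)
  cat(sprintf("\nAccuracy %.4f (exact binomial %d%% CI %.3f-%.3f)\n",
              x$accuracy, round(100 * x$level), x$ci_lower, x$ci_upper))
  invisible(x)
}

#' Tidy an evaluation: per-class metrics
#'
#' @param x An `"ms_eval"`.
#' @param ... Ignored.
#' @return The per-class metrics tibble.
#' @method tidy ms_eval
#' @export
tidy.ms_eval <- function(x, ...) x$metrics

#' One-row evaluation summary
#'
#' @param x An `"ms_eval"`.
#' @param ... Ignored.
#' @return Tibble: `accuracy`, `ci_lower`, `ci_upper`, `n`.
#' @method glance ms_eval
#' @export
glance.ms_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, ci_lower = x$ci_lower,
         ci_upper = x$ci_upper, n = x$n)
}

#' Confusion-matrix heatmap
#'
#' @param object An `"ms_eval"`.
#' @param ... Ignored.
#' @return A ggplot tile plot (predicted rows vs true columns).
#' @method autoplot ms_eval
#' @export
autoplot.ms_eval <- function(object, ...) {
  df <- as_tibble(as.table(object$confusion))
  names(df) <- c("predicted", "true", "n")
  df$predicted <- factor(df$predicted, rev(rownames(object$confusion)))
  df$true <- factor(df$true, colnames(object$confusion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$predicted,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "True class", y = "Predicted class", fill = "Count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
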