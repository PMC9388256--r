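# Evaluation: confusion matrix, per-class accuracy/sensitivity/specificity
# and one-vs-rest ROC/AUC over the fixed class order N, S, V, F, Q.

#' Confusion matrix over the AAMI classes
#'
#' @param truth,estimate Equal-length label vectors (characters or factors
#'   over N, S, V, F, Q).
#' @return An `ecg_confusion` object: a 5x5 integer matrix, rows = true
#'   class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, estimate) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) != length(estimate)) {
    abort("truth and estimate must have equal length")
  }
  bad <- setdiff(unique(c(truth, estimate)), aami_classes())
  if (length(bad)) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  cm <- table(factor(truth, levels = aami_classes()),
              factor(estimate, levels = aami_classes()))
  cm <- matrix(as.integer(cm), 5, 5,
               dimnames = list(truth = aami_classes(),
                               estimate = aami_classes()))
  structure(cm, class = c("ecg_confusion", "matrix"))
}

#' @export
print.ecg_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = truth, columns = prediction)\n")
  print(unclass(x))
  invisible(x)
}

.safe_div <- function(a, b) ifelse(b == 0, NA_real_, a / b)

#' Per-class classification metrics
#'
#' One-vs-rest TP/TN/FP/FN per class, with accuracy `(TP+TN)/total`,
#' sensitivity `TP/(TP+FN)`, and two specificity variants:
#' `specificity_printed = TP/(TP+FP)` — the positive-predictive-value
#' expression this evaluation scheme prints as "Spe" — and the standard
#' `specificity_standard = TN/(TN+FP)`. Divisions by zero yield `NA`.
#'
#' @param cm An [confusion_matrix()] result.
#' @return An `ecg_metrics` list: tibble `by_class`, number `overall_accuracy`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "ecg_confusion"))
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  k <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  by_class <- tibble(
    class = factor(aami_classes(), levels = aami_classes()),
    tp = as.integer(tp), fn = as.integer(fn), fp = as.integer(fp),
    tn = as.integer(tn),
    accuracy = (tp + tn) / total,
    sensitivity = .safe_div(tp, tp + fn),
    specificity_printed = .safe_div(tp, tp + fp),
    specificity_standard = .safe_div(tn, tn + fp))
  structure(list(by_class = by_class,
                 overall_accuracy = sum(tp) / total,
                 confusion = cm),
            class = "ecg_metrics")
}

#' @export
print.ecg_metrics <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.4f\n", x$overall_accuracy))
  print(x$by_class)
  invisible(x)
}

#' @export
tidy.ecg_metrics <- function(x, ...) x$by_class

#' @export
glance.ecg_metrics <- function(x, ...) {
  tibble(overall_accuracy = x$overall_accuracy,
         n = sum(x$confusion),
         macro_sensitivity = mean(x$by_class$sensitivity, na.rm = TRUE))
}

#' One-vs-rest ROC curves and AUC
#'
#' For each class, sweeps a threshold over that class's probability column
#' against the binary truth (this class vs the rest) and integrates the ROC
#' curve by the trapezoid rule. A constant probability column gives AUC 0.5
#' with a warning.
#'
#' @param truth Label vector over the AAMI classes.
#' @param prob Probability matrix (n x 5) with columns in class order
#'   N, S, V, F, Q (rows summing to about 1), e.g. the `.prob_*` columns of
#'   [classify_beats()].
#' @return An `ecg_roc` list: tibble `curves` (class, fpr, tpr, threshold)
#'   and tibble `auc` (class, auc).
#' @export
roc_ovr <- function(truth, prob) {
  truth <- as.character(truth)
  prob <- as.matrix(prob)
  stopifnot(nrow(prob) == length(truth), ncol(prob) == 5)
  curves <- list(); aucs <- numeric(5)
  for (ci in seq_along(aami_classes())) {
    cls <- aami_classes()[ci]
    y <- as.integer(truth == cls)
    p <- prob[, ci]
    if (length(unique(p)) == 1) {
      warn(paste0("constant probability column for class ", cls,
                  "; AUC set to 0.5"))
      aucs[ci] <- 0.5
      curves[[ci]] <- tibble(class = cls, fpr = c(0, 1), tpr = c(0, 1),
                             threshold = c(Inf, -Inf))
      next
    }
    ord <- order(p, decreasing = TRUE)
    yo <- y[ord]
    tps <- cumsum(yo); fps <- cumsum(1 - yo)
    # collapse ties so each threshold appears once
    keep <- c(diff(p[ord]) != 0, TRUE)
    tps <- c(0, tps[keep]); fps <- c(0, fps[keep])
    np <- sum(y); nn <- length(y) - np
    tpr <- if (np > 0) tps / np else rep(0, length(tps))
    fpr <- if (nn > 0) fps / nn else rep(0, length(fps))
    aucs[ci] <- if (np == 0 || nn == 0) NA_real_ else
      sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
    curves[[ci]] <- tibble(class = cls, fpr = fpr, tpr = tpr,
                           threshold = c(Inf, p[ord][keep]))
  }
  structure(list(curves = dplyr::bind_rows(curves),
                 auc = tibble(class = factor(aami_classes(),
                                             levels = aami_classes()),
                              auc = aucs)),
            class = "ecg_roc")
}

#' @export
print.ecg_roc <- function(x, ...) {
  print(x$auc)
  invisible(x)
}

#' @export
tidy.ecg_roc <- function(x, ...) x$curves

#' @export
glance.ecg_roc <- function(x, ...) {
  tibble(macro_auc = mean(x$auc$auc, na.rm = TRUE),
         min_auc = min(x$auc$auc, na.rm = TRUE))
}

#' @export
autoplot.ecg_roc <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = "class") +
    ggplot2::theme_minimal()
}

#' Full metrics report from predictions
#'
#' @param predictions Tibble with `truth`, `estimate` (or `.pred_class`) and
#'   optionally `.prob_*` columns (for ROC), e.g. from
#'   [holdout_predictions()].
#' @return An `ecg_metrics` object with an `roc` element when probabilities
#'   are present.
#' @export
metrics_report <- function(predictions) {
  est <- predictions[["estimate"]] %||% predictions[[".pred_class"]]
  rep_ <- classification_metrics(confusion_matrix(predictions$truth, est))
  prob_cols <- paste0(".prob_", aami_classes())
  if (all(prob_cols %in% names(predictions))) {
    rep_$roc <- roc_ovr(predictions$truth,
                        as.matrix(predictions[, prob_cols]))
  }
  rep_
}
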