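# Majority-voting ensemble and the classification report: per-class
# precision, recall, F1 and one-vs-rest ROC-AUC, overall accuracy, macro and
# support-weighted averages, confusion matrix.

#' Bundle per-model predictions into a vote panel
#'
#' @param labels `instances x models` matrix (or data frame) of predicted
#'   class labels.
#' @param probabilities Optional `instances x models x classes` array of
#'   probability vectors (class order = `classes`).
#' @param model_ids Optional model names (default column names or `model<k>`).
#' @param classes Declared class set (default: sorted unique labels).
#' @return Object of class `vote_panel`.
#' @export
vote_panel <- function(labels, probabilities = NULL, model_ids = NULL,
                       classes = NULL) {
  labels <- as.matrix(labels)
  if (nrow(labels) < 1L || ncol(labels) < 1L) abort_invalid("panel must be non-empty")
  storage.mode(labels) <- "character"
  if (is.null(classes)) classes <- sort(unique(as.vector(labels)))
  if (!all(labels %in% classes)) abort_invalid("labels outside the declared class set")
  if (is.null(model_ids)) {
    model_ids <- colnames(labels) %||% paste0("model", seq_len(ncol(labels)))
  }
  if (!is.null(probabilities)) {
    d <- dim(probabilities)
    if (length(d) != 3L || d[1L] != nrow(labels) || d[2L] != ncol(labels) ||
        d[3L] != length(classes)) {
      abort_invalid("probabilities must be instances x models x classes")
    }
    sums <- apply(probabilities, c(1L, 2L), sum)
    if (any(abs(sums - 1) > 1e-5) || any(probabilities < -1e-8)) {
      abort_invalid("probability slices must lie on the simplex")
    }
  }
  structure(list(labels = labels, probabilities = probabilities,
                 model_ids = model_ids, classes = classes),
            class = "vote_panel")
}

#' Majority vote over a panel of classifiers
#'
#' Per instance, the most frequent label among the k member predictions
#' (the statistical mode). Ties are resolved by `tie_policy`:
#' `"highest_mean_prob"` picks, among tied classes, the one with the highest
#' mean predicted probability across members (requires probabilities);
#' `"lowest_index"` picks the tied class earliest in the declared class
#' order. The default `"auto"` uses mean probabilities when present and
#' falls back to the lowest class index otherwise.
#'
#' @param panel A [vote_panel()].
#' @param tie_policy `"auto"`, `"highest_mean_prob"` or `"lowest_index"`.
#' @return Character vector of ensemble labels, one per instance.
#' @export
majority_vote <- function(panel, tie_policy = c("auto", "highest_mean_prob",
                                                "lowest_index")) {
  if (!inherits(panel, "vote_panel")) abort_invalid("panel must be a vote_panel")
  tie_policy <- match.arg(tie_policy)
  if (tie_policy == "highest_mean_prob" && is.null(panel$probabilities)) {
    abort_config("tie_policy = 'highest_mean_prob' requires probabilities")
  }
  if (tie_policy == "auto") {
    tie_policy <- if (is.null(panel$probabilities)) "lowest_index" else "highest_mean_prob"
  }
  classes <- panel$classes
  n <- nrow(panel$labels)
  out <- character(n)
  for (i in seq_len(n)) {
    counts <- tabulate(match(panel$labels[i, ], classes), nbins = length(classes))
    winners <- which(counts == max(counts))
    if (length(winners) == 1L || tie_policy == "lowest_index") {
      out[i] <- classes[winners[1L]]
    } else {
      mean_p <- colMeans(panel$probabilities[i, , winners, drop = FALSE][1, , , drop = TRUE],
                         na.rm = TRUE)
      if (length(winners) == 1L) mean_p <- mean_p[1L]
      out[i] <- classes[winners[which.max(mean_p)]]
    }
  }
  out
}

# One-vs-rest ROC-AUC by explicit trapezoidal integration of the ROC curve
# (TPR against FPR across all score thresholds).
auc_trapezoid <- function(positive, score) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) return(NA_real_)
  o <- order(score, decreasing = TRUE)
  pos <- positive[o]; sc <- score[o]
  tp <- cumsum(pos); fp <- cumsum(!pos)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tied block
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Full classification report
#'
#' Per class, one-vs-rest TP/FP/FN/TN counts yield precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and `F1 = 2 PR / (P + R)`;
#' overall accuracy is the confusion-matrix trace over the instance count.
#' Macro averages are unweighted class means; weighted averages are
#' support-weighted. A class with zero support or zero predicted positives
#' reports 0 for the undefined metric, with a warning. When `scores` are
#' supplied, one-vs-rest ROC-AUC (trapezoidal) is reported per class.
#'
#' @param true_labels,predicted_labels Equal-length label vectors.
#' @param scores Optional `instances x classes` probability matrix (columns
#'   in `classes` order).
#' @param classes Declared class set (default sorted union of labels).
#' @return Object of class `classification_report`: `confusion`, `per_class`
#'   data frame (precision, recall, f1, roc_auc, support), `accuracy`,
#'   `macro`, `weighted`, `n`.
#' @export
classification_report <- function(true_labels, predicted_labels, scores = NULL,
                                  classes = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    abort_invalid("true and predicted label vectors must have equal length")
  }
  if (length(true_labels) == 0L) abort_invalid("label vectors are empty")
  if (is.null(classes)) classes <- sort(unique(c(true_labels, predicted_labels)))
  if (!all(true_labels %in% classes) || !all(predicted_labels %in% classes)) {
    abort_invalid("labels outside the declared class set")
  }
  n <- length(true_labels)
  cm <- table(factor(true_labels, classes), factor(predicted_labels, classes))
  cm <- matrix(as.integer(cm), length(classes), length(classes),
               dimnames = list(true = classes, predicted = classes))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  support <- rowSums(cm)
  safe_div <- function(num, den, metric, cls) {
    out <- ifelse(den > 0, num / den, 0)
    zero <- which(den == 0)
    for (z in zero) {
      warn_metric(sprintf("%s undefined for class %s (zero denominator); reported as 0",
                          metric, cls[z]))
    }
    out
  }
  precision <- safe_div(tp, tp + fp, "precision", classes)
  recall <- safe_div(tp, tp + fn, "recall", classes)
  f1 <- ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
  roc_auc <- rep(NA_real_, length(classes))
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (nrow(scores) != n || ncol(scores) != length(classes)) {
      abort_invalid("scores must be instances x classes")
    }
    for (j in seq_along(classes)) {
      a <- auc_trapezoid(true_labels == classes[j], scores[, j])
      if (is.na(a)) {
        warn_metric(sprintf("ROC-AUC undefined for class %s (single-class labels); reported as 0",
                            classes[j]))
        a <- 0
      }
      roc_auc[j] <- a
    }
  }
  accuracy <- sum(tp) / n
  wmean <- function(x) if (sum(support) > 0) sum(x * support) / sum(support) else 0
  per_class <- data.frame(class = classes, precision = precision,
                          recall = recall, f1 = f1, roc_auc = roc_auc,
                          support = as.integer(support),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(classes = classes, confusion = cm, per_class = per_class,
                 accuracy = accuracy,
                 macro = list(precision = mean(precision), recall = mean(recall),
                              f1 = mean(f1)),
                 weighted = list(precision = wmean(precision),
                                 recall = wmean(recall), f1 = wmean(f1)),
                 n = n),
            class = "classification_report")
}

#' @export
format.classification_report <- function(x, digits = 4, ...) {
  pc <- x$per_class
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  lines <- c(sprintf("%-12s %10s %10s %10s %10s %8s",
                     "class", "precision", "recall", "f1", "roc_auc", "support"))
  for (i in seq_len(nrow(pc))) {
    lines <- c(lines, sprintf("%-12s %10s %10s %10s %10s %8d",
                              pc$class[i], fmt(pc$precision[i]), fmt(pc$recall[i]),
                              fmt(pc$f1[i]),
                              if (is.na(pc$roc_auc[i])) "-" else fmt(pc$roc_auc[i]),
                              pc$support[i]))
  }
  lines <- c(lines,
             sprintf("%-12s %10s  (n = %d)", "accuracy", fmt(x$accuracy), x$n),
             sprintf("%-12s %10s %10s %10s", "macro avg", fmt(x$macro$precision),
                     fmt(x$macro$recall), fmt(x$macro$f1)),
             sprintf("%-12s %10s %10s %10s", "weighted avg", fmt(x$weighted$precision),
                     fmt(x$weighted$recall), fmt(x$weighted$f1)))
  paste(lines, collapse = "\n")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(format(x, ...), "\n")
  invisible(x)
}

report_to_list <- function(report) {
  list(accuracy = report$accuracy, n = report$n,
       per_class = report$per_class,
       macro = report$macro, weighted = report$weighted,
       confusion = list(classes = report$classes,
                        counts = unname(apply(report$confusion, 1L, as.list))))
}

#' Write a classification report as JSON
#'
#' @param report A `classification_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Ensemble prediction over a set of trained models
#'
#' Runs [predict_dataset()] per member, combines the predicted labels by
#' [majority_vote()] and reports against the manifest labels; the ensemble
#' probability used for ROC-AUC is the mean of the member probabilities.
#' Rows any member failed on are dropped from the vote with a warning.
#'
#' @param models List of trained models sharing one class set.
#' @param manifest Dataset manifest with true labels.
#' @param images Optional named list of in-memory images.
#' @param roi_provider ROI provider shared by dual-branch members.
#' @param tie_policy Passed to [majority_vote()].
#' @return List: `predictions` (data frame with per-model and ensemble
#'   labels), `panel` (the [vote_panel()]), `report`
#'   (a [classification_report()]).
#' @export
ensemble_predict <- function(models, manifest, images = NULL,
                             roi_provider = NULL, tie_policy = "auto") {
  if (length(models) < 1L) abort_invalid("need at least one model")
  class_sets <- lapply(models, function(m) m$classes)
  if (length(unique(vapply(class_sets, paste, character(1), collapse = "\r"))) != 1L) {
    abort_config("ensemble members have mismatched class sets")
  }
  classes <- class_sets[[1L]]
  manifest <- as_manifest(manifest)
  n <- nrow(manifest)
  k <- length(models)
  labels <- matrix(NA_character_, n, k)
  probs <- array(NA_real_, dim = c(n, k, length(classes)))
  for (j in seq_len(k)) {
    pd <- predict_dataset(models[[j]], manifest, images = images,
                          roi_provider = roi_provider)
    labels[, j] <- pd$pred_label
    probs[, j, ] <- as.matrix(pd[, paste0("prob_", classes), drop = FALSE])
  }
  ok <- stats::complete.cases(labels)
  if (!all(ok)) {
    warning(sprintf("%d instance(s) dropped from the vote (member prediction errors)",
                    sum(!ok)))
  }
  panel <- vote_panel(labels[ok, , drop = FALSE],
                      probabilities = probs[ok, , , drop = FALSE],
                      classes = classes)
  y_hat <- majority_vote(panel, tie_policy = tie_policy)
  mean_probs <- apply(probs[ok, , , drop = FALSE], c(1L, 3L), mean)
  report <- classification_report(manifest$label[ok], y_hat,
                                  scores = mean_probs, classes = classes)
  predictions <- data.frame(image_id = manifest$image_id[ok],
                            true_label = manifest$label[ok],
                            stringsAsFactors = FALSE)
  for (j in seq_len(k)) predictions[[paste0("model", j)]] <- labels[ok, j]
  predictions$ensemble_label <- y_hat
  list(predictions = predictions, panel = panel, report = report)
}
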