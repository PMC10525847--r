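# Threshold tuning and multi-label evaluation.
#
# Evaluation is one-vs-rest per disease: the disease is the positive
# class and every other condition, including the Normal state, is
# negative. An image is predicted positive when its probability is
# strictly greater than the per-disease cut-off; cut-offs are tuned to
# maximize sensitivity x specificity. Micro-average metrics pool the
# confusion counts across classes.

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a random
#' positive outranks a random negative, with ties counted 0.5.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels, same length; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: labels contain a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Confusion counts at a threshold
#'
#' Predicted positive iff `score > threshold` (strict).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param threshold cut-off in `[0, 1]`.
#' @return object of class `confusion_counts`: list `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  stopifnot(threshold >= 0, threshold <= 1,
            length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- scores > threshold
  structure(list(tp = sum(pred & labels == 1L),
                 tn = sum(!pred & labels == 0L),
                 fp = sum(pred & labels == 0L),
                 fn = sum(!pred & labels == 1L)),
            class = "confusion_counts")
}

.sens <- function(cc) if ((cc$tp + cc$fn) == 0L) NA_real_ else cc$tp / (cc$tp + cc$fn)
.spec <- function(cc) if ((cc$tn + cc$fp) == 0L) NA_real_ else cc$tn / (cc$tn + cc$fp)
.acc <- function(cc) (cc$tp + cc$tn) / (cc$tp + cc$tn + cc$fp + cc$fn)

#' Tune the cut-off threshold
#'
#' Exhaustive search over all cut points where the confusion table can
#' change: midpoints between consecutive sorted unique scores, plus 0 and
#' 1. Returns the candidate maximizing sensitivity x specificity; ties go
#' to the lowest threshold (favouring sensitivity).
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels with both classes present.
#' @return scalar threshold in `[0, 1]`.
#' @export
tune_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("threshold tuning undefined: labels contain a single class")
  }
  u <- sort(unique(scores))
  cands <- unique(sort(c(0, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, 1)))
  cands <- cands[cands >= 0 & cands <= 1]
  prods <- vapply(cands, function(t) {
    cc <- confusion_at(scores, labels, t)
    .sens(cc) * .spec(cc)
  }, numeric(1L))
  cands[which.max(prods)] # which.max -> earliest, i.e. lowest threshold
}

#' Tune thresholds for every disease
#'
#' @param probs `n x 6` probability matrix, columns [disease_names()].
#' @param labels `n x 6` 0/1 matrix.
#' @return named threshold vector (a threshold set).
#' @export
tune_thresholds <- function(probs, labels) {
  stopifnot(ncol(probs) == 6L, ncol(labels) == 6L)
  stats::setNames(vapply(seq_len(6L), function(j) {
    tune_threshold(probs[, j], labels[, j])
  }, numeric(1L)), disease_names())
}

#' Micro-average metrics from pooled counts
#'
#' @param per_class list of `confusion_counts`, one per class.
#' @return list with `micro_accuracy`, `micro_sensitivity`,
#'   `micro_specificity`.
#' @export
micro_average <- function(per_class) {
  stopifnot(length(per_class) >= 1L)
  tp <- sum(vapply(per_class, `[[`, numeric(1L), "tp"))
  tn <- sum(vapply(per_class, `[[`, numeric(1L), "tn"))
  fp <- sum(vapply(per_class, `[[`, numeric(1L), "fp"))
  fn <- sum(vapply(per_class, `[[`, numeric(1L), "fn"))
  if ((tp + fn) == 0 || (tn + fp) == 0 || (tp + tn + fp + fn) == 0) {
    stop("micro-average undefined: zero pooled denominator")
  }
  list(micro_accuracy = (tp + tn) / (tp + tn + fp + fn),
       micro_sensitivity = tp / (tp + fn),
       micro_specificity = tn / (tn + fp))
}

#' Evaluate the derived Normal class
#'
#' An image is truly Normal iff its label vector is all zero, and is
#' predicted Normal iff every disease probability is at or below its
#' threshold. Standard confusion tally on that binary task, with Normal
#' as the positive class.
#'
#' @param probs `n x 6` probability matrix.
#' @param labels `n x 6` 0/1 matrix.
#' @param thresholds named threshold vector from [tune_thresholds()].
#' @return `confusion_counts`.
#' @export
normal_eval <- function(probs, labels, thresholds) {
  stopifnot(nrow(probs) == nrow(labels))
  true_norm <- rowSums(labels) == 0L
  pred_norm <- rowSums(sweep(probs, 2L, thresholds[disease_names()], ">")) == 0L
  structure(list(tp = sum(pred_norm & true_norm),
                 tn = sum(!pred_norm & !true_norm),
                 fp = sum(pred_norm & !true_norm),
                 fn = sum(!pred_norm & true_norm)),
            class = "confusion_counts")
}

#' Repeated-run 95% confidence interval
#'
#' Student-t interval over per-run metric values:
#' `half_width = t(0.975, n - 1) * sd / sqrt(n)`.
#'
#' @param values numeric vector of per-run values (length >= 2).
#' @return list with `mean` and `half_width`.
#' @export
run_ci <- function(values) {
  n <- length(values)
  if (n < 2L) stop("confidence interval needs at least 2 runs")
  list(mean = mean(values),
       half_width = stats::qt(0.975, n - 1L) * stats::sd(values) / sqrt(n))
}

#' Two-sample significance test for per-run AUCs
#'
#' Welch two-sided t-test computed in closed form. When both groups have
#' zero variance the p-value is 1 for equal means and 0 otherwise.
#'
#' @param runs_a,runs_b numeric vectors (length >= 2 each).
#' @return two-sided p-value.
#' @export
significance <- function(runs_a, runs_b) {
  stopifnot(length(runs_a) >= 2L, length(runs_b) >= 2L)
  na <- length(runs_a); nb <- length(runs_b)
  va <- stats::var(runs_a); vb <- stats::var(runs_b)
  se2 <- va / na + vb / nb
  dm <- mean(runs_a) - mean(runs_b)
  if (se2 == 0) return(if (dm == 0) 1 else 0)
  t <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

#' Single-label misclassification matrix
#'
#' Restricted to images carrying exactly one disease label or none
#' (Normal); multi-label images are excluded. Rows are the true class,
#' columns the predicted classes: every disease whose probability exceeds
#' its threshold increments its column; an all-negative prediction
#' increments the Normal column.
#'
#' @param probs `n x 6` probability matrix.
#' @param labels `n x 6` 0/1 matrix.
#' @param thresholds named threshold vector.
#' @return 7 x 7 integer matrix, dimnames
#'   `c(disease_names(), "normal")`.
#' @export
misclassification_matrix <- function(probs, labels, thresholds) {
  cls <- c(disease_names(), "normal")
  m <- matrix(0L, 7L, 7L, dimnames = list(true = cls, predicted = cls))
  thr <- thresholds[disease_names()]
  for (i in seq_len(nrow(labels))) {
    nlab <- sum(labels[i, ])
    if (nlab > 1L) next
    true_cls <- if (nlab == 0L) "normal" else disease_names()[labels[i, ] == 1L]
    pred_pos <- disease_names()[probs[i, ] > thr]
    if (!length(pred_pos)) pred_pos <- "normal"
    for (p in pred_pos) m[true_cls, p] <- m[true_cls, p] + 1L
  }
  m
}

#' Export an ROC curve as CSV
#'
#' One row per candidate cut (the same candidate set as
#' [tune_threshold()]), columns `threshold`, `fpr`, `tpr`, ordered so the
#' curve runs from (0, 0) to (1, 1). The trapezoidal area under the
#' exported curve equals [auc()] up to floating-point error.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 labels with both classes present.
#' @param out_path CSV output path.
#' @return the curve data frame, invisibly.
#' @export
roc_export <- function(scores, labels, out_path) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("ROC undefined: labels contain a single class")
  }
  u <- sort(unique(scores))
  cands <- unique(sort(c(0, if (length(u) > 1L) (u[-1] + u[-length(u)]) / 2, 1),
                       decreasing = TRUE))
  rows <- lapply(cands, function(t) {
    cc <- confusion_at(scores, labels, t)
    data.frame(threshold = t, fpr = 1 - .spec(cc), tpr = .sens(cc))
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  utils::write.csv(curve, out_path, row.names = FALSE)
  invisible(curve)
}

#' Per-class and micro-average metrics report
#'
#' @param probs `n x 6` probability matrix.
#' @param labels `n x 6` 0/1 matrix.
#' @param thresholds named threshold vector.
#' @return object of class `metrics_report`: list with `per_class` data
#'   frame (class, auc, accuracy, sensitivity, specificity, threshold),
#'   `micro` (pooled metrics over the six diseases), `normal`
#'   (accuracy/sensitivity/specificity of the derived Normal class) and
#'   `n` (number of images).
#' @export
metrics_report <- function(probs, labels, thresholds) {
  stopifnot(ncol(probs) == 6L, ncol(labels) == 6L)
  colnames(probs) <- disease_names()
  colnames(labels) <- disease_names()
  counts <- lapply(disease_names(), function(d) {
    confusion_at(probs[, d], labels[, d], thresholds[[d]])
  })
  per_class <- do.call(rbind, lapply(seq_len(6L), function(j) {
    cc <- counts[[j]]
    data.frame(class = disease_names()[j],
               auc = auc(probs[, j], labels[, j]),
               accuracy = .acc(cc), sensitivity = .sens(cc),
               specificity = .spec(cc),
               threshold = thresholds[[j]],
               stringsAsFactors = FALSE)
  }))
  nn <- normal_eval(probs, labels, thresholds)
  structure(list(per_class = per_class,
                 micro = micro_average(counts),
                 normal = list(accuracy = .acc(nn), sensitivity = .sens(nn),
                               specificity = .spec(nn)),
                 n = nrow(probs)),
            class = "metrics_report")
}
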