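#' Confusion counts under a one-vs-all reduction
#'
#' @param true_labels,predicted_labels equal-length integer label vectors.
#' @param positive_class the class index treated as positive.
#' @return list of class `confusion_counts` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(true_labels, predicted_labels, positive_class) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  known <- unique(c(true_labels, predicted_labels))
  if (!positive_class %in% known)
    stop("positive_class ", positive_class, " never occurs in the labels")
  tp_ <- true_labels == positive_class
  pp_ <- predicted_labels == positive_class
  structure(list(TP = sum(tp_ & pp_), FP = sum(!tp_ & pp_),
                 TN = sum(!tp_ & !pp_), FN = sum(tp_ & !pp_)),
            class = "confusion_counts")
}

sensitivity_of <- function(cc) if (cc$TP + cc$FN == 0) NA_real_ else cc$TP / (cc$TP + cc$FN)
specificity_of <- function(cc) if (cc$TN + cc$FP == 0) NA_real_ else cc$TN / (cc$TN + cc$FP)
precision_of <- function(cc) if (cc$TP + cc$FP == 0) 0 else cc$TP / (cc$TP + cc$FP)

#' F-measure: geometric mean of sensitivity and precision
#'
#' \eqn{F = \sqrt{\frac{TP}{TP+FN} \cdot \frac{TP}{TP+FP}}}. When `TP = 0`
#' both factors are taken as 0 (precision is defined as 0 when no positive
#' predictions are made), giving `F = 0`, the conservative limit.
#'
#' @param counts a [confusion()] result.
#' @export
f_measure <- function(counts) {
  if (counts$TP == 0) return(0)
  sqrt((counts$TP / (counts$TP + counts$FN)) * (counts$TP / (counts$TP + counts$FP)))
}

#' G-mean: geometric mean of sensitivity and specificity
#'
#' \eqn{G = \sqrt{\frac{TP}{TP+FN} \cdot \frac{TN}{TN+FP}}}.
#'
#' @param counts a [confusion()] result.
#' @export
g_mean <- function(counts) {
  sens <- counts$TP / (counts$TP + counts$FN)
  spec <- counts$TN / (counts$TN + counts$FP)
  sqrt(sens * spec)
}

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties credited 1/2 — the normalised Mann-Whitney
#' statistic, computed from midranks.
#'
#' @param scores per-sample scores for the positive class.
#' @param labels binary 0/1 (or logical) truth; 1 = positive.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUROC undefined: both classes must be present (got ",
         n_pos, " positives, ", n_neg, " negatives)")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Hanley-McNeil confidence interval for AUROC
#'
#' Closed-form standard error
#' \deqn{SE^2 = \frac{A(1-A) + (n_+-1)(Q_1-A^2) + (n_--1)(Q_2-A^2)}{n_+ n_-}}
#' with \eqn{Q_1 = A/(2-A)} and \eqn{Q_2 = 2A^2/(1+A)}; the normal interval
#' \eqn{A \pm z\,SE} is clipped to `[0, 1]`.
#'
#' @param auc AUROC point estimate in `[0, 1]`.
#' @param n_pos,n_neg class sizes (each >= 1).
#' @param level confidence level (default 0.95).
#' @return list with `lower`, `upper`, `se`.
#' @export
hanley_mcneil_ci <- function(auc, n_pos, n_neg, level = 0.95) {
  if (!is.finite(auc) || auc < 0 || auc > 1) stop("auc must lie in [0, 1]")
  stopifnot(n_pos >= 1, n_neg >= 1)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lower = max(0, auc - z * se), upper = min(1, auc + z * se), se = se)
}

#' Decision threshold achieving a target sensitivity
#'
#' Returns the largest threshold t (classify positive when `score >= t`)
#' whose sensitivity on the supplied calibration data is at least
#' `target_sensitivity`; candidates are the observed score values plus
#' `+Inf`. Fit this on a calibration split (typically the training set),
#' never on the test set.
#'
#' @param scores positive-class scores.
#' @param labels binary truth (1 = positive).
#' @param target_sensitivity target in `(0, 1]`, e.g. 0.9.
#' @export
threshold_for_sensitivity <- function(scores, labels, target_sensitivity) {
  labels <- as.integer(as.logical(labels))
  if (sum(labels == 1L) == 0L) stop("no positives present; sensitivity undefined")
  stopifnot(target_sensitivity > 0, target_sensitivity <= 1)
  pos <- scores[labels == 1L]
  cand <- sort(unique(scores), decreasing = TRUE)
  for (t in cand) {
    if (mean(pos >= t) >= target_sensitivity) return(t)
  }
  min(pos)  # unreachable for target <= 1: threshold min(pos) attains sens 1
}

#' Binary evaluation report at a stated threshold
#'
#' @param scores positive-class scores.
#' @param labels binary truth (1 = positive).
#' @param threshold decision threshold (score >= threshold -> positive);
#'   default 0.5.
#' @param level CI level for AUROC.
#' @return one-row data frame: sensitivity, specificity, precision, F, G,
#'   AUROC with Hanley-McNeil CI, threshold, prevalence.
#' @export
evaluate_binary <- function(scores, labels, threshold = 0.5, level = 0.95) {
  labels <- as.integer(as.logical(labels))
  pred <- as.integer(scores >= threshold)
  tp_ <- labels == 1L; pp_ <- pred == 1L
  cc <- list(TP = sum(tp_ & pp_), FP = sum(!tp_ & pp_),
             TN = sum(!tp_ & !pp_), FN = sum(tp_ & !pp_))
  a <- auroc(scores, labels)
  ci <- hanley_mcneil_ci(a, sum(labels == 1L), sum(labels == 0L), level)
  data.frame(sensitivity = sensitivity_of(cc), specificity = specificity_of(cc),
             precision = precision_of(cc), f_measure = f_measure(cc),
             g_mean = g_mean(cc), auroc = a, auroc_lower = ci$lower,
             auroc_upper = ci$upper, threshold = threshold,
             prevalence = mean(labels))
}

#' One-vs-all multi-class evaluation report
#'
#' Each class in turn is treated as positive: predictions come from the
#' row-wise argmax of the score matrix, and the class's own score column
#' feeds the ROC. Per-class sensitivity, specificity, precision, F, G and
#' AUROC (with CI) are reported together with the unweighted mean and
#' standard deviation across classes. A class absent from the truth is
#' reported as `NA` and excluded from the aggregates, with a warning.
#'
#' @param true_labels 0-based integer truth.
#' @param scores_matrix `n x K` score matrix (rows sum to 1).
#' @param K number of classes (default `ncol(scores_matrix)`).
#' @param level CI level.
#' @return list of class `eval_report`: `per_class` data frame and
#'   `aggregate` (means and SDs across classes).
#' @export
one_vs_all_report <- function(true_labels, scores_matrix, K = ncol(scores_matrix),
                              level = 0.95) {
  stopifnot(nrow(scores_matrix) == length(true_labels))
  pred <- max.col(scores_matrix, ties.method = "first") - 1L
  rows <- lapply(seq_len(K) - 1L, function(k) {
    if (!any(true_labels == k)) {
      warning("class ", k, " absent from the truth; reported as NA and excluded from the mean")
      return(data.frame(class = k, n = 0L, prevalence = 0, sensitivity = NA_real_,
                        specificity = NA_real_, precision = NA_real_,
                        f_measure = NA_real_, g_mean = NA_real_, auroc = NA_real_,
                        auroc_lower = NA_real_, auroc_upper = NA_real_))
    }
    cc <- confusion(true_labels, pred, k)
    a <- tryCatch(auroc(scores_matrix[, k + 1L], true_labels == k),
                  error = function(e) NA_real_)
    ci <- if (is.na(a)) list(lower = NA_real_, upper = NA_real_)
          else hanley_mcneil_ci(a, sum(true_labels == k), sum(true_labels != k), level)
    data.frame(class = k, n = sum(true_labels == k),
               prevalence = mean(true_labels == k),
               sensitivity = sensitivity_of(cc), specificity = specificity_of(cc),
               precision = precision_of(cc), f_measure = f_measure(cc),
               g_mean = g_mean(cc), auroc = a,
               auroc_lower = ci$lower, auroc_upper = ci$upper)
  })
  per_class <- do.call(rbind, rows)
  ok <- !is.na(per_class$sensitivity)
  agg <- list(
    mean_sensitivity = mean(per_class$sensitivity[ok]),
    sd_sensitivity = stats::sd(per_class$sensitivity[ok]),
    mean_g_mean = mean(per_class$g_mean[ok]),
    sd_g_mean = stats::sd(per_class$g_mean[ok]),
    mean_f_measure = mean(per_class$f_measure[ok]),
    mean_auroc = mean(per_class$auroc[ok]))
  structure(list(per_class = per_class, aggregate = agg), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("one-vs-all evaluation report\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  with(x$aggregate, cat(sprintf(
    "mean sensitivity %.3f (SD %.3f); mean G %.3f (SD %.3f)\n",
    mean_sensitivity, sd_sensitivity, mean_g_mean, sd_g_mean)))
  invisible(x)
}

#' Paired Wilcoxon signed-rank comparison of two models' scores
#'
#' Thin pass-through to [stats::wilcox.test()] with `paired = TRUE`, for
#' significance reporting between per-sample scores of two models evaluated
#' on the same test set. No bespoke logic.
#'
#' @param scores_a,scores_b per-sample scores from two models on identical
#'   samples.
#' @param ... forwarded to [stats::wilcox.test()].
#' @export
wilcoxon_compare <- function(scores_a, scores_b, ...) {
  stats::wilcox.test(scores_a, scores_b, paired = TRUE, ...)
}
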