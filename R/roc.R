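#' ROC analysis with DeLong confidence interval and Youden cutoff
#'
#' The AUC is the Mann-Whitney pair statistic (ties count 1/2), computed via
#' pROC together with its DeLong variance for the 95% CI (a stratified
#' bootstrap CI is available as an option). The operating-point arrays use
#' the inclusive convention -- a case is called positive iff
#' `score >= threshold` -- over all observed score values, so sensitivities
#' and specificities correspond exactly to reachable classifications. The
#' Youden cutoff maximizes `sensitivity + specificity - 1`; ties break
#' toward the smallest threshold, favoring sensitivity.
#'
#' @param scores numeric risk scores or probabilities (higher = more
#'   likely positive).
#' @param labels binary outcomes (0/1).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param conf_level confidence level of the AUC CI.
#' @return Object of class `roc_result`: `auc`, `ci`, `ci_method`,
#'   `thresholds`, `sensitivities`, `specificities`, `youden_cutoff`,
#'   `youden_j`, `n_pos`, `n_neg`.
#' @examples
#' r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' r$auc
#' @export
roc_auc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                    conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("AUC undefined: only one class present", call. = FALSE)
  rocobj <- pROC::roc(response = labels, predictor = scores,
                      levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(rocobj))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(
    rocobj, conf.level = conf_level,
    method = if (ci_method == "delong") "delong" else "bootstrap",
    boot.n = 2000, progress = "none")))[c(1, 3)]
  ths <- c(-Inf, sort(unique(scores)))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(ths, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(ths, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]  # ths ascending: smallest wins ties
  structure(list(auc = auc, ci = ci, ci_method = ci_method,
                 conf_level = conf_level,
                 thresholds = ths, sensitivities = sens,
                 specificities = spec,
                 youden_cutoff = ths[best], youden_j = j[best],
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%d%% CI %.3f-%.3f, %s), Youden cutoff %.4g (J = %.3f)\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2],
              x$ci_method, x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Confusion-matrix classification metrics
#'
#' Sensitivity, specificity, accuracy, precision and F1 from predicted and
#' true binary labels. Precision is 0 when nothing is called positive, and
#' F1 is 0 when precision + recall is 0, keeping the metrics defined on
#' degenerate classifiers.
#'
#' @param predicted predicted 0/1 labels.
#' @param labels true 0/1 labels.
#' @return Named numeric vector: `sensitivity`, `specificity`, `accuracy`,
#'   `precision`, `f1`.
#' @export
classification_metrics <- function(predicted, labels) {
  predicted <- as.integer(predicted); labels <- as.integer(labels)
  stopifnot(length(predicted) == length(labels))
  tp <- sum(predicted == 1 & labels == 1)
  fp <- sum(predicted == 1 & labels == 0)
  tn <- sum(predicted == 0 & labels == 0)
  fn <- sum(predicted == 0 & labels == 1)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (!is.na(sens) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else 0
  c(sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / length(labels), precision = prec, f1 = f1)
}

#' Waterfall data for per-patient risk scores
#'
#' Patients sorted by score, each bar tagged with its true label and its
#' side of the cutoff (positive call iff `score >= cutoff`, the same
#' convention as [roc_auc()], so the bars above the cutoff reproduce the
#' sensitivity/specificity of the corresponding classification exactly).
#'
#' @param scores numeric risk scores.
#' @param labels true 0/1 labels.
#' @param cutoff decision cutoff, typically `roc_auc(...)$youden_cutoff`.
#' @return List of class `waterfall`: `data` (ordered data frame with
#'   `rank`, `score`, `label`, `called_positive`) and `cutoff`,
#'   `cutoff_index` (number of bars below the cutoff).
#' @export
waterfall <- function(scores, labels, cutoff) {
  stopifnot(length(scores) == length(labels))
  ord <- order(scores)
  d <- data.frame(rank = seq_along(scores),
                  score = scores[ord],
                  label = as.integer(labels)[ord],
                  called_positive = scores[ord] >= cutoff)
  structure(list(data = d, cutoff = cutoff,
                 cutoff_index = sum(!d$called_positive)),
            class = "waterfall")
}

#' @export
print.waterfall <- function(x, ...) {
  cat(sprintf("<waterfall> %d patients, cutoff %.4g (%d below / %d above)\n",
              nrow(x$data), x$cutoff, x$cutoff_index,
              nrow(x$data) - x$cutoff_index))
  invisible(x)
}
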