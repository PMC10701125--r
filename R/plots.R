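# ggplot2 figure helpers (Suggests-only; every function guards the import)

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the plotting helpers need the `ggplot2` package", call. = FALSE)
}

#' Plot ROC curves
#'
#' @param rocs a `roc_result` or a named list of them (one curve each).
#' @return A ggplot object.
#' @export
plot_roc <- function(rocs) {
  need_ggplot2()
  if (inherits(rocs, "roc_result")) rocs <- list(model = rocs)
  d <- do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(model = sprintf("%s (AUC %.3f)", nm, r$auc),
               fpr = 1 - r$specificities, tpr = r$sensitivities)
  }))
  ggplot2::ggplot(d, ggplot2::aes(.data$fpr, .data$tpr,
                                  color = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot decision curves
#'
#' @param curves a `decision_curve` or a named list of them; the treat-all
#'   and treat-none references come from the first.
#' @return A ggplot object.
#' @export
plot_decision_curve <- function(curves) {
  need_ggplot2()
  if (inherits(curves, "decision_curve")) curves <- list(model = curves)
  d <- do.call(rbind, lapply(names(curves), function(nm)
    data.frame(model = nm, threshold = curves[[nm]]$threshold,
               nb = curves[[nm]]$net_benefit)))
  ref <- curves[[1]]
  d <- rbind(d,
             data.frame(model = "treat all", threshold = ref$threshold,
                        nb = ref$nb_all),
             data.frame(model = "treat none", threshold = ref$threshold,
                        nb = 0))
  ggplot2::ggplot(d, ggplot2::aes(.data$threshold, .data$nb,
                                  color = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(ylim = c(-0.1, max(d$nb) + 0.02)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  color = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a waterfall of per-patient scores
#'
#' @param wf a [waterfall()] object.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(wf) {
  need_ggplot2()
  d <- wf$data
  d$outcome <- factor(d$label, c(0, 1), c("no severe toxicity",
                                          "severe toxicity"))
  ggplot2::ggplot(d, ggplot2::aes(.data$rank, .data$score,
                                  fill = .data$outcome)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::geom_vline(xintercept = wf$cutoff_index + 0.5,
                        linetype = 2) +
    ggplot2::labs(x = "Patients (sorted by score)", y = "Score",
                  fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
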