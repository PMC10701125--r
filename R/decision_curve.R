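#' Decision curve analysis (net benefit)
#'
#' Net benefit of treating patients whose predicted probability is at least
#' the threshold probability `p_t`:
#' `NB(p_t) = TP/N - (FP/N) * p_t / (1 - p_t)`, compared with treating all
#' (`NB_all = pi - (1 - pi) * p_t / (1 - p_t)`, `pi` the prevalence) and
#' treating none (identically 0). The treat-all curve crosses zero exactly
#' at `p_t = pi`.
#'
#' @param probabilities predicted probabilities in \[0, 1\].
#' @param labels true 0/1 labels.
#' @param thresholds threshold probabilities, strictly inside (0, 1);
#'   values at 0 or 1 are dropped with a warning.
#' @return Data frame of class `decision_curve`: `threshold`,
#'   `net_benefit` (model), `nb_all`, `nb_none`, with the prevalence as
#'   attribute `prevalence`.
#' @examples
#' dc <- decision_curve(c(0.2, 0.8, 0.6, 0.1), c(0, 1, 1, 0))
#' head(dc, 3)
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  labels <- as.integer(labels)
  stopifnot(length(probabilities) == length(labels))
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  bad <- thresholds <= 0 | thresholds >= 1
  if (any(bad)) {
    warning("dropping threshold(s) at 0 or 1")
    thresholds <- thresholds[!bad]
  }
  n <- length(labels)
  prev <- mean(labels)
  odds <- thresholds / (1 - thresholds)
  nb <- vapply(seq_along(thresholds), function(k) {
    called <- probabilities >= thresholds[k]
    tp <- sum(called & labels == 1)
    fp <- sum(called & labels == 0)
    tp / n - (fp / n) * odds[k]
  }, numeric(1))
  out <- data.frame(threshold = thresholds, net_benefit = nb,
                    nb_all = prev - (1 - prev) * odds, nb_none = 0)
  attr(out, "prevalence") <- prev
  class(out) <- c("decision_curve", "data.frame")
  out
}
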