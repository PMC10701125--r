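#' Between-group comparison tests
#'
#' Dispatches the standard baseline-table tests. A contingency matrix
#' (variables in rows, groups in columns) gets a Pearson chi-squared test
#' without continuity correction, or Fisher's exact test when any expected
#' cell count is below 5. A numeric variable with a grouping factor gets a
#' Student t test (or Mann-Whitney U) for two groups and one-way ANOVA for
#' more.
#'
#' @param x a contingency matrix of counts, or a numeric vector.
#' @param group grouping factor (ignored when `x` is a matrix).
#' @param method `"auto"` picks as above; or force one of `"chisq"`,
#'   `"fisher"`, `"t"`, `"wilcoxon"`, `"anova"`.
#' @return List: `test` (label), `statistic`, `p_value`.
#' @examples
#' sex <- matrix(c(82, 33, 31, 18, 36, 14), nrow = 2)
#' compare_groups(sex)$p_value  # 0.542
#' @export
compare_groups <- function(x, group = NULL,
                           method = c("auto", "chisq", "fisher", "t",
                                      "wilcoxon", "anova")) {
  method <- match.arg(method)
  if (is.matrix(x)) {
    if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
    if (any(colSums(x) == 0) || any(rowSums(x) == 0))
      stop("empty group or category", call. = FALSE)
    if (method == "auto") {
      expected <- suppressWarnings(chisq.test(x, correct = FALSE)$expected)
      method <- if (any(expected < 5)) "fisher" else "chisq"
    }
    if (method == "chisq") {
      ht <- suppressWarnings(chisq.test(x, correct = FALSE))
      return(list(test = "Pearson chi-squared",
                  statistic = unname(ht$statistic), p_value = ht$p.value))
    }
    if (method == "fisher") {
      ht <- fisher.test(x)
      return(list(test = "Fisher exact", statistic = NA_real_,
                  p_value = ht$p.value))
    }
    stop("method `", method, "` needs a numeric variable", call. = FALSE)
  }
  group <- droplevels(as.factor(group))
  if (length(group) != length(x)) stop("x/group length mismatch",
                                       call. = FALSE)
  if (any(table(group) == 0) || nlevels(group) < 2)
    stop("need at least two non-empty groups", call. = FALSE)
  if (method == "auto") method <- if (nlevels(group) == 2) "t" else "anova"
  switch(method,
    t = {
      ht <- t.test(x ~ group, var.equal = TRUE)
      list(test = "Student t", statistic = unname(ht$statistic),
           p_value = ht$p.value)
    },
    wilcoxon = {
      ht <- wilcox.test(x ~ group)
      list(test = "Mann-Whitney U", statistic = unname(ht$statistic),
           p_value = ht$p.value)
    },
    anova = {
      ht <- summary(aov(x ~ group))[[1]]
      list(test = "One-way ANOVA", statistic = ht$`F value`[1],
           p_value = ht$`Pr(>F)`[1])
    },
    stop("method `", method, "` needs a contingency matrix", call. = FALSE))
}

#' One-way ANOVA from per-group summary statistics
#'
#' Reconstructs the F test from group means, SDs and sizes (between-group
#' and within-group sums of squares), for comparing published baseline
#' tables without raw data.
#'
#' @param means,sds,ns per-group mean, SD and size.
#' @return List: `test`, `statistic` (F), `df`, `p_value`.
#' @examples
#' anova_from_summary(c(55.4, 54.5, 51.5), c(10.3, 9.9, 8.3),
#'                    c(115, 49, 50))$p_value
#' @export
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(means); n <- sum(ns)
  gm <- sum(ns * means) / n
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(test = "One-way ANOVA (from summaries)", statistic = f,
       df = c(k - 1, n - k),
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Pooled mean and SD across groups
#'
#' The pooled mean is the size-weighted mean; the pooled SD combines
#' within-group sums of squares with the between-group dispersion over
#' `sum(n) - 1` degrees of freedom, i.e. the SD the merged sample would
#' show.
#'
#' @param means,sds,ns per-group mean, SD and size (`ns >= 1`; SD ignored
#'   for singleton groups).
#' @return Named vector: `mean`, `sd`, `n`.
#' @examples
#' pooled_summary(c(47.2, 44.9, 47.7), c(7.5, 6.3, 8.4), c(115, 49, 50))
#' @export
pooled_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  if (any(ns < 1)) stop("group sizes must be positive", call. = FALSE)
  n <- sum(ns)
  m <- sum(ns * means) / n
  if (n < 2) return(c(mean = m, sd = NA_real_, n = n))
  ss <- sum((ns - 1) * sds^2, na.rm = TRUE) + sum(ns * (means - m)^2)
  c(mean = m, sd = sqrt(ss / (n - 1)), n = n)
}
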