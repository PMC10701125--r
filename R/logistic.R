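#' Uni- and multivariate logistic odds ratios
#'
#' Wald-based per-variable summaries: `OR = exp(beta)`, 95% CI
#' `exp(beta +/- 1.96 SE)`, two-sided Wald p-value. In univariate mode each
#' predictor is fitted alone against the outcome; in multivariate mode all
#' predictors enter one model. A predictor whose fit fails (separation,
#' singularity) yields an `NA` row and a warning, not an error.
#'
#' @param x data frame of predictors.
#' @param y binary outcome.
#' @param mode `"univariate"` or `"multivariate"`.
#' @return Data frame: `variable`, `or`, `ci_low`, `ci_high`, `p`.
#' @export
logistic_odds_ratios <- function(x, y, mode = c("univariate",
                                                "multivariate")) {
  mode <- match.arg(mode)
  x <- as.data.frame(x, check.names = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("outcome has a single class", call. = FALSE)
  row_from <- function(fit, vars) {
    sm <- summary(fit)$coefficients
    keep <- intersect(rownames(sm), vars)
    # a Wald SE this large means separation: the estimate is meaningless
    bad <- keep[sm[keep, 2] > 50]
    if (length(bad)) {
      warning("quasi-separation for: ", paste(bad, collapse = ", "),
              "; reporting NA")
      sm[bad, ] <- NA_real_
    }
    data.frame(variable = keep,
               or = exp(sm[keep, 1]),
               ci_low = exp(sm[keep, 1] - qnorm(0.975) * sm[keep, 2]),
               ci_high = exp(sm[keep, 1] + qnorm(0.975) * sm[keep, 2]),
               p = sm[keep, 4],
               row.names = NULL)
  }
  na_row <- function(v) data.frame(variable = v, or = NA_real_,
                                   ci_low = NA_real_, ci_high = NA_real_,
                                   p = NA_real_)
  if (mode == "univariate") {
    out <- lapply(names(x), function(v) {
      dat <- data.frame(y = y, x[[v]]); names(dat)[2] <- v
      tryCatch({
        fit <- glm(y ~ ., family = binomial(), data = dat)
        if (any(is.na(coef(fit)))) stop("singular fit")
        row_from(fit, v)
      }, error = function(e) {
        warning("univariate fit failed for ", v, ": ", conditionMessage(e))
        na_row(v)
      })
    })
    do.call(rbind, out)
  } else {
    dat <- cbind(data.frame(y = y), x)
    tryCatch({
      fit <- glm(y ~ ., family = binomial(), data = dat)
      out <- row_from(fit, setdiff(names(coef(fit)), "(Intercept)"))
      bad <- names(coef(fit))[is.na(coef(fit))]
      if (length(bad)) {
        warning("dropped aliased predictor(s): ", paste(bad, collapse = ", "))
        out <- rbind(out, do.call(rbind, lapply(bad, na_row)))
      }
      out
    }, error = function(e) {
      warning("multivariate fit failed: ", conditionMessage(e))
      do.call(rbind, lapply(names(x), na_row))
    })
  }
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)`, with `R2_j` from the least-squares regression
#' of column `j` on the remaining columns. Exactly collinear columns are
#' reported as `Inf` with a warning.
#'
#' @param x data frame or matrix with at least 2 columns and 3 rows.
#' @return Named numeric vector of VIFs.
#' @examples
#' vif(data.frame(a = rnorm(50), b = rnorm(50)))
#' @export
vif <- function(x) {
  x <- as.data.frame(x, check.names = FALSE)
  if (ncol(x) < 2) stop("need at least 2 columns", call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 rows", call. = FALSE)
  out <- vapply(seq_along(x), function(j) {
    fit <- lm(x[[j]] ~ ., data = x[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(out) <- names(x)
  if (any(is.infinite(out)))
    warning("exact collinearity: ",
            paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}
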