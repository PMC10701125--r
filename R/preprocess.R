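#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda`, with the `lambda = 0` limit `log(x)`. Defined
#' for strictly positive `x`.
#'
#' @param x positive numeric vector.
#' @param lambda power parameter.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values",
                        call. = FALSE)
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Estimate the Box-Cox parameter by profile maximum likelihood
#'
#' Maximizes the normal-theory profile log-likelihood
#' `-n/2 log(sigma_hat^2(lambda)) + (lambda - 1) sum(log x)` over a grid on
#' `[-2, 2]`.
#'
#' @param x positive numeric vector.
#' @param grid candidate lambda values.
#' @return The maximizing lambda.
#' @examples
#' estimate_boxcox_lambda(exp(rnorm(500)))  # near 0 for lognormal data
#' @export
estimate_boxcox_lambda <- function(x, grid = seq(-2, 2, by = 0.05)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values",
                        call. = FALSE)
  n <- length(x)
  slx <- sum(log(x))
  ll <- vapply(grid, function(lam) {
    y <- boxcox_transform(x, lam)
    s2 <- mean((y - mean(y))^2)
    if (s2 <= 0) return(-Inf)
    -n / 2 * log(s2) + (lam - 1) * slx
  }, numeric(1))
  grid[which.max(ll)]
}

#' Fit feature preprocessing on the training set
#'
#' Per feature: a Box-Cox transform (lambda by profile maximum likelihood on
#' a grid over \[-2, 2\]) when the feature is strictly positive, skipped
#' otherwise; then centering to mean 0 and scaling to SD 1. All parameters
#' come from the training rows only, so applying them to validation data
#' cannot leak information. Zero-variance features are dropped with a
#' warning.
#'
#' @param table data frame or matrix of numeric features (training rows).
#' @param boxcox apply the Box-Cox step at all.
#' @return An object of class `preprocess_params`: per-feature `lambda`
#'   (`NA` = skipped), `center`, `scale`, and the names of `dropped`
#'   features.
#' @seealso [apply_preprocess()]
#' @export
fit_preprocess <- function(table, boxcox = TRUE) {
  x <- as.data.frame(table, check.names = FALSE)
  if (nrow(x) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (!all(vapply(x, is.numeric, TRUE)))
    stop("all feature columns must be numeric", call. = FALSE)
  sds <- vapply(x, sd, numeric(1))
  dropped <- names(x)[sds == 0 | is.na(sds)]
  if (length(dropped))
    warning("dropping zero-variance feature(s): ",
            paste(dropped, collapse = ", "))
  keep <- setdiff(names(x), dropped)
  lambda <- floor_ <- setNames(rep(NA_real_, length(keep)), keep)
  center <- scale_ <- setNames(numeric(length(keep)), keep)
  for (f in keep) {
    v <- x[[f]]
    if (boxcox && all(v > 0)) {
      lambda[f] <- estimate_boxcox_lambda(v)
      # new data may dip to or below zero where training data did not;
      # such values are clipped to half the smallest training value
      floor_[f] <- min(v) / 2
      v <- boxcox_transform(v, lambda[f])
    }
    center[f] <- mean(v)
    scale_[f] <- sd(v)
  }
  if (any(scale_ == 0)) {
    bad <- names(scale_)[scale_ == 0]
    warning("dropping feature(s) degenerate after transform: ",
            paste(bad, collapse = ", "))
    keep <- setdiff(keep, bad)
    lambda <- lambda[keep]; center <- center[keep]; scale_ <- scale_[keep]
    floor_ <- floor_[keep]
    dropped <- c(dropped, bad)
  }
  structure(list(features = keep, lambda = lambda, center = center,
                 scale = scale_, floor = floor_, dropped = dropped),
            class = "preprocess_params")
}

#' Apply fitted preprocessing parameters
#'
#' Transforms a feature table with parameters estimated by
#' [fit_preprocess()] -- unchanged, with no re-estimation, which is what
#' makes validation-set transforms leakage-free. The training table maps to
#' columnwise mean 0 / SD 1 by construction.
#'
#' @param params a `preprocess_params`.
#' @param table feature table containing at least the retained features.
#' @return Data frame of transformed features, columns in `params` order.
#' @export
apply_preprocess <- function(params, table) {
  stopifnot(inherits(params, "preprocess_params"))
  x <- as.data.frame(table, check.names = FALSE)
  missing <- setdiff(params$features, names(x))
  if (length(missing))
    stop("feature(s) absent from table: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  out <- lapply(params$features, function(f) {
    v <- x[[f]]
    if (!is.na(params$lambda[f])) {
      v <- pmax(v, params$floor[f])
      v <- boxcox_transform(v, params$lambda[f])
    }
    (v - params$center[f]) / params$scale[f]
  })
  names(out) <- params$features
  as.data.frame(out, check.names = FALSE, optional = TRUE)
}

#' @export
print.preprocess_params <- function(x, ...) {
  cat(sprintf("<preprocess_params> %d features (%d Box-Cox, %d dropped)\n",
              length(x$features), sum(!is.na(x$lambda)), length(x$dropped)))
  invisible(x)
}
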