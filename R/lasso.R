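#' LASSO-penalized logistic feature selection
#'
#' Fits an L1-penalized logistic regression over a penalty path and selects
#' the penalty by minimum mean cross-validated binomial deviance over `k`
#' stratified folds (seeded). Features entering here are expected to be
#' preprocessed (centered/scaled), so the penalty treats them
#' symmetrically; `glmnet`'s internal standardization is disabled.
#'
#' @param x numeric matrix or data frame of predictors (rows = patients).
#' @param y binary outcome (0/1), both classes present.
#' @param k number of cross-validation folds.
#' @param seed seed for the fold assignment.
#' @param lambda optional fixed penalty; skips cross-validation. `0` gives
#'   an (essentially) unpenalized fit.
#' @return Object of class `rad_lasso`: `lambda`, `intercept`,
#'   `coefficients` (nonzero only, named), `selected`, `path` (number of
#'   nonzero coefficients along the lambda path), and the `cv` object when
#'   cross-validation ran.
#' @export
fit_lasso_logistic <- function(x, y, k = 5, seed = 1, lambda = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  if (nrow(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  if (nrow(x) < k) stop("fewer rows than folds", call. = FALSE)
  cv <- NULL
  if (is.null(lambda)) {
    foldid <- integer(length(y))
    set.seed(seed)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", foldid = foldid,
                            type.measure = "deviance", standardize = FALSE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    path <- sort(unique(c(exp(seq(log(max(lambda, 0.5)), log(1e-5),
                                  length.out = 60)), lambda)),
                 decreasing = TRUE)
    fit <- glmnet::glmnet(x, y, family = "binomial", lambda = path,
                          standardize = FALSE, thresh = 1e-12)
  }
  cf <- as.matrix(coef(fit, s = lambda, exact = TRUE, x = x, y = y))[, 1]
  nz <- cf[-1][cf[-1] != 0]
  structure(list(lambda = lambda, intercept = unname(cf[1]),
                 coefficients = nz, selected = names(nz),
                 path = fit$df, path_lambda = fit$lambda, cv = cv,
                 k = k, seed = seed),
            class = "rad_lasso")
}

#' @export
print.rad_lasso <- function(x, ...) {
  cat(sprintf("<rad_lasso> lambda = %.5g, %d feature(s) selected\n",
              x$lambda, length(x$selected)))
  if (length(x$selected)) {
    cf <- sort(x$coefficients)
    for (f in names(cf)) cat(sprintf("  %-42s %+ .4f\n", f, cf[f]))
  }
  invisible(x)
}

#' Radiomics score
#'
#' The rad-score of a patient is the linear combination of the selected
#' *radiomics* features weighted by their LASSO coefficients (no
#' intercept). The SMI, even if it survives selection, is excluded here and
#' enters the combined model as its own covariate, which matches reporting
#' the SMI and the rad-score as separate predictors.
#'
#' @param model a `rad_lasso` fit.
#' @param x preprocessed feature table containing all selected features.
#' @param exclude feature names to leave out of the score (default `"smi"`).
#' @return Numeric score per row of `x`.
#' @export
rad_score <- function(model, x, exclude = "smi") {
  stopifnot(inherits(model, "rad_lasso"))
  feats <- setdiff(model$selected, exclude)
  if (length(feats) == 0) return(rep(0, nrow(as.data.frame(x))))
  x <- as.data.frame(x, check.names = FALSE)
  missing <- setdiff(feats, names(x))
  if (length(missing))
    stop("selected feature(s) absent from table: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  as.vector(as.matrix(x[feats]) %*% model$coefficients[feats])
}

#' Combined SMI + rad-score logistic model
#'
#' Ordinary two-covariate maximum-likelihood logistic regression of the
#' outcome on the (raw) SMI and the rad-score. Perfect separation is
#' detected and handled by a ridge-stabilized refit (penalty `1e-6`) with a
#' warning rather than an error.
#'
#' @param smi SMI values (cm2/m2).
#' @param radscore rad-scores from [rad_score()].
#' @param y binary outcome.
#' @return Object of class `combined_model`: `coefficients` (intercept,
#'   smi, radscore), `fitted` probabilities, `separation` flag, and the
#'   underlying `glm` when applicable.
#' @export
fit_combined <- function(smi, radscore, y) {
  stopifnot(length(smi) == length(y), length(radscore) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  dat <- data.frame(y = y, smi = smi, radscore = radscore)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ smi + radscore, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf0 <- coef(fit)
  if (any(is.na(cf0))) {
    warning("degenerate covariate(s) dropped from the combined model: ",
            paste(names(cf0)[is.na(cf0)], collapse = ", "))
    cf0[is.na(cf0)] <- 0
    fit$coefficients <- cf0
  }
  if (sep || !fit$converged || any(abs(cf0[-1]) > 50)) {
    warning("perfect or quasi-separation detected; ",
            "refitting with a small ridge penalty")
    xm <- as.matrix(dat[, c("smi", "radscore")])
    rg <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                         lambda = c(1, 0.1, 1e-6), standardize = FALSE)
    cf <- as.matrix(coef(rg, s = 1e-6))[, 1]
    eta <- cf[1] + xm %*% cf[-1]
    return(structure(list(coefficients = setNames(cf, c("(Intercept)",
                                                        "smi", "radscore")),
                          fitted = as.vector(plogis(eta)),
                          separation = TRUE, glm = NULL),
                     class = "combined_model"))
  }
  structure(list(coefficients = coef(fit),
                 fitted = as.vector(fit$fitted.values),
                 separation = FALSE, glm = fit),
            class = "combined_model")
}

#' @param object a `combined_model`.
#' @param newdata data frame with `smi` and `radscore` columns.
#' @param ... unused.
#' @rdname fit_combined
#' @export
predict.combined_model <- function(object, newdata, ...) {
  cf <- object$coefficients
  eta <- cf[1] + cf["smi"] * newdata$smi + cf["radscore"] * newdata$radscore
  as.vector(plogis(eta))
}

#' @export
print.combined_model <- function(x, ...) {
  cat("<combined_model> logit(p) =",
      sprintf("%.3f %+.3f*SMI %+.3f*radscore\n", x$coefficients[1],
              x$coefficients["smi"], x$coefficients["radscore"]))
  if (x$separation) cat("  (ridge-stabilized: separation detected)\n")
  invisible(x)
}
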