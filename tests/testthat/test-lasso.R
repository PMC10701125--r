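sim_logistic <- function(n, p, informative = c(1, 2), beta = c(1.2, -1),
                         seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- -0.5 + x[, informative, drop = FALSE] %*% beta
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}

test_that("an overwhelming penalty zeroes every coefficient", {
  d <- sim_logistic(100, 8)
  fit <- fit_lasso_logistic(d$x, d$y, lambda = 10)
  expect_length(fit$selected, 0)
  expect_equal(unname(fit$intercept), qlogis(mean(d$y)), tolerance = 1e-4)
})

test_that("lambda = 0 reproduces the Newton-Raphson (glm) solution", {
  d <- sim_logistic(300, 3)
  fit <- fit_lasso_logistic(d$x, d$y, lambda = 0)
  oracle <- glm(d$y ~ d$x, family = binomial())
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(coef(oracle)), tolerance = 1e-4)
})

test_that("cross-validated selection finds the informative features", {
  d <- sim_logistic(400, 253, informative = c(10, 200),
                    beta = c(1.5, -1.5), seed = 5)
  fit <- fit_lasso_logistic(d$x, d$y, k = 5, seed = 9)
  expect_true(all(c("f10", "f200") %in% fit$selected))
  # sparsity: far fewer survivors than predictors
  expect_lt(length(fit$selected), 60)
})

test_that("nonzero count is non-increasing in the penalty", {
  d <- sim_logistic(200, 20, informative = 1:5, beta = rep(1, 5))
  fit <- fit_lasso_logistic(d$x, d$y, k = 5, seed = 2)
  # path_lambda is decreasing; allow glmnet's occasional single-step jitter
  viol <- sum(diff(fit$path) < 0)
  expect_lte(viol, 1)
})

test_that("fold assignment is stratified and seeded", {
  d <- sim_logistic(150, 5)
  f1 <- fit_lasso_logistic(d$x, d$y, seed = 3)
  f2 <- fit_lasso_logistic(d$x, d$y, seed = 3)
  expect_identical(f1$lambda, f2$lambda)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_error(fit_lasso_logistic(d$x, rep(1, 150)), "single class")
})

test_that("the rad-score is the selected linear combination", {
  fit <- structure(list(lambda = 0.1, intercept = 0.3,
                        coefficients = c(smi = -0.5, a = 2, b = -1),
                        selected = c("smi", "a", "b")),
                   class = "rad_lasso")
  x <- data.frame(smi = c(40, 50), a = c(0, 1), b = c(0, 2))
  s <- rad_score(fit, x)
  # smi excluded; score = 2a - b, no intercept
  expect_equal(s, c(0, 0))
  x2 <- x; x2$a <- x2$a + 1
  expect_equal(rad_score(fit, x2) - s, c(2, 2))
  expect_error(rad_score(fit, x[, "smi", drop = FALSE]), "absent")
  expect_equal(rad_score(fit, x, exclude = NULL),
               -0.5 * x$smi + 2 * x$a - 1 * x$b)
})

test_that("combined model satisfies the logistic score equation", {
  set.seed(6)
  n <- 300
  smi <- rnorm(n, 47, 7)
  rs <- rnorm(n)
  y <- rbinom(n, 1, plogis(-0.5 - 0.1 * (smi - 47) + rs))
  fit <- fit_combined(smi, rs, y)
  expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-6)
  expect_lt(fit$coefficients["smi"], 0)
  expect_gt(fit$coefficients["radscore"], 0)
  pr <- predict(fit, data.frame(smi = smi, radscore = rs))
  expect_equal(pr, fit$fitted, tolerance = 1e-12)
})

test_that("null coefficients give probability one half", {
  m <- structure(list(coefficients = c(`(Intercept)` = 0, smi = 0,
                                       radscore = 0)),
                 class = "combined_model")
  expect_equal(predict(m, data.frame(smi = c(10, 80), radscore = c(-5, 5))),
               c(0.5, 0.5))
})

test_that("separation is caught and ridge-stabilized", {
  smi <- c(30:39, 50:59)
  y <- rep(c(1, 0), each = 10)
  rs <- rep(0, 20)
  w <- capture_warnings(fit <- fit_combined(smi, rs, y))
  expect_true(any(grepl("separation", w)))
  expect_true(fit$separation)
  expect_true(all(is.finite(fit$coefficients)))
  expect_lt(fit$coefficients["smi"], 0)
})
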