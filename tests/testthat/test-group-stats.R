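# Published three-cohort baseline rows (training / internal / external):
# counts transcribed from the source study's baseline table.
sex_counts <- matrix(c(82, 33, 31, 18, 36, 14), nrow = 2)
irino_counts <- matrix(c(34, 81, 8, 41, 7, 43), nrow = 2)

test_that("chi-squared reproduces the published baseline p-values", {
  expect_equal(round(compare_groups(sex_counts)$p_value, 3), 0.542)
  expect_equal(round(compare_groups(irino_counts)$p_value, 3), 0.042)
})

test_that("identical groups give a zero statistic and p = 1", {
  tab <- matrix(c(30, 20, 30, 20), nrow = 2)
  res <- compare_groups(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("sparse tables fall back to Fisher's exact test", {
  tab <- matrix(c(2, 1, 1, 9), nrow = 2)
  res <- compare_groups(tab)
  expect_match(res$test, "Fisher")
  expect_equal(res$p_value, fisher.test(tab)$p.value)
})

test_that("continuous comparisons dispatch to t, Wilcoxon, ANOVA", {
  set.seed(81)
  x <- c(rnorm(30, 0), rnorm(30, 1))
  g <- rep(c("a", "b"), each = 30)
  expect_equal(compare_groups(x, g)$p_value,
               t.test(x ~ g, var.equal = TRUE)$p.value)
  expect_equal(compare_groups(x, g, method = "wilcoxon")$p_value,
               wilcox.test(x ~ g)$p.value)
  x3 <- c(x, rnorm(30, 2)); g3 <- rep(c("a", "b", "c"), each = 30)
  expect_equal(compare_groups(x3, g3)$p_value,
               summary(aov(x3 ~ factor(g3)))[[1]]$`Pr(>F)`[1])
  expect_error(compare_groups(x, rep("a", 60)), "two non-empty")
})

test_that("summary-statistic ANOVA matches raw-data ANOVA", {
  set.seed(82)
  gs <- list(rnorm(40, 10, 2), rnorm(25, 11, 2), rnorm(30, 9.5, 2.5))
  raw_p <- summary(aov(unlist(gs) ~ rep(letters[1:3], lengths(gs))))[[1]]$
    `Pr(>F)`[1]
  res <- anova_from_summary(vapply(gs, mean, 0), vapply(gs, sd, 0),
                            lengths(gs))
  expect_equal(res$p_value, raw_p, tolerance = 1e-10)
})

test_that("published age summaries give a borderline ANOVA p", {
  res <- anova_from_summary(c(55.4, 54.5, 51.5), c(10.3, 9.9, 8.3),
                            c(115, 49, 50))
  expect_equal(round(res$p_value, 2), 0.06)
})

test_that("pooled summaries recover the published whole-cohort values", {
  smi <- pooled_summary(c(47.2, 44.9, 47.7), c(7.5, 6.3, 8.4),
                        c(115, 49, 50))
  expect_equal(round(unname(smi["mean"]), 1), 46.8)
  expect_equal(round(unname(smi["sd"]), 1), 7.5)
  bmi <- pooled_summary(c(23.1, 23.3, 23.4), c(2.7, 2.6, 3.2),
                        c(115, 49, 50))
  expect_equal(round(unname(bmi["mean"]), 1), 23.2)
  expect_equal(round(unname(bmi["sd"]), 1), 2.8)
})

test_that("pooled-summary identities", {
  one <- pooled_summary(5.5, 1.2, 30)
  expect_equal(unname(one[c("mean", "sd")]), c(5.5, 1.2))
  # equal means: zero between-group SS, so only within-group SS remains
  # (denominator is the merged-sample n - 1)
  eq <- pooled_summary(c(10, 10), c(2, 3), c(20, 30))
  within <- sqrt((19 * 4 + 29 * 9) / 49)
  expect_equal(unname(eq["sd"]), within)
  expect_error(pooled_summary(1, 1, 0), "positive")
})
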