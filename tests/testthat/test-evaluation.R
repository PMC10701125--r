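test_that("AUC on the worked four-patient example is 0.75", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)
  expect_true(r$ci[1] <= r$auc && r$auc <= r$ci[2])
})

test_that("separated and degenerate score vectors", {
  r <- roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$youden_j, 1.0)
  flat <- roc_auc(rep(0.4, 10), rep(c(0, 1), 5))
  expect_equal(flat$auc, 0.5)
  expect_error(roc_auc(1:5, rep(1, 5)), "one class")
})

test_that("AUC equals exhaustive pair counting on random instances", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(10:50, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_pair_oracle(scores, labels))
  }
})

test_that("bootstrap CI option works and brackets the AUC", {
  set.seed(62)
  scores <- rnorm(60); labels <- rbinom(60, 1, plogis(scores))
  r <- roc_auc(scores, labels, ci_method = "bootstrap")
  expect_true(r$ci[1] < r$auc && r$auc < r$ci[2])
})

test_that("confusion metrics match hand counting", {
  m <- classification_metrics(c(1, 1, 1, 1, 0, 0), c(1, 1, 0, 0, 0, 0))
  expect_equal(unname(m["precision"]), 0.5)
  expect_equal(unname(m["sensitivity"]), 1.0)
  expect_equal(unname(m["f1"]), 2 / 3)
  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unname(perfect), rep(1, 5))
  set.seed(63)
  for (rep in 1:10) {
    pred <- rbinom(40, 1, 0.5); truth <- rbinom(40, 1, 0.4)
    cm <- confusion_oracle(pred, truth)
    m <- classification_metrics(pred, truth)
    expect_equal(unname(m["accuracy"]),
                 unname((cm["tp"] + cm["tn"]) / 40))
    if (cm["tp"] + cm["fn"] > 0)
      expect_equal(unname(m["sensitivity"]),
                   unname(cm["tp"] / (cm["tp"] + cm["fn"])))
  }
})

test_that("degenerate classifiers keep F1 defined", {
  m <- classification_metrics(rep(0, 6), c(1, 1, 0, 0, 0, 0))
  expect_equal(unname(m["precision"]), 0)
  expect_equal(unname(m["f1"]), 0)
})

test_that("waterfall partition agrees with the Youden operating point", {
  set.seed(64)
  for (rep in 1:8) {
    n <- 60
    scores <- round(rnorm(n), 2)
    labels <- rbinom(n, 1, plogis(scores))
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    wf <- waterfall(scores, labels, r$youden_cutoff)
    expect_equal(nrow(wf$data), n)
    m <- classification_metrics(as.integer(scores >= r$youden_cutoff),
                                labels)
    above <- wf$data[wf$data$called_positive, ]
    expect_equal(sum(above$label == 1) / sum(labels == 1),
                 unname(m["sensitivity"]))
    expect_equal(wf$cutoff_index, sum(scores < r$youden_cutoff))
  }
})

test_that("monotone scores partition the waterfall perfectly", {
  scores <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- roc_auc(scores, labels)
  wf <- waterfall(scores, labels, r$youden_cutoff)
  expect_equal(wf$data$label, sort(labels))
  expect_equal(wf$cutoff_index, 3)
})
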