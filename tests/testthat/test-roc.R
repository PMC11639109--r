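test_that("roc_points sweeps all cut-offs with anchored, monotone curve", {
  rp <- roc_points(c(0, 10), c(FALSE, TRUE))
  expect_true(any(rp$fpr == 0 & rp$sensitivity == 1))  # perfect separation
  expect_equal(min(rp$sensitivity), 0)
  expect_equal(max(rp$fpr), 1)

  set.seed(3)
  scores <- sample(0:10, 40, replace = TRUE)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  rp <- roc_points(scores, labels)
  expect_true(all(diff(rp$sensitivity) <= 0))
  expect_true(all(diff(rp$fpr) <= 0))
  expect_true(any(rp$sensitivity == 1 & rp$fpr == 1))
  expect_true(any(rp$sensitivity == 0 & rp$fpr == 0))

  # dichotomized published counts give the single interior point
  calls <- printed_calls()
  rp <- roc_points(as.integer(calls$index), calls$reference)
  interior <- rp[rp$cutoff == 1, ]
  expect_equal(interior$sensitivity, 52 / 54)
  expect_equal(interior$fpr, 32 / 570)

  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "one positive and one negative")
})

test_that("trapezoid and Mann-Whitney AUROC agree and match pROC", {
  expect_equal(auroc(c(0, 1, 2, 5), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(rep(3, 6), rep(c(TRUE, FALSE), 3)), 0.5)  # all ties

  # dichotomized test: AUROC = (sens + spec) / 2 exactly
  calls <- printed_calls()
  expect_equal(
    auroc(as.integer(calls$index), calls$reference),
    (52 / 54 + 538 / 570) / 2
  )

  # random small instances against the independent pROC implementation
  set.seed(21)
  for (i in 1:60) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(0:5, n, replace = TRUE)
    got <- auroc(scores, labels)
    oracle <- as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores,
      direction = "<", levels = c(FALSE, TRUE), quiet = TRUE
    )))
    expect_equal(got, oracle, tolerance = 1e-12)
  }

  # shuffled labels hover around the diagonal
  set.seed(4)
  scores <- rep(0:10, 40)
  aucs <- replicate(30, auroc(scores, sample(rep(c(TRUE, FALSE), 220))))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("DeLong variance matches direct placement computation and pROC", {
  # small mixed instance: recompute placement-value variances by hand
  scores <- c(3, 2, 1, 0, 1, 2, 3)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  got <- delong_ci(scores, labels)
  pos <- scores[labels]; neg <- scores[!labels]
  v10 <- sapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)))
  v01 <- sapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)))
  expect_equal(got$auc, mean(v10))
  expect_equal(got$se, sqrt(var(v10) / 3 + var(v01) / 4))

  # published dichotomized counts: two-decimal CI bounds
  calls <- printed_calls()
  dl <- delong_ci(as.integer(calls$index), calls$reference)
  expect_equal(round(dl$auc, 2), 0.95)
  expect_equal(round(dl$conf.low, 2), 0.93)
  expect_equal(round(dl$conf.high, 2), 0.98)

  # independent oracle on random instances
  set.seed(8)
  for (i in 1:20) {
    labels <- c(rep(TRUE, 6), rep(FALSE, 10))
    scores <- sample(0:8, 16, replace = TRUE)
    got <- delong_ci(scores, labels)
    oracle <- pROC::ci.auc(pROC::roc(
      response = labels, predictor = scores,
      direction = "<", levels = c(FALSE, TRUE), quiet = TRUE
    ), method = "delong")
    expect_equal(got$auc, as.numeric(oracle[2]), tolerance = 1e-12)
    expect_equal(got$conf.low, max(0, as.numeric(oracle[1])), tolerance = 1e-8)
    expect_equal(got$conf.high, min(1, as.numeric(oracle[3])), tolerance = 1e-8)
  }

  # perfect separation: zero variance, interval collapses at 1
  perf <- delong_ci(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(perf$se, 0)
  expect_equal(perf$conf.low, 1)
  expect_error(delong_ci(c(0, 1, 2), c(TRUE, FALSE, FALSE)), "two positives")
})

test_that("Youden selection maximizes J with low-cutoff tie-break", {
  published <- tibble::tibble(
    cutoff = c(3L, 4L, 5L),
    sensitivity = c(0.96, 0.89, 0.83),
    specificity = c(0.94, 0.98, 0.99)
  )
  expect_identical(youden_optimal(published), 3L)
  expect_identical(youden_optimal(published[2, ]), 4L)
  tie <- tibble::tibble(
    cutoff = c(2L, 1L),
    sensitivity = c(0.5, 0.9), specificity = c(0.9, 0.5)
  )
  expect_identical(youden_optimal(tie), 1L)
})
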