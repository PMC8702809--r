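test_that("class balance counts vessel and background pixels", {
  y <- c(1, 0, 0, 0)
  b <- class_balance(y)
  expect_equal(b$m, 4)
  expect_equal(b$x_plus, 1)
  expect_equal(b$x_minus, 3)
  expect_equal(b$alpha, 0.75)
  expect_equal(b$alpha + b$x_plus / b$m, 1)
})

test_that("weighted BCE matches a hand-evaluated scalar oracle", {
  y <- c(1, 0, 0, 0)
  yhat <- c(0.9, 0.1, 0.2, 0.3)
  # direct evaluation: -(1/4) [0.75 ln 0.9 + 0.25 (ln 0.9 + ln 0.8 + ln 0.7)]
  oracle <- -(1 / 4) * (0.75 * log(0.9) +
                          0.25 * (log(0.9) + log(0.8) + log(0.7)))
  expect_equal(weighted_bce(y, yhat), oracle, tolerance = 1e-12)

  # near-perfect predictions drive the loss to (almost) zero
  expect_lt(weighted_bce(y, c(1 - 1e-9, 1e-9, 1e-9, 1e-9)), 1e-5)

  # alpha = 0.5 halves the unweighted cross-entropy
  y2 <- c(1, 1, 0, 0)
  p2 <- c(0.8, 0.6, 0.3, 0.1)
  unweighted <- -mean(y2 * log(p2) + (1 - y2) * log(1 - p2))
  expect_equal(weighted_bce(y2, p2), unweighted / 2, tolerance = 1e-12)

  expect_error(weighted_bce(y, yhat[1:3]), class = "retseg_shape_error")
})

test_that("weighted BCE is non-negative with zero only at exact match", {
  set.seed(21)
  for (i in 1:25) {
    y <- (runif(50) > 0.7) + 0
    if (all(y == y[1])) next
    p <- runif(50, 0.01, 0.99)
    expect_gte(weighted_bce(y, p), 0)
  }
  y <- c(1, 0, 1, 0)
  expect_equal(weighted_bce(y, y), 0, tolerance = 1e-5)
})

test_that("beta schedule is affine, decreasing, with the stated endpoints", {
  expect_equal(beta_weight(loss_schedule(0, 500)), 1)
  expect_equal(beta_weight(loss_schedule(500, 500)), 0)
  expect_equal(beta_weight(loss_schedule(250, 500)), 0.5)
  b <- sapply(0:500, function(e) beta_weight(loss_schedule(e, 500)))
  expect_true(all(diff(b) < 0))
  expect_equal(diff(b), rep(-1 / 500, 500))
  expect_error(loss_schedule(501, 500), class = "retseg_parameter_error")
})

test_that("total loss composes by mode and is monotone in its components", {
  expect_equal(total_loss(1, 2, 3, 4, beta = 0), 4)          # supervision fades out
  expect_equal(total_loss(1, 2, 3, 4, beta = 0, mode = "strict"), 0)
  expect_equal(total_loss(2, 2, 2, 2, beta = 1), 8)
  expect_equal(total_loss(2, 2, 2, 2, beta = 1, mode = "strict"), 8)
  expect_gt(total_loss(1.1, 2, 3, 4, beta = 0.5), total_loss(1, 2, 3, 4, beta = 0.5))
  expect_error(total_loss(-1, 2, 3, 4, beta = 0.5), class = "retseg_domain_error")
})

test_that("confusion counts enumerate the toy example and degenerate cases", {
  truth <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  pred <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fn", "fp", "tn")],
               list(tp = 2, fn = 1, fp = 1, tn = 6))
  m <- acc_se_sp(cc)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 2 / 3)
  expect_equal(m$specificity, 6 / 7)

  perfect <- confusion_counts(truth, truth)
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_equal(unlist(acc_se_sp(perfect)), c(accuracy = 1, sensitivity = 1,
                                             specificity = 1))
  inverted <- confusion_counts(1 - truth, truth)
  expect_equal(inverted$tp + inverted$tn, 0)

  # undefined metrics are absent, not zero
  allneg <- confusion_counts(rep(0, 5), rep(0, 5))
  expect_true(is.na(acc_se_sp(allneg)$sensitivity))

  expect_error(confusion_counts(pred, truth, rep(0, 10)),
               class = "retseg_degenerate_error")
})

test_that("metrics respect the evaluation mask", {
  truth <- matrix(c(1, 0, 0, 1), 2, 2)
  pred <- matrix(c(1, 1, 0, 0), 2, 2)
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  cc <- confusion_counts(pred, truth, mask)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, sum(mask))
  expect_equal(cc$tp, 1)
  expect_equal(cc$fp, 1)
})

test_that("ROC/AUC: worked example, extremes, and concordance equivalence", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)

  # perfectly separating scores
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  # constant scores: ties as one half
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  expect_error(roc_auc(runif(5), rep(1, 5)), class = "retseg_degenerate_error")

  # threshold sweep equals brute-force pairwise concordance (with tied scores)
  set.seed(31)
  for (i in 1:120) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE) # many ties
    y <- (runif(n) > runif(1, 0.2, 0.8)) + 0
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(roc_auc(sc, y)$auc, auc_bruteforce(sc, y), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- runif(300)
  y <- (runif(300) > 0.7) + 0
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(sc, y)$auc, ref, tolerance = 1e-10)
})
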