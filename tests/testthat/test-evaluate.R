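test_that("confusion matrices tally, are order-invariant and validate", {
  truth <- c("N", "N", "V", "S", "F", "Q", "V", "N")
  est <- c("N", "V", "V", "S", "F", "Q", "V", "N")
  cm <- confusion_matrix(truth, est)
  expect_equal(sum(cm), 8L)
  expect_equal(unname(diag(cm)), c(2L, 1L, 2L, 1L, 1L))
  expect_equal(cm["N", "V"], 1L)
  perm <- sample(8)
  expect_equal(unclass(confusion_matrix(truth[perm], est[perm])),
               unclass(cm))
  # constant predictor: one nonzero column
  cm2 <- confusion_matrix(truth, rep("N", 8))
  expect_true(all(cm2[, -1] == 0))
  expect_error(confusion_matrix("N", c("N", "V")), "equal length")
  expect_error(confusion_matrix("N", "X"), "unknown label")
})

test_that("perfect predictions give all-ones metrics", {
  cm <- confusion_matrix(rep(aami_classes(), 2), rep(aami_classes(), 2))
  m <- classification_metrics(cm)
  expect_equal(m$overall_accuracy, 1)
  expect_true(all(m$by_class$accuracy == 1))
  expect_true(all(m$by_class$sensitivity == 1))
  expect_true(all(m$by_class$specificity_printed == 1))
})

test_that("metrics match a hand-evaluated one-vs-rest instance", {
  # class N: TP = 8, FN = 2 (as S), FP = 1 (S as N), TN = 9
  truth <- c(rep("N", 10), rep("S", 10))
  est <- c(rep("N", 8), "S", "S", "N", rep("S", 9))
  m <- classification_metrics(confusion_matrix(truth, est))
  n_row <- m$by_class[m$by_class$class == "N", ]
  expect_equal(n_row$sensitivity, 0.8)
  expect_equal(n_row$specificity_printed, 8 / 9)
  expect_equal(n_row$specificity_standard, 9 / 10)
  expect_equal(n_row$accuracy, 0.85)
})

test_that("metrics agree with scalar brute force on random matrices", {
  set.seed(91)
  for (rep_i in 1:5) {
    cm <- confusion_matrix(sample(aami_classes(), 200, replace = TRUE),
                           sample(aami_classes(), 200, replace = TRUE))
    m <- classification_metrics(cm)
    total <- sum(cm)
    for (ci in 1:5) {
      tp <- cm[ci, ci]
      fn <- sum(cm[ci, ]) - tp
      fp <- sum(cm[, ci]) - tp
      tn <- total - tp - fn - fp
      row <- m$by_class[ci, ]
      expect_equal(row$accuracy, (tp + tn) / total, tolerance = 1e-10)
      expect_equal(row$sensitivity, tp / (tp + fn), tolerance = 1e-10)
      expect_equal(row$specificity_printed, tp / (tp + fp),
                   tolerance = 1e-10)
    }
    expect_equal(m$overall_accuracy, sum(diag(cm)) / total,
                 tolerance = 1e-10)
  }
})

test_that("absent classes yield NA metrics without breaking the rest", {
  truth <- c("N", "N", "V")
  est <- c("N", "V", "V")
  m <- classification_metrics(confusion_matrix(truth, est))
  expect_true(is.na(m$by_class$sensitivity[m$by_class$class == "F"]))
  expect_equal(m$overall_accuracy, 2 / 3)
})

test_that("ROC hits AUC 1 on separable data and 0.5 on shuffled labels", {
  set.seed(92)
  n <- 2000
  truth <- sample(aami_classes(), n, replace = TRUE)
  # perfectly separating probabilities
  prob <- t(vapply(truth, function(cl) {
    p <- rep(0.025, 5); p[match(cl, aami_classes())] <- 0.9; p
  }, numeric(5)))
  r <- roc_ovr(truth, prob)
  expect_true(all(r$auc$auc == 1))
  # labels shuffled independently of probabilities
  prob2 <- matrix(runif(n * 5), n)
  prob2 <- prob2 / rowSums(prob2)
  r2 <- roc_ovr(sample(truth), prob2)
  expect_true(all(abs(r2$auc$auc - 0.5) < 0.05))
})

test_that("trapezoid AUC equals the concordant-pair count on small data", {
  set.seed(93)
  n <- 50
  truth <- sample(aami_classes(), n, replace = TRUE,
                  prob = c(0.4, 0.15, 0.15, 0.15, 0.15))
  prob <- matrix(runif(n * 5), n)
  prob <- prob / rowSums(prob)
  r <- roc_ovr(truth, prob)
  for (ci in 1:5) {
    y <- as.integer(truth == aami_classes()[ci])
    if (sum(y) == 0 || sum(y) == n) next
    p <- prob[, ci]
    pos <- p[y == 1]; neg <- p[y == 0]
    conc <- 0
    for (a in pos) for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(r$auc$auc[ci], conc / (length(pos) * length(neg)),
                 tolerance = 1e-10)
  }
})

test_that("our AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(94)
  n <- 300
  truth <- sample(aami_classes(), n, replace = TRUE)
  prob <- matrix(runif(n * 5), n)
  prob <- prob / rowSums(prob)
  # correlate column N with the truth so the AUC is informative
  prob[truth == "N", 1] <- prob[truth == "N", 1] + 0.5
  r <- roc_ovr(truth, prob)
  ref <- pROC::auc(pROC::roc(as.integer(truth == "N"), prob[, 1],
                             quiet = TRUE, direction = "<"))
  expect_equal(r$auc$auc[1], as.numeric(ref), tolerance = 1e-10)
})

test_that("constant probability columns warn and fall back to AUC 0.5", {
  truth <- c("N", "V", "N", "V")
  prob <- cbind(0.2, 0.2, 0.2, 0.2, 0.2)[rep(1, 4), ]
  w <- testthat::capture_warnings(r <- roc_ovr(truth, prob))
  expect_length(w, 5)   # one per constant column
  expect_match(w, "constant probability", all = TRUE)
  expect_equal(r$auc$auc[1], 0.5)
})
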