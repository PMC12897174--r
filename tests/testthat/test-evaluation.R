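# brute-force AUC oracle: concordant pairs + half ties over all pos/neg pairs
aucByPairs <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

test_that("one-vs-rest AUC matches brute-force pair counting", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(6:15, 1)
    labels <- sample(c("A2", "A3", "A4"), n, replace = TRUE)
    while (length(unique(labels)) < 3)
      labels <- sample(c("A2", "A3", "A4"), n, replace = TRUE)
    scores <- matrix(round(runif(n * 3), 1), n, 3,
                     dimnames = list(NULL, c("A2", "A3", "A4")))
    auc <- rocAucOvr(scores, labels)
    for (cl in c("A2", "A3", "A4"))
      expect_equal(auc$perClass[[cl]], aucByPairs(scores[, cl], labels == cl),
                   tolerance = 1e-12)
    expect_equal(auc$macro, mean(auc$perClass), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(22)
  score <- runif(40)
  positive <- runif(40) < 0.4
  got <- hafnet:::aucMannWhitney(score, positive)
  want <- as.numeric(pROC::auc(pROC::roc(response = positive,
                                         predictor = score, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("AUC limiting cases and invariances", {
  labels <- c("A2", "A2", "A3", "A3", "A4", "A4")
  perfect <- diag(3)[match(labels, c("A2", "A3", "A4")), ]
  colnames(perfect) <- c("A2", "A3", "A4")
  expect_equal(unname(rocAucOvr(perfect, labels)$perClass), rep(1, 3))
  flat <- matrix(1 / 3, 6, 3, dimnames = list(NULL, c("A2", "A3", "A4")))
  expect_equal(unname(rocAucOvr(flat, labels)$perClass), rep(0.5, 3))

  set.seed(23)
  score <- runif(20)
  pos <- rep(c(TRUE, FALSE), 10)
  base <- hafnet:::aucMannWhitney(score, pos)
  # strictly monotone transforms preserve ranks, hence AUC
  expect_equal(hafnet:::aucMannWhitney(exp(3 * score) - 1, pos), base,
               tolerance = 1e-12)
  # reversing score order complements the AUC
  expect_equal(hafnet:::aucMannWhitney(-score, pos), 1 - base,
               tolerance = 1e-12)
})

test_that("a class absent from the labels is excluded from the macro AUC", {
  labels <- c("A2", "A2", "A3", "A3")
  scores <- matrix(runif(12), 4, 3,
                   dimnames = list(NULL, c("A2", "A3", "A4")))
  expect_warning(auc <- rocAucOvr(scores, labels), "A4")
  expect_true(is.na(auc$perClass[["A4"]]))
  expect_equal(auc$macro, mean(auc$perClass[c("A2", "A3")]))
})

test_that("confusion matrix, accuracy and macro F1 match hand tallies", {
  truth <- c("A2", "A2", "A2", "A3", "A3", "A4", "A4", "A4")
  pred <- c("A2", "A3", "A2", "A3", "A4", "A4", "A4", "A2")
  rep_ <- confusionAndF1(pred, truth, classes = c("A2", "A3", "A4"))
  want <- matrix(c(2, 1, 0,
                   0, 1, 1,
                   1, 0, 2), 3, 3, byrow = TRUE)
  expect_equal(unname(confusionMatrix(rep_)), want)
  expect_equal(rep_@accuracy, 5 / 8)
  # hand F1: A2 P=2/3 R=2/3; A3 P=1/2 R=1/2; A4 P=2/3 R=2/3
  expect_equal(rep_@macroF1, mean(c(2 / 3, 1 / 2, 2 / 3)), tolerance = 1e-12)
  expect_equal(sum(confusionMatrix(rep_)), rep_@nTest)

  perfect <- confusionAndF1(truth, truth)
  expect_equal(perfect@accuracy, 1)
  expect_equal(perfect@macroF1, 1)
  expect_true(all(confusionMatrix(perfect)[upper.tri(want)] == 0))

  allOne <- confusionAndF1(rep("A2", 8), truth, c("A2", "A3", "A4"))
  expect_equal(unname(confusionMatrix(allOne)[, 1]), c(3L, 2L, 3L))
  expect_equal(allOne@accuracy, 3 / 8)
  expect_error(confusionAndF1(character(0), character(0)), "empty")
})

test_that("macro metrics are invariant to class relabeling", {
  set.seed(24)
  truth <- sample(c("A2", "A3", "A4"), 30, replace = TRUE)
  pred <- sample(c("A2", "A3", "A4"), 30, replace = TRUE)
  a <- confusionAndF1(pred, truth, c("A2", "A3", "A4"))
  mapper <- c(A2 = "A4", A3 = "A2", A4 = "A3")
  b <- confusionAndF1(unname(mapper[pred]), unname(mapper[truth]),
                      c("A2", "A3", "A4"))
  expect_equal(a@accuracy, b@accuracy)
  expect_equal(a@macroF1, b@macroF1, tolerance = 1e-12)
})

test_that("paired t-test matches the closed form and handles degeneracy", {
  a <- c(0.92, 0.95, 0.91, 0.93, 0.94)
  b <- a - c(0.02, 0.05, 0.01, 0.03, 0.04)
  res <- pairedTTest(a, b)
  d <- a - b
  tWant <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res@statistic, tWant, tolerance = 1e-12)
  expect_equal(res@df, 4)
  expect_equal(res@pValue, 2 * pt(-abs(tWant), df = 4), tolerance = 1e-12)
  expect_false(res@degenerate)
  expect_gt(res@statistic, 0)

  same <- pairedTTest(a, a)
  expect_equal(same@statistic, 0)
  expect_equal(same@pValue, 1)

  const <- pairedTTest(a, a - 1)
  expect_true(const@degenerate)
  expect_equal(const@pValue, 0)
  expect_error(pairedTTest(a, a[1:3]), "paired")
})

test_that("training curves tabulate and compare runs", {
  h1 <- data.frame(epoch = 1:100, lr = 1e-4, train_loss = exp(-(1:100) / 30),
                   train_acc = seq(0.2, 0.99, length.out = 100),
                   val_loss = exp(-(1:100) / 25),
                   val_acc = seq(0.2, 0.97, length.out = 100))
  expect_equal(nrow(trainingCurves(h1)), 100L)
  expect_equal(nrow(trainingCurves(h1[1, ])), 1L)
  h2 <- h1
  h2$val_acc <- h2$val_acc - 0.05
  cmp <- trainingCurves(h1, h2)
  expect_equal(cmp$val_acc_diff, h1$val_acc - h2$val_acc, tolerance = 1e-12)
  expect_error(trainingCurves(h1[0, ]), "empty")
})
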