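test_that("confusion metrics match formula oracles, with stated conventions", {
  # perfect classifier
  m <- confusionMetrics(tp = 50, fp = 0, tn = 50, fn = 0)
  expect_equal(m$ACR, 100); expect_equal(m$MCC, 1)

  # frozen hand computation
  m2 <- confusionMetrics(tp = 90, fp = 20, tn = 80, fn = 10)
  expect_equal(m2$MCC, 0.70352647, tolerance = 1e-7)
  expect_equal(m2$ACR, 85); expect_equal(m2$SES, 90); expect_equal(m2$SPF, 80)

  # degenerate all-positive predictor: SES 100, MCC 0 by convention
  m3 <- confusionMetrics(tp = 30, fp = 20, tn = 0, fn = 0)
  expect_equal(m3$SES, 100); expect_equal(m3$MCC, 0)

  # undefined rates reported as NA, not 0
  expect_true(is.na(confusionMetrics(tp = 5, fp = 0, tn = 0, fn = 0)$SPF))
  expect_true(is.na(confusionMetrics(tp = 0, fp = 2, tn = 5, fn = 0)$SES))

  # random confusion tables against the independent oracle
  set.seed(77)
  for (i in 1:200) {
    cts <- as.list(sample(0:60, 4, replace = TRUE))
    names(cts) <- c("tp", "fp", "tn", "fn")
    got <- do.call(confusionMetrics, cts)
    expect_equal(got$MCC, do.call(bruteMcc, cts), tolerance = 1e-12)
    n <- sum(unlist(cts))
    if (n > 0) expect_equal(got$ACR, 100 * (cts$tp + cts$tn) / n)
  }
})

test_that("MCC sign symmetry under label/prediction swaps", {
  set.seed(3)
  truth <- sample(c("tumor", "non-tumor"), 80, replace = TRUE)
  pred <- sample(c("tumor", "non-tumor"), 80, replace = TRUE)
  mcc <- evaluationReport(truth, pred)$metrics$MCC
  # swapping classes in BOTH truth and predictions leaves MCC unchanged
  swap <- function(v) ifelse(v == "tumor", "non-tumor", "tumor")
  both <- evaluationReport(swap(truth), swap(pred))$metrics$MCC
  expect_equal(both, mcc, tolerance = 1e-12)
  # swapping only predictions negates it
  only <- evaluationReport(truth, swap(pred))$metrics$MCC
  expect_equal(only, -mcc, tolerance = 1e-12)
})

test_that("AUC equals the concordant-pair oracle, with bootstrap CI", {
  # frozen example: 15 of 16 pairs concordant
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.65, 0.5, 0.4, 0.3)
  labels <- rep(c("tumor", "non-tumor"), each = 4)
  r <- rocCurveAuc(scores, labels, nBoot = 200, seed = 1)
  expect_equal(r$auc, 15 / 16)
  expect_true(r$ciLower <= r$auc && r$auc <= r$ciUpper)

  # perfect ranking
  expect_equal(rocCurveAuc(c(1, 1, 0, 0), labels[c(1, 2, 5, 6)],
                           nBoot = 50)$auc, 1)

  # random scores incl. ties vs the exhaustive pair-count oracle
  set.seed(21)
  for (i in 1:25) {
    n <- sample(4:50, 1)
    lab <- c("tumor", "non-tumor",
             sample(c("tumor", "non-tumor"), n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    got <- rocCurveAuc(sc, lab, nBoot = 10)$auc
    expect_equal(got, bruteAuc(sc, lab), tolerance = 1e-12)
  }

  expect_error(rocCurveAuc(1:3, rep("tumor", 3)), "both classes")
})

test_that("classifier training, prediction and evaluation are coherent", {
  sep <- separableFeatures(60)
  algos <- c("svm_rbf", "decision_tree", "logistic_regression",
             "random_forest", "naive_bayes", "bayes_net")
  for (algo in algos) {
    rep <- evaluateClassifier(classifierSpec(algo), sep$features, sep$labels,
                              sep$features, sep$labels, computeRoc = FALSE)
    expect_equal(rep$metrics$ACR, 100, info = algo)
  }
  # the bayes_net comparator is flagged as structure-free
  repBn <- evaluateClassifier(classifierSpec("bayes_net"), sep$features,
                              sep$labels, sep$features, sep$labels,
                              computeRoc = FALSE)
  expect_match(repBn$note, "structure-free")

  # decision scores are monotone with the predicted class: thresholding
  # the SVM score at 0 reproduces the confusion matrix
  model <- trainClassifier(classifierSpec("svm_rbf"), sep$features, sep$labels)
  pr <- predictClassifier(model, sep$features)
  expect_identical(pr$class, ifelse(pr$score > 0, "tumor", "non-tumor"))

  # single-class test set: only the defined rate is reported
  tumorOnly <- sep$labels == "tumor"
  repT <- evaluateClassifier(classifierSpec("svm_rbf"), sep$features,
                             sep$labels, sep$features[tumorOnly, ],
                             sep$labels[tumorOnly], computeRoc = FALSE)
  expect_equal(repT$metrics$SES, 100)
  expect_true(is.na(repT$metrics$SPF))

  expect_error(evaluateClassifier(classifierSpec(), sep$features, sep$labels,
                                  sep$features[0, ], character()), "empty")
})

test_that("stratified CV pools predictions deterministically", {
  sep <- separableFeatures(40)
  rep1 <- crossValidate(classifierSpec("svm_rbf"), sep$features, sep$labels,
                        kFolds = 5, seed = 11)
  expect_equal(rep1$metrics$ACR, 100)
  rep2 <- crossValidate(classifierSpec("svm_rbf"), sep$features, sep$labels,
                        kFolds = 5, seed = 11)
  expect_identical(rep1$predictions, rep2$predictions)
  expect_identical(rep1$metrics, rep2$metrics)

  # a fold that would lose a class errors with advice
  small <- separableFeatures(6)
  lop <- c(rep("tumor", 5), "non-tumor")
  expect_error(crossValidate(classifierSpec("svm_rbf"), small$features,
                             lop, kFolds = 5, seed = 1), "fewer folds")
})

test_that("permuted labels give near-zero pooled MCC", {
  set.seed(55)
  n <- 60
  feats <- matrix(sample(c(-1, 0, 1), n * 4, replace = TRUE), n, 4)
  mccs <- vapply(1:20, function(s) {
    labs <- sample(rep(c("tumor", "non-tumor"), each = n / 2))
    crossValidate(classifierSpec("svm_rbf"), feats, labs, kFolds = 5,
                  seed = s, computeRoc = FALSE)$metrics$MCC
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("grid search prefers accurate, then smaller, hyperparameters", {
  # the default grids contain the canonical powers of two
  expect_true(32 %in% eval(formals(gridSearchSvm)$cGrid))
  expect_true(0.03125 %in% eval(formals(gridSearchSvm)$gammaGrid))

  sep <- separableFeatures(40)
  spec <- gridSearchSvm(sep$features, sep$labels, cGrid = c(1, 32),
                        gammaGrid = c(0.03125, 1), kFolds = 4, seed = 2)
  expect_equal(attr(spec, "cvAccuracy"), 100)
  grid <- attr(spec, "grid")
  # exhaustive check: the returned point attains the grid maximum and is
  # the smallest (C, gamma) doing so
  best <- grid[grid$accuracy == max(grid$accuracy), ]
  best <- best[order(best$C, best$gamma), ][1, ]
  expect_equal(spec$C, best$C)
  expect_equal(spec$gamma, best$gamma)

  # a singleton grid returns that point
  one <- gridSearchSvm(sep$features, sep$labels, cGrid = 4, gammaGrid = 0.5,
                       kFolds = 4, seed = 2)
  expect_equal(one$C, 4); expect_equal(one$gamma, 0.5)
  expect_error(gridSearchSvm(sep$features, sep$labels, cGrid = numeric()),
               "empty")
})
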