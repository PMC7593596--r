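#' Specify a classifier
#'
#' Light-weight description of one of the supported classification
#' algorithms. `"svm_rbf"` is the workhorse (radial-basis-function kernel
#' support vector machine, fitted by the LibSVM engine via e1071, on the
#' raw ternary codes without rescaling); the others are comparators.
#' `"bayes_net"` is served by a structure-free discrete Bayes classifier
#' (i.e. naive Bayes with independence structure disabled) and the fitted
#' model carries a note saying so.
#'
#' @param algorithm one of `"svm_rbf"`, `"decision_tree"`,
#'   `"logistic_regression"`, `"random_forest"`, `"naive_bayes"`,
#'   `"bayes_net"`.
#' @param C,gamma RBF-SVM hyperparameters (used by `"svm_rbf"` only);
#'   both must be positive. Defaults are the powers of two 2^5 and 2^-5.
#' @param seed seed consumed by stochastic fitters (random forest).
#' @return a `ClassifierSpec` list.
#' @export
classifierSpec <- function(algorithm = c("svm_rbf", "decision_tree",
                                         "logistic_regression", "random_forest",
                                         "naive_bayes", "bayes_net"),
                           C = 32, gamma = 0.03125, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (C <= 0 || gamma <= 0) stop("C and gamma must be positive")
  structure(list(algorithm = algorithm, C = C, gamma = gamma,
                 seed = as.integer(seed)),
            class = "ClassifierSpec")
}

.classFactor <- function(labels, positive = "tumor") {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) > 2L)
    stop("binary classification only; got classes: ",
         paste(lev, collapse = ", "), call. = FALSE)
  negative <- setdiff(lev, positive)
  if (!length(negative)) negative <- ".negative"
  factor(labels, levels = c(negative[1L], positive))
}

.featureFrame <- function(x) {
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  df
}

#' Train a classifier on a ternary feature matrix
#'
#' @param spec a [classifierSpec()].
#' @param x samples x features numeric matrix (REO codes).
#' @param y class labels (`"tumor"`/`"non-tumor"`); both classes required.
#' @param positive label of the positive class; default `"tumor"`.
#' @return fitted model object for [predictClassifier()].
#' @export
trainClassifier <- function(spec, x, y, positive = "tumor") {
  stopifnot(inherits(spec, "ClassifierSpec"))
  x <- as.matrix(x)
  yf <- .classFactor(y, positive)
  if (length(unique(y)) < 2L)
    stop("training labels hold a single class", call. = FALSE)
  df <- .featureFrame(x)
  note <- NULL
  fit <- withSeed(spec$seed, switch(spec$algorithm,
    svm_rbf = e1071::svm(x, yf, kernel = "radial", cost = spec$C,
                         gamma = spec$gamma, scale = FALSE),
    decision_tree = rpart::rpart(.y ~ ., data = cbind(df, .y = yf),
                                 method = "class"),
    logistic_regression = suppressWarnings(
      stats::glm(.y ~ ., data = cbind(df, .y = yf), family = stats::binomial())),
    random_forest = randomForest::randomForest(x, yf),
    naive_bayes = e1071::naiveBayes(df, yf),
    bayes_net = {
      note <- "bayes_net served by a structure-free naive Bayes classifier"
      e1071::naiveBayes(df, yf)
    }
  ))
  structure(list(spec = spec, fit = fit, levels = levels(yf),
                 positive = levels(yf)[2L], nFeatures = ncol(x), note = note),
            class = "ReoClassifier")
}

#' Predict with a trained classifier
#'
#' @param model a fitted model from [trainClassifier()].
#' @param x samples x features matrix with the training feature count.
#' @return list with `class` (character predictions) and `score` (numeric
#'   decision score, monotone with confidence in the positive class; the
#'   0.5 / 0 threshold reproduces `class`).
#' @export
predictClassifier <- function(model, x) {
  stopifnot(inherits(model, "ReoClassifier"))
  x <- as.matrix(x)
  if (ncol(x) != model$nFeatures)
    stop("feature count mismatch: model expects ", model$nFeatures,
         call. = FALSE)
  df <- .featureFrame(x)
  pos <- model$positive
  spec <- model$spec
  if (spec$algorithm == "svm_rbf") {
    pr <- stats::predict(model$fit, x, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # LibSVM labels the column "A/B" with positive values favoring A
    score <- if (startsWith(colnames(dv)[1L], paste0(pos, "/"))) dv[, 1L] else -dv[, 1L]
    cls <- as.character(pr)
  } else {
    prob <- switch(spec$algorithm,
      decision_tree = stats::predict(model$fit, df, type = "prob")[, pos],
      logistic_regression = {
        p <- stats::predict(model$fit, df, type = "response")
        as.numeric(p)   # response models P(second level) = P(positive)
      },
      random_forest = stats::predict(model$fit, x, type = "prob")[, pos],
      naive_bayes = ,
      bayes_net = stats::predict(model$fit, df, type = "raw")[, pos]
    )
    score <- as.numeric(prob)
    cls <- ifelse(score > 0.5, pos, setdiff(model$levels, pos))
  }
  list(class = unname(cls), score = unname(as.numeric(score)))
}

#' Metrics from confusion counts
#'
#' Accuracy, sensitivity and specificity in percent, plus the Matthews
#' correlation coefficient — the primary metric under class imbalance.
#' `SES` is `NA` when there are no positives and `SPF` is `NA` when there
#' are no negatives (an undefined rate is reported as absent, not 0); a
#' zero denominator in the MCC yields 0 by convention.
#'
#' @param tp,fp,tn,fn confusion counts (positive class = tumor).
#' @return list with `ACR`, `SES`, `SPF` (percent) and `MCC`.
#' @examples
#' confusionMetrics(tp = 90, fp = 20, tn = 80, fn = 10)
#' @export
confusionMetrics <- function(tp, fp, tn, fn) {
  n <- tp + fp + tn + fn
  acr <- if (n > 0) 100 * (tp + tn) / n else NA_real_
  ses <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spf <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  denom <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
    sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (denom == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / denom
  list(ACR = acr, SES = ses, SPF = spf, MCC = mcc)
}

#' Build an evaluation report from predictions
#'
#' @param truth true class labels.
#' @param predicted predicted class labels.
#' @param scores optional decision scores (for ROC/AUC).
#' @param positive positive-class label; default `"tumor"`.
#' @param computeRoc compute ROC/AUC with bootstrap CI when scores are
#'   available and both classes occur in `truth`.
#' @param rocSeed seed for the bootstrap CI.
#' @param nBoot bootstrap resamples for the AUC CI.
#' @return list with `counts` (TP/FP/TN/FN), `metrics` (see
#'   [confusionMetrics()]), `predictions` data.frame, and `roc` (or NULL).
#' @export
evaluationReport <- function(truth, predicted, scores = NULL,
                             positive = "tumor", computeRoc = !is.null(scores),
                             rocSeed = 1L, nBoot = 2000L) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  if (!length(truth)) stop("empty evaluation set", call. = FALSE)
  isPos <- truth == positive
  predPos <- predicted == positive
  counts <- list(TP = sum(isPos & predPos), FP = sum(!isPos & predPos),
                 TN = sum(!isPos & !predPos), FN = sum(isPos & !predPos))
  metrics <- confusionMetrics(counts$TP, counts$FP, counts$TN, counts$FN)
  roc <- NULL
  if (computeRoc && !is.null(scores) && length(unique(truth)) == 2L)
    roc <- rocCurveAuc(scores, truth, positive = positive,
                       nBoot = nBoot, seed = rocSeed)
  preds <- data.frame(truth = truth, predicted = predicted,
                      stringsAsFactors = FALSE)
  if (!is.null(scores)) preds$score <- as.numeric(scores)
  structure(list(counts = counts, metrics = metrics,
                 predictions = preds, roc = roc),
            class = "ReoEvaluationReport")
}

#' @export
print.ReoEvaluationReport <- function(x, ...) {
  with(x$counts, cat(sprintf("Confusion: TP=%d FP=%d TN=%d FN=%d\n",
                             TP, FP, TN, FN)))
  m <- x$metrics
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  cat(sprintf("ACR=%s%% SES=%s%% SPF=%s%% MCC=%s\n",
              fmt(m$ACR), fmt(m$SES), fmt(m$SPF),
              if (is.na(m$MCC)) "NA" else sprintf("%.4f", m$MCC)))
  if (!is.null(x$roc))
    cat(sprintf("AUC=%.4f (95%% CI %.4f-%.4f)\n",
                x$roc$auc, x$roc$ciLower, x$roc$ciUpper))
  invisible(x)
}

#' Train on one set, evaluate on another
#'
#' @param spec a [classifierSpec()].
#' @param trainX,trainY training features and labels (both classes needed).
#' @param testX,testY test features and labels; a single-class test set is
#'   allowed (the undefined rate comes back `NA`).
#' @param ... passed to [evaluationReport()].
#' @return a [evaluationReport()] on the test set.
#' @export
evaluateClassifier <- function(spec, trainX, trainY, testX, testY, ...) {
  if (!length(testY)) stop("test set is empty", call. = FALSE)
  model <- trainClassifier(spec, trainX, trainY)
  pr <- predictClassifier(model, testX)
  rep <- evaluationReport(testY, pr$class, pr$score, ...)
  rep$classifier <- model$spec$algorithm
  if (!is.null(model$note)) rep$note <- model$note
  rep
}

#' Stratified cross-validation with pooled predictions
#'
#' Assigns samples to stratified folds, fits on each training split,
#' predicts the held-out fold, pools all held-out predictions and computes
#' one report — the convention that turns k-fold CV into a single set of
#' training metrics.
#'
#' @param spec a [classifierSpec()].
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param kFolds number of folds (>= 2); default 5.
#' @param seed fold-assignment seed; the result is deterministic given it.
#' @param computeRoc compute pooled ROC/AUC.
#' @return a [evaluationReport()] over the pooled held-out predictions.
#' @export
crossValidate <- function(spec, features, labels, kFolds = 5L, seed = 1L,
                          computeRoc = TRUE) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(length(labels) == n)
  fold <- makeStratifiedFolds(labels, kFolds, seed)
  predicted <- character(n)
  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    trIdx <- which(fold != f)
    teIdx <- which(fold == f)
    if (length(unique(labels[trIdx])) < 2L)
      stop("a training fold holds a single class; use fewer folds",
           call. = FALSE)
    model <- trainClassifier(spec, features[trIdx, , drop = FALSE], labels[trIdx])
    pr <- predictClassifier(model, features[teIdx, , drop = FALSE])
    predicted[teIdx] <- pr$class
    scores[teIdx] <- pr$score
  }
  rep <- evaluationReport(labels, predicted, scores, computeRoc = computeRoc,
                          rocSeed = seed)
  rep$classifier <- spec$algorithm
  rep$kFolds <- as.integer(kFolds)
  rep$seed <- as.integer(seed)
  rep
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Exhaustive search over a (C, gamma) grid scored by pooled k-fold CV
#' accuracy. Defaults are the customary powers-of-two grids
#' C in 2^-5..2^15 and gamma in 2^-15..2^3. Ties prefer the smaller C,
#' then the smaller gamma.
#'
#' @param features samples x features matrix.
#' @param labels class labels.
#' @param cGrid,gammaGrid candidate values (nonempty, positive).
#' @param kFolds CV folds; default 5.
#' @param seed fold seed.
#' @return the winning [classifierSpec()], with attributes `cvAccuracy`
#'   and `grid` (the full accuracy table).
#' @export
gridSearchSvm <- function(features, labels,
                          cGrid = 2^(-5:15), gammaGrid = 2^(-15:3),
                          kFolds = 5L, seed = 1L) {
  if (!length(cGrid) || !length(gammaGrid))
    stop("empty hyperparameter grid", call. = FALSE)
  cGrid <- sort(cGrid)
  gammaGrid <- sort(gammaGrid)
  best <- NULL
  bestAcc <- -Inf
  tab <- expand.grid(C = cGrid, gamma = gammaGrid)
  tab <- tab[order(tab$C, tab$gamma), ]
  tab$accuracy <- NA_real_
  for (r in seq_len(nrow(tab))) {
    spec <- classifierSpec("svm_rbf", C = tab$C[r], gamma = tab$gamma[r],
                           seed = seed)
    rep <- crossValidate(spec, features, labels, kFolds = kFolds,
                         seed = seed, computeRoc = FALSE)
    tab$accuracy[r] <- rep$metrics$ACR
    if (tab$accuracy[r] > bestAcc) {   # strict: earlier (smaller C, gamma) wins ties
      bestAcc <- tab$accuracy[r]
      best <- spec
    }
  }
  attr(best, "cvAccuracy") <- bestAcc
  attr(best, "grid") <- tab
  best
}

#' ROC curve, AUC and bootstrap confidence interval
#'
#' Standard ROC over decision-score thresholds; the trapezoid AUC equals
#' the normalized Mann-Whitney concordant-pair count (ties counted 1/2).
#' The 95% CI comes from a stratified bootstrap (resampling positives and
#' negatives separately), seeded for reproducibility.
#'
#' @param scores numeric decision scores, higher = more positive.
#' @param labels class labels; both classes must be present.
#' @param positive positive-class label; default `"tumor"`.
#' @param nBoot bootstrap resamples; default 2000.
#' @param seed bootstrap seed.
#' @return list with `points` (data.frame `fpr`, `tpr`, `threshold`),
#'   `auc`, `ciLower`, `ciUpper`, `nBoot`.
#' @export
rocCurveAuc <- function(scores, labels, positive = "tumor",
                        nBoot = 2000L, seed = 1L) {
  labels <- as.character(labels)
  if (length(unique(labels)) != 2L)
    stop("ROC needs both classes present", call. = FALSE)
  negative <- setdiff(unique(labels), positive)[1L]
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(negative, positive), direction = "<",
                 quiet = TRUE)
  ci <- withSeed(seed, suppressWarnings(
    pROC::ci.auc(r, method = "bootstrap", boot.n = nBoot,
                 boot.stratified = TRUE)))
  pts <- data.frame(fpr = rev(1 - r$specificities),
                    tpr = rev(r$sensitivities),
                    threshold = rev(r$thresholds))
  list(points = pts, auc = as.numeric(pROC::auc(r)),
       ciLower = as.numeric(ci[1L]), ciUpper = as.numeric(ci[3L]),
       nBoot = as.integer(nBoot))
}
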