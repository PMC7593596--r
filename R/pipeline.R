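# Undefined rates (single-class cohorts) are absent from JSON reports,
# not serialized as "NA".
.definedMetrics <- function(m) m[!vapply(m, is.na, logical(1L))]

#' Run reversal-signature discovery end to end
#'
#' Executes the full discovery workflow on a training cohort: stable-pair
#' detection per subgroup, per-class intersection (consistent stable
#' pairs), reversal-pair extraction, ternary encoding, mRMR ranking,
#' incremental feature selection under a cross-validated classifier, and
#' final model training on the optimal prefix. Artifacts are written to
#' `outDir`: `signature.json` (the optimal-k signature in rank order),
#' `ranked_pairs.tsv`, `ifs_curve.tsv`, `training_report.json` and
#' `manifest.json`. The manifest records seeds, thresholds, group sizes
#' and all intermediate pair counts, and contains no timestamps — two
#' runs with the same inputs and seeds produce byte-identical artifacts.
#'
#' Finding zero reversal pairs is reported (manifest with
#' `nReversalPairs = 0`), not an error.
#'
#' @param exprs genes x samples matrix (or a path readable by
#'   [readExpressionMatrix()]).
#' @param labels data.frame `sample_id`/`group`/`class` (or a path for
#'   [readSampleLabels()]).
#' @param outDir output directory (created if needed).
#' @param threshold REO stability threshold; default 0.85.
#' @param classifier a [classifierSpec()], or `"auto"` to grid-search
#'   RBF-SVM hyperparameters on the full candidate feature set first.
#' @param kFolds cross-validation folds; default 5.
#' @param seed seed for folds / grid search / stochastic fitters.
#' @param maxK largest IFS prefix; default all candidates.
#' @param cGrid,gammaGrid grids for `classifier = "auto"`.
#' @return (invisibly) list with `signature`, `ranked`, `ifs`, `model`,
#'   `trainingReport`, `manifest` and `paths`.
#' @export
runDiscovery <- function(exprs, labels, outDir,
                         threshold = 0.85,
                         classifier = classifierSpec("svm_rbf"),
                         kFolds = 5L, seed = 1L, maxK = Inf,
                         cGrid = 2^(-5:15), gammaGrid = 2^(-15:3)) {
  if (is.character(exprs) && length(exprs) == 1L)
    exprs <- readExpressionMatrix(exprs)
  if (is.character(labels) && length(labels) == 1L)
    labels <- readSampleLabels(labels)
  .assertExpressionMatrix(exprs)
  labels <- labels[match(colnames(exprs), labels$sample_id), , drop = FALSE]
  if (anyNA(labels$sample_id))
    stop("labels missing for some samples in the matrix", call. = FALSE)
  if (length(unique(labels$class)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  # stable pairs per subgroup, then per-class intersection
  classOf <- split(unique(labels$group),
                   labels$class[match(unique(labels$group), labels$group)])
  stableCounts <- list()
  classSets <- list()
  for (cl in c("tumor", "non-tumor")) {
    groups <- classOf[[cl]]
    if (is.null(groups) || !length(groups))
      stop("class '", cl, "' has no groups", call. = FALSE)
    sets <- lapply(groups, function(g) {
      ids <- labels$sample_id[labels$group == g]
      computeStablePairs(exprs, samples = ids, threshold = threshold,
                         group = g)
    })
    for (s in sets) stableCounts[[groupLabel(s)]] <- length(s)
    classSets[[cl]] <- if (length(sets) > 1L)
      intersectStablePairs(sets, group = cl) else sets[[1L]]
  }
  signature <- findReversalPairs(classSets[["tumor"]], classSets[["non-tumor"]])

  manifest <- list(
    package = "REOsig",
    version = as.character(utils::packageVersion("REOsig")),
    seed = as.integer(seed),
    threshold = threshold,
    kFolds = as.integer(kFolds),
    nGenes = nrow(exprs),
    nSamples = ncol(exprs),
    groupSizes = as.list(table(labels$group)),
    stablePairCounts = stableCounts,
    consistentStablePairs = list(
      tumor = length(classSets[["tumor"]]),
      `non-tumor` = length(classSets[["non-tumor"]])),
    nReversalPairs = length(signature))
  paths <- list(manifest = file.path(outDir, "manifest.json"))

  if (!length(signature)) {
    message("no reversal pairs found at threshold ", threshold)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(list(signature = signature, ranked = NULL, ifs = NULL,
                          model = NULL, trainingReport = NULL,
                          manifest = manifest, paths = paths)))
  }

  features <- encodeReoFeatures(exprs, signature)
  if (identical(classifier, "auto")) {
    classifier <- gridSearchSvm(features, labels$class, cGrid = cGrid,
                                gammaGrid = gammaGrid, kFolds = kFolds,
                                seed = seed)
    manifest$gridSearch <- list(C = classifier$C, gamma = classifier$gamma,
                                cvAccuracy = attr(classifier, "cvAccuracy"))
  }
  ranked <- mrmrRank(features, labels$class)
  ifs <- ifsSelect(ranked, features, labels$class, classifier = classifier,
                   kFolds = kFolds, seed = seed,
                   maxK = min(maxK, nrow(ranked)))
  optIdx <- ranked$index[seq_len(ifs$optimalK)]
  sigPairs <- pairTable(signature)[optIdx, , drop = FALSE]
  sigPairs$rank <- seq_len(nrow(sigPairs))
  finalSignature <- ReversalSignature(sigPairs)
  model <- trainClassifier(classifier, features[, optIdx, drop = FALSE],
                           labels$class)
  trainingReport <- ifs$reports[[ifs$optimalK]]

  manifest$classifier <- list(algorithm = classifier$algorithm,
                              C = classifier$C, gamma = classifier$gamma)
  manifest$optimalK <- ifs$optimalK
  manifest$trainingMetrics <- trainingReport$metrics

  paths$signature <- file.path(outDir, "signature.json")
  paths$ranked <- file.path(outDir, "ranked_pairs.tsv")
  paths$ifsCurve <- file.path(outDir, "ifs_curve.tsv")
  paths$trainingReport <- file.path(outDir, "training_report.json")
  writeSignature(finalSignature, paths$signature)
  utils::write.table(
    cbind(ranked["rank"],
          pairTable(signature)[ranked$index, c("geneI", "geneJ")],
          ranked[c("score", "relevance")]),
    paths$ranked, sep = "\t", quote = FALSE, row.names = FALSE)
  writeIfsCurve(ifs, paths$ifsCurve)
  jsonlite::write_json(list(counts = trainingReport$counts,
                            metrics = .definedMetrics(trainingReport$metrics)),
                       paths$trainingReport, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(signature = finalSignature, ranked = ranked, ifs = ifs,
                 model = model, trainingReport = trainingReport,
                 manifest = manifest, paths = paths))
}

#' Apply a discovered signature to a new cohort
#'
#' Encodes a (possibly cross-platform) expression matrix against a
#' signature — genes absent from the matrix encode as -1 — and predicts
#' with a trained model. With labels for both classes the full metric set
#' and ROC/AUC are reported; with a single-class cohort only the defined
#' rate (sensitivity for all-tumor cohorts) is reported, the other coming
#' back `NA`. If no signature pair is computable (every feature -1) the
#' report is written but flagged.
#'
#' @param signature a [ReversalSignature-class] or path to a signature
#'   JSON.
#' @param exprs genes x samples matrix or path.
#' @param model a trained model from [trainClassifier()] /
#'   [runDiscovery()], or a [classifierSpec()] together with
#'   `trainFeatures`/`trainLabels` to fit on the spot.
#' @param labels optional data.frame or path; when `NULL` only
#'   predictions are written.
#' @param outDir output directory; `report.json` (plus `roc_points.tsv`
#'   when ROC is defined) is written there.
#' @param trainFeatures,trainLabels training data, used only when `model`
#'   is a [classifierSpec()].
#' @return (invisibly) the evaluation report (or prediction list when no
#'   labels were given) with `$features` attached.
#' @export
runApply <- function(signature, exprs, model, labels = NULL, outDir,
                     trainFeatures = NULL, trainLabels = NULL) {
  if (is.character(signature) && length(signature) == 1L)
    signature <- readSignature(signature)
  if (is.character(exprs) && length(exprs) == 1L)
    exprs <- readExpressionMatrix(exprs)
  if (is.character(labels) && length(labels) == 1L)
    labels <- readSampleLabels(labels)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  features <- encodeReoFeatures(exprs, signature)
  flagged <- all(features == -1L)
  if (flagged)
    warning("no signature pair computable on this matrix; all features are -1")
  if (inherits(model, "ClassifierSpec")) {
    if (is.null(trainFeatures) || is.null(trainLabels))
      stop("a ClassifierSpec needs trainFeatures and trainLabels",
           call. = FALSE)
    model <- trainClassifier(model, trainFeatures, trainLabels)
  }
  pr <- predictClassifier(model, features)
  if (is.null(labels)) {
    out <- list(predictions = data.frame(sample_id = rownames(features),
                                         predicted = pr$class,
                                         score = pr$score,
                                         stringsAsFactors = FALSE),
                allFeaturesMissing = flagged)
    jsonlite::write_json(out, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$features <- features
    return(invisible(out))
  }
  labels <- labels[match(rownames(features), labels$sample_id), , drop = FALSE]
  rep <- evaluationReport(labels$class, pr$class, pr$score)
  rep$allFeaturesMissing <- flagged
  jsonlite::write_json(list(counts = rep$counts,
                            metrics = .definedMetrics(rep$metrics),
                            auc = if (!is.null(rep$roc))
                              list(value = rep$roc$auc,
                                   ciLower = rep$roc$ciLower,
                                   ciUpper = rep$roc$ciUpper),
                            allFeaturesMissing = flagged),
                       file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(rep$roc))
    utils::write.table(rep$roc$points, file.path(outDir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  rep$features <- features
  invisible(rep)
}
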