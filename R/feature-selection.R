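#' Plug-in mutual information between discrete vectors
#'
#' Empirical mutual information in nats over the observed joint table:
#' `MI = sum p(a,b) * ln(p(a,b) / (p(a) p(b)))`, with `0 ln 0 = 0`. The
#' ternary REO codes \{0, 1, -1\} and binary class labels are both finite
#' alphabets, so the plug-in estimator is exact for this pipeline; the -1
#' code is an ordinary third symbol, not missing data.
#'
#' @param x,y equal-length vectors over finite alphabets.
#' @return non-negative mutual information in nats (symmetric in x, y).
#' @examples
#' v <- rep(c(0, 1), 50)
#' mutualInformation(v, v)  # = H(v) = ln 2
#' @export
mutualInformation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("empty vectors")
  n <- length(x)
  joint <- table(x, y) / n
  px <- rowSums(joint)
  py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

# Empirical entropy in nats (internal; used for MI bounds and tests).
discreteEntropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log(p[p > 0]))
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Greedy forward selection under the difference (MID) form of the mRMR
#' criterion: the first feature maximizes its mutual information with the
#' class (relevance); each subsequent feature maximizes
#' `MI(v, C) - mean(MI(v, s) for s already selected)` — relevance
#' penalized by mean redundancy with the selected set. Exact ties are
#' broken by original column order, so the ranking is deterministic.
#'
#' @param features samples x features matrix of discrete codes (e.g. the
#'   ternary REO profile from [encodeReoFeatures()]).
#' @param labels class vector, one entry per sample; at least two classes.
#' @param nSelect number of features to rank; default all.
#' @return data.frame with one row per selected feature in rank order:
#'   `rank`, `index` (original column), `feature` (column name), `score`
#'   (mRMR objective at selection time) and `relevance` (`MI(v, C)`).
#' @export
mrmrRank <- function(features, labels, nSelect = ncol(features)) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels))
    stop("labels length must match the number of rows (samples)")
  if (length(unique(labels)) < 2L)
    stop("labels hold a single class; mRMR needs at least two", call. = FALSE)
  m <- ncol(features)
  nSelect <- min(nSelect, m)
  if (nSelect < 1L) stop("nSelect must be at least 1")
  relevance <- vapply(seq_len(m),
                      function(j) mutualInformation(features[, j], labels),
                      numeric(1L))
  selected <- integer(0)
  scores <- numeric(0)
  # pairwise MI with already-selected features, filled lazily
  redundancy <- matrix(NA_real_, m, m)
  for (step in seq_len(nSelect)) {
    remaining <- setdiff(seq_len(m), selected)
    if (step == 1L) {
      obj <- relevance[remaining]
    } else {
      for (s in selected) {
        todo <- remaining[is.na(redundancy[remaining, s])]
        for (j in todo) {
          v <- mutualInformation(features[, j], features[, s])
          redundancy[j, s] <- v
          redundancy[s, j] <- v
        }
      }
      obj <- relevance[remaining] -
        rowMeans(redundancy[remaining, selected, drop = FALSE])
    }
    pick <- remaining[which.max(obj)]   # which.max: first max = original order
    selected <- c(selected, pick)
    scores <- c(scores, max(obj))
  }
  data.frame(rank = seq_along(selected), index = selected,
             feature = colnames(features)[selected],
             score = scores, relevance = relevance[selected],
             stringsAsFactors = FALSE)
}

#' Incremental feature selection over a ranked list
#'
#' Evaluates nested prefixes of the mRMR-ranked feature list: for each
#' k = 1..K the classifier is assessed by stratified k-fold
#' cross-validation (default fivefold) on the top-k features, and the
#' optimal k is the one maximizing pooled CV accuracy, ties broken toward
#' the smaller (more parsimonious) k. The full metric set — accuracy,
#' sensitivity, specificity and MCC — is recorded per k, so the signature
#' can also be judged on MCC under class imbalance.
#'
#' @param ranked ranking from [mrmrRank()] (or any data.frame with an
#'   `index` column in rank order).
#' @param features samples x features matrix the ranking refers to.
#' @param labels class vector (`"tumor"`/`"non-tumor"`).
#' @param classifier a [classifierSpec()]; default RBF-kernel SVM.
#' @param kFolds folds for cross-validation; default 5.
#' @param seed fold-assignment seed, recorded in the result.
#' @param maxK largest prefix to evaluate; default all ranked features.
#' @return list with `curve` (data.frame k/ACR/SES/SPF/MCC), `optimalK`,
#'   `optimalMetrics` (the curve row at `optimalK`), `reports` (full
#'   [crossValidate()] report per k) and `seed`.
#' @export
ifsSelect <- function(ranked, features, labels,
                      classifier = classifierSpec("svm_rbf"),
                      kFolds = 5L, seed = 1L, maxK = nrow(ranked)) {
  if (!nrow(ranked)) stop("ranked feature list is empty", call. = FALSE)
  if (kFolds < 2L) stop("kFolds must be >= 2", call. = FALSE)
  maxK <- min(maxK, nrow(ranked))
  reports <- vector("list", maxK)
  curve <- data.frame(k = seq_len(maxK), ACR = NA_real_, SES = NA_real_,
                      SPF = NA_real_, MCC = NA_real_)
  for (k in seq_len(maxK)) {
    idx <- ranked$index[seq_len(k)]
    rep <- crossValidate(classifier, features[, idx, drop = FALSE], labels,
                         kFolds = kFolds, seed = seed, computeRoc = FALSE)
    reports[[k]] <- rep
    curve$ACR[k] <- rep$metrics$ACR
    curve$SES[k] <- rep$metrics$SES
    curve$SPF[k] <- rep$metrics$SPF
    curve$MCC[k] <- rep$metrics$MCC
  }
  optimalK <- which.max(curve$ACR)   # first max = smallest k on ties
  list(curve = curve, optimalK = optimalK,
       optimalMetrics = curve[optimalK, , drop = FALSE],
       reports = reports, seed = as.integer(seed))
}

#' Export an IFS curve as TSV
#'
#' @param ifs result of [ifsSelect()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeIfsCurve <- function(ifs, path) {
  utils::write.table(ifs$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
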