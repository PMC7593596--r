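#' Configuration for the synthetic expression generator
#'
#' Describes a synthetic cohort with the statistical structure the REO
#' pipeline assumes: four sample groups (two per class), a small set of
#' planted reversal pairs whose within-class ordering holds in a
#' controlled fraction of samples, background gene pairs that are stable
#' with the SAME direction in both classes, a large remainder of
#' non-informative genes, and an optional per-sample strictly increasing
#' "platform" distortion. Default group sizes (80/20/8/40) scale down the
#' tumor / tumor-adjacent / pancreatitis / normal imbalance of typical
#' PDAC compendia — the imbalance that motivates MCC as the primary
#' metric.
#'
#' @param nGenes total genes; default 500.
#' @param groupSizes named integer vector of samples per group; names must
#'   be covered by `classMap`; each at least 2.
#' @param nReversalPairs planted reversal pairs; default 16.
#' @param reversalStability fraction of samples per group respecting the
#'   class ordering, in (0.85, 1]; default 0.95. Enforced by construction
#'   (exactly `ceiling(stability * n)` conforming samples per group), so
#'   recovery tests are exact rather than stochastic.
#' @param nConsistentStablePairs background pairs stable with the same
#'   direction in both classes; default 30.
#' @param nRedundantPairs how many of the planted reversal pairs duplicate
#'   the sample-wise ordering pattern of an earlier planted pair (feature
#'   redundancy for selection tests); default 0.
#' @param noiseSd i.i.d. Gaussian noise on non-planted genes; default 0.3.
#' @param batchDistortion per-sample strictly increasing transform applied
#'   last: `"none"`, `"affine"` (a x + b, a > 0) or
#'   `"monotone-nonlinear"` (signed power law).
#' @param seed integer seed; generation is fully deterministic given it.
#' @param classMap named vector mapping group to `"tumor"`/`"non-tumor"`.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(nGenes = 500L,
                        groupSizes = c(PDAC = 80L, PDAC_adjacent = 20L,
                                       pancreatitis = 8L, normal = 40L),
                        nReversalPairs = 16L,
                        reversalStability = 0.95,
                        nConsistentStablePairs = 30L,
                        nRedundantPairs = 0L,
                        noiseSd = 0.3,
                        batchDistortion = c("none", "affine",
                                            "monotone-nonlinear"),
                        seed = 1L,
                        classMap = defaultClassMap()) {
  batchDistortion <- match.arg(batchDistortion)
  if (is.null(names(groupSizes)) || anyDuplicated(names(groupSizes)))
    stop("groupSizes must have unique group names")
  if (any(groupSizes < 2L)) stop("every group needs at least 2 samples")
  unknown <- setdiff(names(groupSizes), names(classMap))
  if (length(unknown))
    stop("no class mapping for group(s): ", paste(unknown, collapse = ", "))
  if (reversalStability <= 0.85 || reversalStability > 1)
    stop("reversalStability must lie in (0.85, 1]")
  if (nRedundantPairs >= nReversalPairs && nRedundantPairs > 0L)
    stop("nRedundantPairs must be smaller than nReversalPairs")
  if (2L * (nReversalPairs + nConsistentStablePairs) > nGenes)
    stop("nGenes too small for the requested planted pairs")
  structure(list(nGenes = as.integer(nGenes),
                 groupSizes = groupSizes,
                 nReversalPairs = as.integer(nReversalPairs),
                 reversalStability = reversalStability,
                 nConsistentStablePairs = as.integer(nConsistentStablePairs),
                 nRedundantPairs = as.integer(nRedundantPairs),
                 noiseSd = noiseSd,
                 batchDistortion = batchDistortion,
                 seed = as.integer(seed),
                 classMap = classMap),
            class = "SynthConfig")
}

# Bounded jitter keeps planted-pair values at least 1.5*d apart, so the
# planted ordering can never tie and realized supports are exact.
.pairValues <- function(m, d, greaterFirst) {
  hi <- m + d * (0.75 + 0.5 * stats::runif(length(greaterFirst)))
  lo <- m - d * (0.75 + 0.5 * stats::runif(length(greaterFirst)))
  list(vI = ifelse(greaterFirst, hi, lo), vJ = ifelse(greaterFirst, lo, hi))
}

# Gaussian noise truncated at +/- 4 sd: background genes can then never
# wander into a planted pair's reserved value band, which keeps the
# planted reversal pairs the ONLY reversal pairs in the data.
.truncNorm <- function(n, sd) pmin(pmax(stats::rnorm(n, 0, sd), -4 * sd), 4 * sd)

# Materialize a cohort from a planted model: shared by the discovery
# generator and the cross-platform test-set generator. Must run inside
# withSeed().
.materializeSamples <- function(model, groupSizes, sampleTag = "") {
  cfg <- model$config
  genes <- model$genes
  groups <- names(groupSizes)
  sampleIds <- unlist(lapply(groups, function(g)
    sprintf("%s%s_%03d", sampleTag, g, seq_len(groupSizes[[g]]))),
    use.names = FALSE)
  sampleGroup <- rep(groups, groupSizes)
  labels <- data.frame(sample_id = sampleIds, group = sampleGroup,
                       class = unname(cfg$classMap[sampleGroup]),
                       stringsAsFactors = FALSE)
  n <- length(sampleIds)
  x <- matrix(NA_real_, nrow = length(genes), ncol = n,
              dimnames = list(genes, sampleIds))

  free <- model$freeGenes
  x[free, ] <- model$baselines[free] +
    matrix(.truncNorm(length(free) * n, cfg$noiseSd), length(free), n)

  # conforming / violating samples per group, per informative pattern;
  # redundant pairs reuse the pattern of the pair they copy
  stability <- cfg$reversalStability
  violSets <- list()
  patternViolators <- function(patternId) {
    if (is.null(violSets[[patternId]])) {
      v <- logical(n)
      for (g in groups) {
        idx <- which(sampleGroup == g)
        nViol <- length(idx) - ceiling(stability * length(idx))
        if (nViol > 0) v[sample(idx, nViol)] <- TRUE
      }
      violSets[[patternId]] <<- v
    }
    violSets[[patternId]]
  }

  isTumor <- labels$class == "tumor"
  supports <- NULL
  for (pm in model$pairModels) {
    viol <- if (pm$classDependent) patternViolators(pm$pattern) else
      rep(FALSE, n)
    wantGreater <- if (pm$classDependent) {
      ifelse(isTumor, pm$tumorDirection == "greater",
             pm$tumorDirection != "greater")
    } else rep(pm$tumorDirection == "greater", n)
    wantGreater <- xor(wantGreater, viol)
    vals <- .pairValues(pm$m, pm$d, wantGreater)
    x[pm$geneI, ] <- vals$vI
    x[pm$geneJ, ] <- vals$vJ
    if (pm$classDependent) {
      sup <- vapply(groups, function(g) {
        idx <- sampleGroup == g
        ng <- sum(idx)
        ceiling(stability * ng) / ng
      }, numeric(1L))
      supports <- rbind(supports,
                        data.frame(geneI = pm$geneI, geneJ = pm$geneJ,
                                   group = groups, support = sup,
                                   stringsAsFactors = FALSE))
    }
  }
  list(exprs = x, labels = labels, supports = supports)
}

.applyDistortion <- function(x, kind, aRange = c(0.5, 2), bRange = c(0, 5),
                             pRange = c(1.2, 2.5)) {
  if (kind == "none") return(x)
  n <- ncol(x)
  a <- stats::runif(n, aRange[1L], aRange[2L])
  b <- stats::runif(n, bRange[1L], bRange[2L])
  if (kind == "affine")
    return(sweep(sweep(x, 2L, a, `*`), 2L, b, `+`))
  p <- stats::runif(n, pRange[1L], pRange[2L])
  for (s in seq_len(n))   # signed power law: strictly increasing on all of R
    x[, s] <- a[s] * sign(x[, s]) * abs(x[, s])^p[s] + b[s]
  x
}

#' Generate a synthetic expression cohort with planted reversal pairs
#'
#' Draws heavy-right-tailed (log-normal) baseline levels for background
#' genes — only the ranks matter to REO methods, so the marginal law is
#' otherwise immaterial — then plants `nReversalPairs` gene pairs whose
#' within-pair ordering follows a class-dependent direction in exactly
#' `ceiling(stability * n)` samples of every group, plants
#' class-independent consistent stable pairs, adds truncated i.i.d. noise
#' to the background genes and finally applies the configured per-sample
#' strictly increasing distortion. Each planted pair occupies a value
#' band disjoint from the background range and from every other pair's
#' band, so the planted reversal pairs are exactly the reversal pairs
#' present in the data and recovery tests are exact.
#'
#' @param config a [synthConfig()].
#' @return list with `exprs` (genes x samples matrix), `labels`
#'   (data.frame `sample_id`/`group`/`class`) and `truth` — a `SynthTruth`
#'   list holding the planted [ReversalSignature-class] (`signature`),
#'   the background consistent pairs (`backgroundPairs`), the realized
#'   per-group supports (`supports`) and the generative model reused by
#'   [generateCrossplatformTestset()].
#' @examples
#' d <- generateDataset(synthConfig(nGenes = 60, nReversalPairs = 3,
#'                                  nConsistentStablePairs = 3, seed = 7))
#' dim(d$exprs)
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  withSeed(config$seed, {
    genes <- sprintf("G%05d", seq_len(config$nGenes))
    nPlanted <- 2L * (config$nReversalPairs + config$nConsistentStablePairs)
    plantedIdx <- sample(config$nGenes, nPlanted)
    freeGenes <- genes[-plantedIdx]
    baselines <- stats::setNames(rep(NA_real_, length(genes)), genes)
    baselines[freeGenes] <- stats::rlnorm(length(freeGenes),
                                          meanlog = 2, sdlog = 0.7)
    # Every planted pair lives in its own value band, disjoint from the
    # background range and from every other band: within-pair order can
    # flip with class while all cross-band orderings stay constant, so
    # the planted reversal pairs are exactly the reversal pairs present.
    dBase <- max(1, 4 * config$noiseSd)
    halfWidth <- 1.25 * 2 * dBase
    marginGap <- 1 + 4 * config$noiseSd
    bandFloor <- max(baselines[freeGenes], 0) + marginGap
    nPairs <- config$nReversalPairs + config$nConsistentStablePairs
    centers <- bandFloor + halfWidth +
      (seq_len(nPairs) - 1L) * (2 * halfWidth + marginGap)
    nInf <- config$nReversalPairs - config$nRedundantPairs
    pairModels <- list()
    take <- function(k) plantedIdx[(2L * k - 1L):(2L * k)]
    for (k in seq_len(config$nReversalPairs)) {
      gs <- canonicalSort(genes[take(k)])
      pattern <- if (k <= nInf) k else ((k - nInf - 1L) %% nInf) + 1L
      pairModels[[k]] <- list(
        geneI = gs[1L], geneJ = gs[2L],
        tumorDirection = sample(.DIRECTIONS, 1L),
        m = centers[k],
        d = dBase * stats::runif(1L, 1, 2),
        classDependent = TRUE,
        pattern = paste0("p", pattern))
    }
    for (k in seq_len(config$nConsistentStablePairs)) {
      gs <- canonicalSort(genes[take(config$nReversalPairs + k)])
      pairModels[[config$nReversalPairs + k]] <- list(
        geneI = gs[1L], geneJ = gs[2L],
        tumorDirection = sample(.DIRECTIONS, 1L),
        m = centers[config$nReversalPairs + k],
        d = dBase * stats::runif(1L, 1, 2),
        classDependent = FALSE,
        pattern = NA_character_)
    }
    model <- list(config = config, genes = genes, freeGenes = freeGenes,
                  baselines = baselines, pairModels = pairModels)

    mat <- .materializeSamples(model, config$groupSizes)
    exprs <- .applyDistortion(mat$exprs, config$batchDistortion)

    rev <- pairModels[seq_len(config$nReversalPairs)]
    sigDf <- data.frame(
      geneI = vapply(rev, `[[`, character(1L), "geneI"),
      geneJ = vapply(rev, `[[`, character(1L), "geneJ"),
      tumorDirection = vapply(rev, `[[`, character(1L), "tumorDirection"),
      stringsAsFactors = FALSE)
    sigDf$controlDirection <- .oppositeDirection(sigDf$tumorDirection)
    sigDf <- sigDf[order(sigDf$geneI, sigDf$geneJ, method = "radix"), ]
    bg <- pairModels[config$nReversalPairs + seq_len(config$nConsistentStablePairs)]
    bgDf <- data.frame(
      geneI = vapply(bg, `[[`, character(1L), "geneI"),
      geneJ = vapply(bg, `[[`, character(1L), "geneJ"),
      direction = vapply(bg, `[[`, character(1L), "tumorDirection"),
      stringsAsFactors = FALSE)
    truth <- structure(list(signature = ReversalSignature(sigDf),
                            backgroundPairs = bgDf,
                            supports = mat$supports,
                            model = model),
                       class = "SynthTruth")
    list(exprs = exprs, labels = mat$labels, truth = truth)
  })
}

#' Generate a cross-platform test cohort from planted truth
#'
#' Draws new samples from the same planted model but under a different
#' monotone distortion family and dynamic range (an RNA-seq-like rescaling
#' of microarray-like values), optionally removing a fraction of
#' non-signature genes and/or named signature genes — removed signature
#' genes exercise the -1 missing-gene code at encoding time.
#'
#' @param truth the `SynthTruth` from [generateDataset()].
#' @param groupSizes named group sizes of the new cohort; default the
#'   discovery configuration's sizes.
#' @param dropGenes fraction of non-signature genes removed, in `[0, 1]`.
#' @param dropSignatureGenes character vector of signature genes to remove
#'   explicitly (warns, rather than errors, if that empties every pair).
#' @param seed integer seed for the new cohort.
#' @return list with `exprs` and `labels` as in [generateDataset()].
#' @export
generateCrossplatformTestset <- function(truth, groupSizes = NULL,
                                         dropGenes = 0,
                                         dropSignatureGenes = character(),
                                         seed = 1L) {
  stopifnot(inherits(truth, "SynthTruth"))
  if (dropGenes < 0 || dropGenes > 1) stop("dropGenes must lie in [0, 1]")
  model <- truth$model
  if (is.null(groupSizes)) groupSizes <- model$config$groupSizes
  withSeed(seed, {
    mat <- .materializeSamples(model, groupSizes, sampleTag = "X")
    # harsher, wider-dynamic-range distortion than any discovery setting
    exprs <- .applyDistortion(mat$exprs, "monotone-nonlinear",
                              aRange = c(50, 200), bRange = c(0, 10),
                              pRange = c(1.5, 3))
    sigGenes <- unique(unlist(pairTable(truth$signature)[c("geneI", "geneJ")]))
    nonSig <- setdiff(rownames(exprs), sigGenes)
    drop <- character()
    if (dropGenes > 0)
      drop <- sample(nonSig, floor(dropGenes * length(nonSig)))
    drop <- union(drop, intersect(dropSignatureGenes, rownames(exprs)))
    if (all(sigGenes %in% drop))
      warning("all signature genes dropped; every encoded feature will be -1")
    keep <- setdiff(rownames(exprs), drop)
    list(exprs = exprs[keep, , drop = FALSE], labels = mat$labels)
  })
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression matrix (TSV), labels (TSV) and planted truth
#' (JSON: signature pairs, background pairs, realized supports).
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return named vector of the three file paths, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             truth = file.path(dir, "truth.json"))
  writeExpressionMatrix(dataset$exprs, paths["matrix"])
  utils::write.table(dataset$labels, paths["labels"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(signature = pairTable(dataset$truth$signature),
         backgroundPairs = dataset$truth$backgroundPairs,
         supports = dataset$truth$supports),
    paths["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
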