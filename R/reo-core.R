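#' Detect stable gene pairs within a sample group
#'
#' For every canonical gene pair (i, j), with i preceding j in the sorted
#' gene universe, the fraction of samples with Gi > Gj and with Gi < Gj is
#' counted (ties fall in neither numerator but stay in the denominator).
#' A pair is stable when one fraction strictly exceeds `threshold` — at the
#' default 0.85 a pair supported in exactly 85% of samples is excluded.
#'
#' Counting streams over pairs in compiled code and materializes only the
#' pairs that pass, so genome-scale universes (20k genes, ~2e8 candidate
#' pairs) never allocate the full pair table. For quick interactive runs
#' the universe can be restricted with `genes` (see
#' [topVariableGenes()]).
#'
#' Because only within-sample order relations are consulted, the result is
#' invariant under any strictly increasing per-sample transform of the
#' expression values — the property that makes REO signatures robust to
#' batch and platform effects.
#'
#' @param x numeric genes x samples expression matrix; must be complete
#'   over its gene universe (gene absence is only meaningful when applying
#'   a signature, see [encodeReoFeatures()]).
#' @param samples sample ids (or logical/integer index on columns) to use;
#'   default all.
#' @param threshold stability threshold in `[0.5, 1)`; default 0.85.
#' @param genes optional gene subset defining the pair universe.
#' @param group label stored on the result.
#' @return a [StablePairSet-class].
#' @examples
#' x <- rbind(A = c(5, 6, 7), B = c(1, 2, 3))
#' colnames(x) <- paste0("s", 1:3)
#' computeStablePairs(x)
#' @export
computeStablePairs <- function(x, samples = colnames(x), threshold = 0.85,
                               genes = NULL, group = "all") {
  .assertExpressionMatrix(x)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0.5 || threshold >= 1)
    stop("threshold must be a single value in [0.5, 1)", call. = FALSE)
  if (is.character(samples)) {
    missing <- setdiff(samples, colnames(x))
    if (length(missing))
      stop("unknown sample id(s): ", paste(utils::head(missing, 5), collapse = ", "),
           call. = FALSE)
  }
  xs <- x[, samples, drop = FALSE]
  if (!ncol(xs)) stop("empty sample subset", call. = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(xs))
    if (length(missing))
      stop("gene id(s) not in matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    xs <- xs[genes, , drop = FALSE]
  }
  universe <- canonicalSort(rownames(xs))
  xs <- xs[universe, , drop = FALSE]
  res <- stable_pairs_scan(xs, threshold)
  pairs <- data.frame(
    geneI = universe[res$i],
    geneJ = universe[res$j],
    direction = c("less", "greater")[(res$dir > 0) + 1L],
    support = res$support,
    stringsAsFactors = FALSE)
  StablePairSet(group = group, threshold = threshold,
                universe = universe, pairs = pairs)
}

#' Top variance-ranked genes
#'
#' Convenience pre-filter restricting a pair universe to the `n` most
#' variable genes, for desk-scale exploration.
#'
#' @param x numeric genes x samples matrix.
#' @param n number of genes to keep.
#' @return character vector of gene ids (canonically sorted).
#' @export
topVariableGenes <- function(x, n) {
  .assertExpressionMatrix(x)
  v <- apply(x, 1L, stats::var)
  canonicalSort(names(sort(v, decreasing = TRUE))[seq_len(min(n, length(v)))])
}

#' Intersect stable pair sets across subgroups
#'
#' Returns the pairs stable with the SAME direction in every input set
#' (the "consistent stable pairs" of a class made of several subgroups,
#' e.g. PDAC and PDAC-adjacent tissue on the tumor side). Support is
#' recorded as the minimum across inputs.
#'
#' @param ... two or more [StablePairSet-class] objects, or a single list
#'   of them; all must share the same threshold and gene universe.
#' @param group label for the resulting set; default concatenates inputs.
#' @return a [StablePairSet-class].
#' @export
intersectStablePairs <- function(..., group = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "StablePairSet"))
    sets <- sets[[1L]]
  if (length(sets) < 2L)
    stop("need at least two StablePairSet objects", call. = FALSE)
  if (!all(vapply(sets, is, logical(1L), "StablePairSet")))
    stop("all inputs must be StablePairSet objects", call. = FALSE)
  th <- threshold(sets[[1L]])
  uni <- geneUniverse(sets[[1L]])
  for (s in sets[-1L]) {
    if (!identical(threshold(s), th))
      stop("stable pair sets have different thresholds", call. = FALSE)
    if (!identical(geneUniverse(s), uni))
      stop("stable pair sets have different gene universes", call. = FALSE)
  }
  acc <- pairTable(sets[[1L]])
  for (s in sets[-1L]) {
    p <- pairTable(s)
    m <- merge(acc, p, by = c("geneI", "geneJ", "direction"))
    if (nrow(m)) {
      m$support <- pmin(m$support.x, m$support.y)
      acc <- m[c("geneI", "geneJ", "direction", "support")]
    } else {
      acc <- acc[0L, ]
    }
  }
  acc <- acc[order(acc$geneI, acc$geneJ, method = "radix"), , drop = FALSE]
  if (is.null(group))
    group <- paste(vapply(sets, groupLabel, character(1L)), collapse = " & ")
  StablePairSet(group = group, threshold = th, universe = uni, pairs = acc)
}

#' Find reversal gene pairs between two classes
#'
#' A reversal pair is stable in both the tumor-side and the control-side
#' pair set but with opposite directions; these are the candidate units of
#' a rank-based diagnostic signature. Output is ordered by canonical pair
#' key (mRMR re-ranks later).
#'
#' @param tumorSet,controlSet [StablePairSet-class] objects over a shared
#'   gene universe.
#' @return a [ReversalSignature-class] with per-pair supports in each class.
#' @export
findReversalPairs <- function(tumorSet, controlSet) {
  stopifnot(is(tumorSet, "StablePairSet"), is(controlSet, "StablePairSet"))
  if (!length(tumorSet) || !length(controlSet)) {
    return(ReversalSignature(data.frame(
      geneI = character(), geneJ = character(),
      tumorDirection = character(), controlDirection = character(),
      supportTumor = numeric(), supportControl = numeric(),
      stringsAsFactors = FALSE)))
  }
  if (!identical(geneUniverse(tumorSet), geneUniverse(controlSet)))
    stop("pair sets have different gene universes", call. = FALSE)
  t <- pairTable(tumorSet)
  c <- pairTable(controlSet)
  m <- merge(t, c, by = c("geneI", "geneJ"), suffixes = c(".t", ".c"))
  m <- m[m$direction.t != m$direction.c, , drop = FALSE]
  m <- m[order(m$geneI, m$geneJ, method = "radix"), , drop = FALSE]
  ReversalSignature(data.frame(
    geneI = m$geneI, geneJ = m$geneJ,
    tumorDirection = m$direction.t, controlDirection = m$direction.c,
    supportTumor = m$support.t, supportControl = m$support.c,
    stringsAsFactors = FALSE))
}

#' Encode samples as ternary REO profiles
#'
#' Builds the samples x pairs feature matrix over \{0, 1, -1\}: per sample
#' and signature pair, 0 when Gi > Gj, 1 when Gi < Gj, and -1 otherwise —
#' i.e. when either gene is absent from the applied matrix (the
#' cross-platform case) or the two values tie. Absent genes are the
#' defined -1 case, not an error, which is what lets a signature
#' discovered on one platform be applied on another.
#'
#' @param x numeric genes x samples matrix (may lack signature genes).
#' @param signature a nonempty [ReversalSignature-class].
#' @return integer matrix, samples in rows, one column per signature pair
#'   (named `"geneI|geneJ"`), values in \{0, 1, -1\}.
#' @export
encodeReoFeatures <- function(x, signature) {
  stopifnot(is(signature, "ReversalSignature"))
  p <- pairTable(signature)
  if (!nrow(p)) stop("signature holds no pairs", call. = FALSE)
  .assertExpressionMatrix(x)
  n <- ncol(x)
  out <- matrix(-1L, nrow = n, ncol = nrow(p),
                dimnames = list(colnames(x), paste(p$geneI, p$geneJ, sep = "|")))
  for (k in seq_len(nrow(p))) {
    gi <- p$geneI[k]; gj <- p$geneJ[k]
    if (gi %in% rownames(x) && gj %in% rownames(x)) {
      a <- x[gi, ]; b <- x[gj, ]
      out[, k] <- ifelse(a > b, 0L, ifelse(a < b, 1L, -1L))
    }
  }
  out
}

#' Export a stable pair set as TSV
#'
#' Writes `gene_i`, `gene_j`, `direction`, `support` rows for inspection;
#' paths ending in `.gz` are gzip-compressed.
#'
#' @param set a [StablePairSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStablePairs <- function(set, path) {
  stopifnot(is(set, "StablePairSet"))
  p <- pairTable(set)
  out <- data.frame(gene_i = p$geneI, gene_j = p$geneJ,
                    direction = p$direction, support = p$support)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a ternary feature matrix as TSV
#'
#' @param features integer samples x pairs matrix from
#'   [encodeReoFeatures()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureMatrix <- function(features, path) {
  df <- data.frame(sample_id = rownames(features), features,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
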