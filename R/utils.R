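# Internal helpers shared across modules.

# Run expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so library code never clobbers a
# user's stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Canonical (locale-independent) sort of gene identifiers.
canonicalSort <- function(ids) sort(as.character(ids), method = "radix")

.assertExpressionMatrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers in ", what, call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate sample identifiers in ", what, call. = FALSE)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

.pairKey <- function(geneI, geneJ) paste(geneI, geneJ, sep = "\r")

.oppositeDirection <- function(d) ifelse(d == "greater", "less", "greater")

# Deterministic stratified fold assignment: within each class, shuffled
# sample positions are dealt round-robin to folds.
makeStratifiedFolds <- function(labels, k, seed) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L) stop("k_folds must be >= 2", call. = FALSE)
  fold <- integer(n)
  withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
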