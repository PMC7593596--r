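#' Accessors for pair containers
#'
#' `pairTable()` returns the underlying pair data.frame, `threshold()` the
#' stability threshold, `groupLabel()` the group label and `geneUniverse()`
#' the gene identifiers a [StablePairSet-class] was enumerated over.
#'
#' @param x a [StablePairSet-class] or [ReversalSignature-class].
#' @return `pairTable()`: a data.frame; the others: length-1 vectors
#'   (or a character vector for `geneUniverse()`).
#' @name pair-accessors
NULL

#' @rdname pair-accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname pair-accessors
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname pair-accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname pair-accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname pair-accessors
setMethod("pairTable", "StablePairSet", function(x) x@pairs)

#' @rdname pair-accessors
setMethod("pairTable", "ReversalSignature", function(x) x@pairs)

#' @rdname pair-accessors
setMethod("threshold", "StablePairSet", function(x) x@threshold)

#' @rdname pair-accessors
setMethod("groupLabel", "StablePairSet", function(x) x@group)

#' @rdname pair-accessors
setMethod("geneUniverse", "StablePairSet", function(x) x@universe)

#' Number of stored pairs
#'
#' @param x a [StablePairSet-class] or [ReversalSignature-class].
#' @return integer pair count.
#' @aliases length,StablePairSet-method length,ReversalSignature-method
#' @name pair-length
NULL

#' @rdname pair-length
#' @export
setMethod("length", "StablePairSet", function(x) nrow(x@pairs))

#' @rdname pair-length
#' @export
setMethod("length", "ReversalSignature", function(x) nrow(x@pairs))

setMethod("show", "StablePairSet", function(object) {
  cat(sprintf("StablePairSet: %d stable pair(s) [group '%s', threshold %g, %d genes]\n",
              nrow(object@pairs), object@group, object@threshold,
              length(object@universe)))
  if (nrow(object@pairs)) {
    n <- min(5L, nrow(object@pairs))
    print(utils::head(object@pairs, n))
    if (nrow(object@pairs) > n) cat("  ...\n")
  }
  invisible(NULL)
})

setMethod("show", "ReversalSignature", function(object) {
  cat(sprintf("ReversalSignature: %d reversal gene pair(s)\n",
              nrow(object@pairs)))
  if (nrow(object@pairs)) print(object@pairs)
  invisible(NULL)
})
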