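#' @import methods
NULL

.DIRECTIONS <- c("greater", "less")

.validPairFrame <- function(df, cols) {
  if (!is.data.frame(df)) return("pairs must be a data.frame")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    return(paste0("pairs is missing column(s): ", paste(miss, collapse = ", ")))
  NULL
}

#' StablePairSet: gene pairs with a stable within-sample ordering
#'
#' Container for the gene pairs whose relative expression ordering (REO)
#' holds in more than a threshold fraction of the samples of one group.
#' Pair keys are canonical: `geneI` precedes `geneJ` in the sorted gene
#' universe, and `direction` is expressed relative to that orientation
#' (`"greater"` means geneI > geneJ within a sample).
#'
#' @slot group label of the sample group the set was computed on.
#' @slot threshold stability threshold in `[0.5, 1)`; a pair is stored only
#'   if its winning ordering fraction strictly exceeds it.
#' @slot universe character vector of the gene identifiers the pairs were
#'   enumerated over.
#' @slot pairs data.frame with columns `geneI`, `geneJ`, `direction`
#'   (`"greater"`/`"less"`) and `support` (winning fraction).
#'
#' @seealso [computeStablePairs()], [intersectStablePairs()],
#'   [findReversalPairs()]
#' @export
setClass("StablePairSet",
  slots = c(
    group = "character",
    threshold = "numeric",
    universe = "character",
    pairs = "data.frame"
  )
)

setValidity("StablePairSet", function(object) {
  msgs <- character()
  if (length(object@group) != 1L) msgs <- c(msgs, "group must be a single string")
  th <- object@threshold
  if (length(th) != 1L || is.na(th) || th < 0.5 || th >= 1)
    msgs <- c(msgs, "threshold must be a single value in [0.5, 1)")
  if (anyDuplicated(object@universe))
    msgs <- c(msgs, "gene universe contains duplicate identifiers")
  bad <- .validPairFrame(object@pairs,
                         c("geneI", "geneJ", "direction", "support"))
  if (!is.null(bad)) return(c(msgs, bad))
  p <- object@pairs
  if (nrow(p)) {
    if (!all(p$direction %in% .DIRECTIONS))
      msgs <- c(msgs, "direction must be 'greater' or 'less'")
    if (any(p$support <= th | p$support > 1))
      msgs <- c(msgs, "all supports must lie in (threshold, 1]")
    if (!all(p$geneI %in% object@universe) || !all(p$geneJ %in% object@universe))
      msgs <- c(msgs, "pair genes must belong to the universe")
    if (any(as.character(p$geneI) >= as.character(p$geneJ)))
      msgs <- c(msgs, "pair keys must be canonical (geneI < geneJ)")
    if (anyDuplicated(paste(p$geneI, p$geneJ, sep = "\r")))
      msgs <- c(msgs, "duplicate pair keys")
  }
  if (length(msgs)) msgs else TRUE
})

#' ReversalSignature: ordered reversal gene pairs
#'
#' A diagnostic signature: gene pairs whose REO is stable in both the
#' tumor-side and the control-side class but with opposite directions.
#' Row order is meaningful (discovery order, then mRMR rank order).
#'
#' @slot pairs data.frame with columns `geneI`, `geneJ`, `tumorDirection`,
#'   `controlDirection` and optionally `supportTumor`, `supportControl`,
#'   `rank`.
#'
#' @seealso [findReversalPairs()], [encodeReoFeatures()],
#'   [readSignature()], [writeSignature()]
#' @export
setClass("ReversalSignature",
  slots = c(pairs = "data.frame")
)

setValidity("ReversalSignature", function(object) {
  bad <- .validPairFrame(object@pairs,
                         c("geneI", "geneJ", "tumorDirection", "controlDirection"))
  if (!is.null(bad)) return(bad)
  p <- object@pairs
  msgs <- character()
  if (nrow(p)) {
    if (!all(p$tumorDirection %in% .DIRECTIONS) ||
        !all(p$controlDirection %in% .DIRECTIONS))
      msgs <- c(msgs, "directions must be 'greater' or 'less'")
    if (any(p$tumorDirection == p$controlDirection))
      msgs <- c(msgs, "every pair must reverse: tumorDirection != controlDirection")
    if (anyDuplicated(paste(p$geneI, p$geneJ, sep = "\r")))
      msgs <- c(msgs, "duplicate pair keys")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StablePairSet
#'
#' @param group group label.
#' @param threshold stability threshold in `[0.5, 1)`.
#' @param universe gene identifiers the pairs were enumerated over.
#' @param pairs data.frame with columns `geneI`, `geneJ`, `direction`,
#'   `support`.
#' @return a [StablePairSet-class] object.
#' @export
StablePairSet <- function(group, threshold, universe, pairs) {
  rownames(pairs) <- NULL
  new("StablePairSet", group = as.character(group),
      threshold = as.numeric(threshold),
      universe = as.character(universe), pairs = pairs)
}

#' Construct a ReversalSignature
#'
#' @param pairs data.frame with columns `geneI`, `geneJ`, `tumorDirection`,
#'   `controlDirection` (optionally supports and `rank`).
#' @return a [ReversalSignature-class] object.
#' @export
ReversalSignature <- function(pairs) {
  rownames(pairs) <- NULL
  new("ReversalSignature", pairs = pairs)
}
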