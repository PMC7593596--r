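#' Read an expression matrix from delimited text
#'
#' Reads a TSV/CSV expression table into the canonical internal form: a
#' numeric matrix with genes in rows and samples in columns. The first
#' column (or, for `"genes-in-columns"`, the first column of the transposed
#' layout) holds identifiers; the header row holds the other axis.
#'
#' Malformed numeric cells raise an error naming the offending gene and
#' sample; duplicate gene or sample identifiers and non-finite cells
#' (NA/NaN/Inf) are rejected. Duplicate gene rows are an error here —
#' probe aggregation is an explicit, separate step
#' ([aggregateProbes()]), never implicit on read.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated (override with `sep`).
#' @param dialect `"genes-in-rows"` (default; GEO series-matrix layout) or
#'   `"genes-in-columns"`.
#' @param sep field separator; `NULL` = infer from the extension.
#' @return numeric matrix, genes x samples, identifiers in file order.
#' @export
readExpressionMatrix <- function(path,
                                 dialect = c("genes-in-rows", "genes-in-columns"),
                                 sep = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "")
  if (ncol(df) < 2L) stop("expected an identifier column plus data columns")
  ids <- as.character(df[[1L]])
  headerIds <- colnames(df)[-1L]
  raw <- df[-1L]
  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(as.character(col)), numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(ids, headerIds))
  bad <- which(is.na(num) & !is.na(as.matrix(raw)), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("malformed numeric cell at row '%s', column '%s'",
                 ids[bad[1L, 1L]], headerIds[bad[1L, 2L]]), call. = FALSE)
  if (dialect == "genes-in-columns") num <- t(num)
  if (anyDuplicated(rownames(num)))
    stop("duplicate gene identifiers; aggregate probes explicitly with aggregateProbes()",
         call. = FALSE)
  if (anyDuplicated(colnames(num)))
    stop("duplicate sample identifiers", call. = FALSE)
  if (!all(is.finite(num)))
    stop("expression matrix contains NA/NaN/Inf cells", call. = FALSE)
  num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]: genes in rows, first column
#' `gene_id`, header row of sample identifiers.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  .assertExpressionMatrix(x)
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default group-to-class assignment
#'
#' Tumor-side groups are PDAC and PDAC-adjacent tissue (adjacent normal
#' tissue carries the tumor's qualitative ordering shifts and is treated as
#' a positive); pancreatitis and normal pancreas form the non-tumor side.
#'
#' @return named character vector mapping group to `"tumor"`/`"non-tumor"`.
#' @export
defaultClassMap <- function() {
  c(PDAC = "tumor", PDAC_adjacent = "tumor",
    pancreatitis = "non-tumor", normal = "non-tumor")
}

#' Read sample labels
#'
#' Reads a two- or three-column TSV (`sample_id`, `group`[, `class`]). When
#' the class column is absent it is derived from `classMap`.
#'
#' @param path file path (tab-separated, header row).
#' @param classMap named character vector group -> class; used only when
#'   the file lacks a class column.
#' @return data.frame with columns `sample_id`, `group`, `class`; class is
#'   always one of `"tumor"`/`"non-tumor"`.
#' @export
readSampleLabels <- function(path, classMap = defaultClassMap()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("labels file needs columns sample_id and group", call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in labels")
  if (!"class" %in% names(df)) {
    unknown <- setdiff(unique(df$group), names(classMap))
    if (length(unknown))
      stop("no class column and no class mapping for group(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    df$class <- unname(classMap[df$group])
  }
  if (!all(df$class %in% c("tumor", "non-tumor")))
    stop("class must be 'tumor' or 'non-tumor'", call. = FALSE)
  df[c("sample_id", "group", "class")]
}

#' Aggregate probe rows to gene rows
#'
#' Collapses a probe-level matrix to gene level by taking, per sample, the
#' arithmetic mean of all probes mapped to the same gene. Probes without a
#' mapping are dropped (with a message reporting how many).
#'
#' @param x numeric probes x samples matrix with probe rownames.
#' @param mapping two-column data.frame (`probe_id`, `gene_id`) or a named
#'   character vector `probe_id -> gene_id`.
#' @return numeric genes x samples matrix; one row per gene that received
#'   at least one probe.
#' @export
aggregateProbes <- function(x, mapping) {
  .assertExpressionMatrix(x, "probe matrix")
  if (is.data.frame(mapping)) {
    if (ncol(mapping) < 2L) stop("mapping needs two columns (probe, gene)")
    map <- stats::setNames(as.character(mapping[[2L]]),
                           as.character(mapping[[1L]]))
  } else {
    map <- as.character(mapping)
    names(map) <- names(mapping)
  }
  if (!length(map)) stop("empty probe-to-gene mapping", call. = FALSE)
  gene <- map[rownames(x)]
  keep <- !is.na(gene) & nzchar(gene)
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " probe(s) without a gene mapping dropped")
  if (!any(keep)) stop("no probe in the matrix is covered by the mapping")
  xm <- x[keep, , drop = FALSE]
  gene <- gene[keep]
  sums <- rowsum(xm, group = gene, reorder = TRUE)
  counts <- as.vector(table(gene)[rownames(sums)])
  out <- sums / counts
  .assertExpressionMatrix(out, "aggregated matrix")
}

#' Stratified train/test split
#'
#' Partitions samples into training and testing sets group by group. The
#' training set receives `floor((1 - testFraction) * groupSize)` samples of
#' each group and the test set the remainder, so that e.g. groups of sizes
#' 573/153/10/74 at `testFraction = 0.2` give test sets of 115/31/2/15.
#'
#' @param labels data.frame with columns `sample_id` and `group` (as from
#'   [readSampleLabels()]).
#' @param testFraction fraction held out per group, in (0, 1).
#' @param seed integer; the split is deterministic given the seed.
#' @return list with `train` and `test` (character sample ids) and `seed`.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.2, seed = 1L) {
  if (!is.numeric(testFraction) || testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie strictly between 0 and 1", call. = FALSE)
  groups <- split(as.character(labels$sample_id), labels$group)
  if (any(!lengths(groups))) stop("every group must be nonempty")
  test <- character()
  withSeed(seed, {
    for (g in names(groups)) {
      ids <- groups[[g]]
      nTrain <- floor((1 - testFraction) * length(ids))
      nTest <- length(ids) - nTrain
      test <- c(test, sample(ids, nTest))
    }
  })
  all <- as.character(labels$sample_id)
  list(train = setdiff(all, test), test = test[order(match(test, all))],
       seed = as.integer(seed))
}

#' Read / write a reversal signature as JSON
#'
#' The interchange format is a JSON array of objects with fields `gene_i`,
#' `gene_j`, `tumor_direction`, `control_direction` and optional `rank`.
#' Direction tokens are `"greater"` (gene i above gene j within a sample)
#' and `"less"`. Pair order in the file is preserved.
#'
#' @param path file path.
#' @return `readSignature()`: a [ReversalSignature-class];
#'   `writeSignature()`: `path`, invisibly.
#' @export
readSignature <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.data.frame(js) || !nrow(js))
    stop("signature file holds no pairs", call. = FALSE)
  need <- c("gene_i", "gene_j", "tumor_direction", "control_direction")
  miss <- setdiff(need, names(js))
  if (length(miss))
    stop("signature file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  badTok <- setdiff(unique(c(js$tumor_direction, js$control_direction)),
                    .DIRECTIONS)
  if (length(badTok))
    stop("unknown direction token(s): ", paste(badTok, collapse = ", "),
         call. = FALSE)
  p <- data.frame(geneI = as.character(js$gene_i),
                  geneJ = as.character(js$gene_j),
                  tumorDirection = js$tumor_direction,
                  controlDirection = js$control_direction,
                  stringsAsFactors = FALSE)
  if ("rank" %in% names(js)) p$rank <- as.integer(js$rank)
  ReversalSignature(p)
}

#' @param signature a [ReversalSignature-class]; must hold at least one pair.
#' @rdname readSignature
#' @export
writeSignature <- function(signature, path) {
  stopifnot(is(signature, "ReversalSignature"))
  p <- pairTable(signature)
  if (!nrow(p)) stop("refusing to write an empty signature", call. = FALSE)
  out <- data.frame(gene_i = p$geneI, gene_j = p$geneJ,
                    tumor_direction = p$tumorDirection,
                    control_direction = p$controlDirection,
                    rank = if ("rank" %in% names(p)) p$rank else seq_len(nrow(p)),
                    stringsAsFactors = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
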