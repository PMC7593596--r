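test_that("stable pair detection matches the threshold semantics", {
  # unanimous ordering: support 1.0
  x <- rbind(A = 11:20, B = 1:10)
  colnames(x) <- sprintf("s%02d", 1:10)
  sp <- computeStablePairs(x, threshold = 0.85)
  expect_identical(length(sp), 1L)
  expect_identical(pairTable(sp)$direction, "greater")
  expect_identical(pairTable(sp)$support, 1.0)

  # exactly 85% support is NOT stable (strictly more than required);
  # one extra sample tips it over
  mk <- function(nGreater, n = 20) {
    a <- numeric(n); b <- numeric(n)
    a[seq_len(nGreater)] <- 2; b[seq_len(nGreater)] <- 1
    if (nGreater < n) { a[(nGreater + 1):n] <- 1; b[(nGreater + 1):n] <- 2 }
    m <- rbind(A = a, B = b); colnames(m) <- sprintf("s%02d", 1:n); m
  }
  expect_identical(length(computeStablePairs(mk(17), threshold = 0.85)), 0L)
  sp18 <- computeStablePairs(mk(18), threshold = 0.85)
  expect_identical(length(sp18), 1L)
  expect_equal(pairTable(sp18)$support, 0.9)

  # ties stay in the denominator but feed neither direction
  xt <- rbind(A = c(2, 2, 2, 1), B = c(1, 1, 2, 2))
  colnames(xt) <- sprintf("s%d", 1:4)
  spt <- computeStablePairs(xt, threshold = 0.5)
  expect_identical(length(spt), 0L)  # f> = 2/4, not > 0.5

  expect_error(computeStablePairs(x, samples = character(0)), "empty sample")
  expect_error(computeStablePairs(x, genes = "nope"), "not in matrix")
  expect_error(computeStablePairs(x, threshold = 0.3), "threshold")
})

test_that("stable pair detection equals the brute-force oracle", {
  set.seed(202)
  for (i in 1:25) {
    g <- sample(5:50, 1); n <- sample(4:30, 1)
    x <- randomExprs(g, n)
    # inject ties occasionally
    if (i %% 3 == 0) x[1, ] <- x[2, ]
    th <- sample(c(0.6, 0.75, 0.85, 0.9), 1)
    got <- pairTable(computeStablePairs(x, threshold = th))
    want <- bruteStablePairs(x, th)
    expect_equal(got, want)
  }
})

test_that("raising the threshold never adds pairs (monotonicity)", {
  set.seed(7)
  x <- randomExprs(30, 15)
  lo <- pairTable(computeStablePairs(x, threshold = 0.6))
  hi <- pairTable(computeStablePairs(x, threshold = 0.9))
  keyLo <- paste(lo$geneI, lo$geneJ)
  keyHi <- paste(hi$geneI, hi$geneJ)
  expect_true(all(keyHi %in% keyLo))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("stable pairs and encodings are invariant to monotone transforms", {
  set.seed(31)
  for (i in 1:5) {
    x <- randomExprs(20, 12)
    tr <- replicate(ncol(x), randomMonotoneTransform())
    xd <- applyPerSample(x, tr)
    expect_identical(pairTable(computeStablePairs(x, threshold = 0.7)),
                     pairTable(computeStablePairs(xd, threshold = 0.7)))
    sig <- ReversalSignature(data.frame(
      geneI = "g001", geneJ = "g002",
      tumorDirection = "greater", controlDirection = "less"))
    expect_identical(encodeReoFeatures(x, sig), encodeReoFeatures(xd, sig))
  }
})

test_that("intersection keeps same-direction pairs with min support", {
  x <- rbind(A = c(5, 6, 7, 8), B = c(1, 2, 3, 4), C = c(9, 9.5, 1, 2))
  colnames(x) <- sprintf("s%d", 1:4)
  s1 <- computeStablePairs(x, samples = c("s1", "s2"), threshold = 0.5, group = "g1")
  s2 <- computeStablePairs(x, samples = c("s3", "s4"), threshold = 0.5, group = "g2")
  both <- intersectStablePairs(s1, s2)
  # A>B holds everywhere; A vs C and B vs C flip between the halves
  expect_identical(pairTable(both)$geneI, "A")
  expect_identical(pairTable(both)$geneJ, "B")
  expect_identical(pairTable(both)$direction, "greater")

  # direction conflict excluded, identity intersection preserved
  expect_identical(pairTable(intersectStablePairs(s1, s1)), pairTable(s1))
  expect_error(intersectStablePairs(s1), "at least two")

  # three-way intersection equals the set-algebra oracle
  set.seed(13)
  big <- randomExprs(25, 30)
  blocks <- list(1:10, 11:20, 21:30)
  sets <- lapply(seq_along(blocks), function(b)
    computeStablePairs(big, samples = colnames(big)[blocks[[b]]],
                       threshold = 0.7, group = paste0("b", b)))
  got <- pairTable(intersectStablePairs(sets))
  tabs <- lapply(sets, pairTable)
  keys <- lapply(tabs, function(t) paste(t$geneI, t$geneJ, t$direction))
  common <- Reduce(intersect, keys)
  expect_setequal(paste(got$geneI, got$geneJ, got$direction), common)
  for (r in seq_len(nrow(got))) {
    k <- paste(got$geneI[r], got$geneJ[r], got$direction[r])
    sups <- vapply(seq_along(tabs), function(i)
      tabs[[i]]$support[keys[[i]] == k], numeric(1))
    expect_equal(got$support[r], min(sups))
  }
})

test_that("reversal pairs are opposite-direction stable pairs, symmetric in class order", {
  mkSet <- function(dirAB, group) {
    x <- if (dirAB == "greater") rbind(A = c(5, 6), B = c(1, 2))
         else rbind(A = c(1, 2), B = c(5, 6))
    colnames(x) <- c("s1", "s2")
    computeStablePairs(x, threshold = 0.5, group = group)
  }
  tum <- mkSet("greater", "tumor"); ctl <- mkSet("less", "control")
  sig <- findReversalPairs(tum, ctl)
  expect_identical(pairTable(sig)$tumorDirection, "greater")
  expect_identical(pairTable(sig)$controlDirection, "less")

  # consistent pair is no reversal
  expect_identical(length(findReversalPairs(tum, mkSet("greater", "x"))), 0L)

  # swapping the argument order swaps the two direction columns
  swapped <- pairTable(findReversalPairs(ctl, tum))
  expect_identical(swapped$tumorDirection, pairTable(sig)$controlDirection)
  expect_identical(swapped$controlDirection, pairTable(sig)$tumorDirection)
})

test_that("planted reversal pairs are recovered exactly among 500 genes", {
  d <- generateDataset(synthConfig(nGenes = 500, nReversalPairs = 16,
                                   reversalStability = 0.95, seed = 417))
  tumorIds <- d$labels$sample_id[d$labels$class == "tumor"]
  controlIds <- d$labels$sample_id[d$labels$class == "non-tumor"]
  tum <- computeStablePairs(d$exprs, samples = tumorIds, threshold = 0.85)
  ctl <- computeStablePairs(d$exprs, samples = controlIds, threshold = 0.85)
  found <- pairTable(findReversalPairs(tum, ctl))
  want <- pairTable(d$truth$signature)
  expect_identical(found[c("geneI", "geneJ")], want[c("geneI", "geneJ")])
  expect_identical(found$tumorDirection, want$tumorDirection)
})

test_that("ternary encoding maps orderings, ties and absent genes", {
  sig <- ReversalSignature(data.frame(
    geneI = c("A", "A"), geneJ = c("B", "Z"),
    tumorDirection = c("greater", "greater"),
    controlDirection = c("less", "less")))
  x <- rbind(A = c(7, 3, 5), B = c(3, 7, 5))
  colnames(x) <- c("s1", "s2", "s3")
  f <- encodeReoFeatures(x, sig)
  expect_identical(f[, "A|B"], c(s1 = 0L, s2 = 1L, s3 = -1L))  # >, <, tie
  expect_identical(unname(f[, "A|Z"]), rep(-1L, 3))            # Z absent
  expect_true(all(f %in% c(-1L, 0L, 1L)))
})

test_that("antisymmetry: canonical storage is unique", {
  # same data presented with rows in reverse order yields identical sets
  x <- randomExprs(10, 8, seed = 9)
  a <- pairTable(computeStablePairs(x, threshold = 0.6))
  b <- pairTable(computeStablePairs(x[rev(rownames(x)), ], threshold = 0.6))
  expect_identical(a, b)
})
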