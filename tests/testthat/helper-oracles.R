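# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, direct formula evaluation) so they
# check the package implementations from a separate route.

randomExprs <- function(nGenes, nSamples, seed = NULL) {
  draw <- function() {
    x <- matrix(rnorm(nGenes * nSamples, 8, 2), nGenes, nSamples,
                dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                                sprintf("s%03d", seq_len(nSamples))))
    x
  }
  if (is.null(seed)) draw() else { set.seed(seed); draw() }
}

# Exhaustive double-loop stable-pair enumeration over the canonical
# (sorted) gene order; ties count in the denominator only.
bruteStablePairs <- function(x, threshold) {
  genes <- sort(rownames(x), method = "radix")
  out <- NULL
  n <- ncol(x)
  for (a in seq_along(genes)[-length(genes)]) {
    for (b in (a + 1L):length(genes)) {
      vi <- x[genes[a], ]; vj <- x[genes[b], ]
      fgt <- sum(vi > vj) / n
      flt <- sum(vi < vj) / n
      if (fgt > threshold)
        out <- rbind(out, data.frame(geneI = genes[a], geneJ = genes[b],
                                     direction = "greater", support = fgt,
                                     stringsAsFactors = FALSE))
      else if (flt > threshold)
        out <- rbind(out, data.frame(geneI = genes[a], geneJ = genes[b],
                                     direction = "less", support = flt,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(geneI = character(), geneJ = character(),
                      direction = character(), support = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Direct plug-in MI over an explicit joint count table (nats).
bruteMiFromCounts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p); py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) total <- total + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  total
}

bruteMi <- function(x, y) unname(bruteMiFromCounts(unclass(table(x, y))))

# AUC as the normalized concordant-pair count (ties worth 1/2).
bruteAuc <- function(scores, labels, positive = "tumor") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

bruteMcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# Strictly increasing per-sample transforms for rank-invariance checks.
randomMonotoneTransform <- function() {
  a <- runif(1, 0.5, 3); b <- runif(1, -2, 5)
  k <- sample(3, 1)
  switch(k,
         function(v) a * v + b,
         function(v) a * exp(v / 10) + b,
         function(v) a * sign(v) * abs(v)^1.7 + b)
}

applyPerSample <- function(x, transforms) {
  for (s in seq_len(ncol(x))) x[, s] <- transforms[[s]](x[, s])
  x
}

# Small labeled feature fixture that is perfectly separable.
separableFeatures <- function(n = 40) {
  labels <- rep(c("tumor", "non-tumor"), each = n / 2)
  f <- cbind(ifelse(labels == "tumor", 0, 1),
             ifelse(labels == "tumor", 1, 0))
  rownames(f) <- sprintf("s%02d", seq_len(n))
  list(features = f, labels = labels)
}
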