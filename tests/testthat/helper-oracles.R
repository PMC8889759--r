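## Independent oracles and small fixtures used across the suite. The oracles
## deliberately use brute-force formulations that share no code with the
## package implementation.

## AUROC by explicit enumeration of all positive-negative pairs (ties 1/2).
bruteForceAuc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

## Hand-Till M by enumerating every unordered class pair and every
## within-pair sample comparison.
bruteForceHandTill <- function(probs, labels) {
  classes <- colnames(probs)
  classes <- classes[classes %in% labels]
  c <- length(classes)
  total <- 0
  for (i in seq_len(c - 1)) for (j in (i + 1):c) {
    ci <- classes[i]; cj <- classes[j]
    sel <- labels %in% c(ci, cj)
    aij <- bruteForceAuc(probs[sel, ci], as.integer(labels[sel] == ci))
    aji <- bruteForceAuc(probs[sel, cj], as.integer(labels[sel] == cj))
    total <- total + (aij + aji) / 2
  }
  2 / (c * (c - 1)) * total
}

## A tiny two-group spec: nCrc cancer (stage II) vs nHd healthy donors.
twoGroupSpec <- function(nHd, nCrc, nGenes, nInformative = 0,
                         effectLog2FC = 0, nAgeGenes = 0, nBatches = 1L,
                         batchSD = 0, dispersion = 0.2, seed = 1L, ...) {
  cohortSpec(nPerGroup = c(HD = nHd, CD = 0, UC = 0, Polyp = 0, Adenoma = 0,
                           "CRC-I" = 0, "CRC-II" = nCrc, "CRC-III" = 0,
                           "CRC-IV" = 0),
             nGenes = nGenes, nInformative = nInformative,
             effectLog2FC = effectLog2FC, nAgeGenes = nAgeGenes,
             nBatches = nBatches, batchSD = batchSD,
             dispersion = dispersion, seed = seed, ...)
}

## Perfectly separable expression toy: one gene carries the labels with a
## wide margin, the rest are noise.
separableExpr <- function(n = 40, nGenes = 10, seed = 5) {
  set.seed(seed)
  y <- rep(c("ctrl", "case"), each = n / 2)
  e <- matrix(rnorm(nGenes * n), nGenes, n,
              dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(n))))
  e[1, y == "case"] <- e[1, y == "case"] + 8
  list(expr = e, labels = y)
}
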