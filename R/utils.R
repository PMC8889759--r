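## Internal helpers shared across modules.

## Derive a reproducible child seed from a global seed and a stage tag, so
## pipeline stages can be rerun in isolation. Kept below 2^31 - 1.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587L)
}

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

## Truncated-normal sampler by rejection; ranges here are wide (several SD)
## so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

## Stratified k-fold assignment: within each class, samples are shuffled and
## dealt round-robin so every fold holds both classes whenever possible.
stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

## 0/1 labels from a two-level input, second level (or `positive`) = 1.
binaryLabels <- function(labels, positive = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2)
    stop("expected exactly two classes, got ", nlevels(f))
  if (is.null(positive)) positive <- levels(f)[2]
  as.integer(f == positive)
}

## Cheap stable fingerprint of a configuration list (no digest dependency).
hashConfig <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}
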