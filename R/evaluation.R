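## Classifier evaluation: ROC/AUROC with DeLong intervals and comparison
## tests, Hand-Till multiclass AUROC, confusion metrics with exact
## Clopper-Pearson intervals, pooled-LOOCV evaluation, and per-stage
## sensitivity tables.

#' Mann-Whitney AUROC
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted one-half: \eqn{(\sum_i R_i - n_1(n_1+1)/2) / (n_1 n_0)} with
#' midranks \eqn{R_i} of the positive scores. Bit-identical to the
#' trapezoidal area of the tie-grouped empirical ROC.
#'
#' @param scores numeric decision values.
#' @param labels 0/1 (or two-level) class labels.
#' @return AUROC in `[0, 1]`.
#' @export
mannWhitneyAuc <- function(scores, labels) {
  y <- if (all(labels %in% c(0, 1))) as.integer(labels) else binaryLabels(labels)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## DeLong placement values; also used for the paired AUC comparison.
.delongPlacements <- function(scores, y) {
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r[seq_len(n1)] - rank(pos, ties.method = "average")) / n0
  v01 <- 1 - (r[n1 + seq_len(n0)] - rank(neg, ties.method = "average")) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC curve with AUROC and DeLong 95% interval
#'
#' Builds the tie-grouped empirical ROC from decision values, computes the
#' trapezoidal AUROC (equal to the Mann-Whitney normalization by
#' construction) and the DeLong variance-based 95% confidence interval.
#'
#' @param scores numeric decision values (larger = more positive).
#' @param labels 0/1 (or two-level) class labels.
#' @return a [RocCurve-class].
#' @examples
#' rc <- rocAuc(c(0.9, 0.8, 0.3, 0.4), c(1, 1, 1, 0))
#' rocAucValue(rc)   # 2/3
#' @export
rocAuc <- function(scores, labels) {
  y <- if (all(labels %in% c(0, 1))) as.integer(labels) else binaryLabels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  ## group tied scores into single ROC vertices
  grp <- cumsum(!duplicated(s))
  tpByThr <- tapply(yy == 1L, grp, sum)
  fpByThr <- tapply(yy == 0L, grp, sum)
  tpr <- c(0, cumsum(tpByThr) / n1)
  fpr <- c(0, cumsum(fpByThr) / n0)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  pl <- .delongPlacements(scores, y)
  v <- stats::var(pl$v10) / n1 + stats::var(pl$v01) / n0
  half <- stats::qnorm(0.975) * sqrt(v)
  new("RocCurve", scores = as.numeric(scores), labels = y,
      fpr = unname(fpr), tpr = unname(tpr), thresholds = unname(thr),
      auc = auc, ciLow = max(0, auc - half), ciHigh = min(1, auc + half),
      delongVar = v)
}

#' DeLong test comparing two AUROCs
#'
#' Two-sided z-test on the difference of two AUROCs. In the paired form the
#' curves must score the identical samples (e.g. gene panel vs serum CEA on
#' the same cohort) and the DeLong covariance of the placement values is
#' subtracted; unpaired assumes independent cohorts.
#'
#' @param roc1,roc2 [RocCurve-class] objects.
#' @param paired logical; curves computed on the same samples.
#' @return list with `delta` (auc1 - auc2), `ciLow`, `ciHigh`, `z`, `p`.
#' @export
compareAucDelong <- function(roc1, roc2, paired = TRUE) {
  a1 <- roc1@auc; a2 <- roc2@auc
  if (paired) {
    if (!identical(roc1@labels, roc2@labels))
      stop("paired comparison requires identical samples and labels")
    p1 <- .delongPlacements(roc1@scores, roc1@labels)
    p2 <- .delongPlacements(roc2@scores, roc2@labels)
    n1 <- length(p1$v10); n0 <- length(p1$v01)
    v <- stats::var(p1$v10 - p2$v10) / n1 + stats::var(p1$v01 - p2$v01) / n0
  } else {
    v <- roc1@delongVar + roc2@delongVar
  }
  delta <- a1 - a2
  if (v <= .Machine$double.eps) {
    if (abs(delta) < .Machine$double.eps^0.5)
      return(list(delta = delta, ciLow = delta, ciHigh = delta, z = 0, p = 1))
    warning("degenerate DeLong variance; p-value unavailable")
    return(list(delta = delta, ciLow = NA_real_, ciHigh = NA_real_,
                z = NA_real_, p = NA_real_))
  }
  z <- delta / sqrt(v)
  half <- stats::qnorm(0.975) * sqrt(v)
  list(delta = delta, ciLow = delta - half, ciHigh = delta + half,
       z = z, p = 2 * stats::pnorm(-abs(z)))
}

## Clopper-Pearson exact 95% interval of k/n (via the beta quantiles that
## binom.test uses); returns c(NA, NA) on an empty margin.
.exactCi <- function(k, n) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(stats::binom.test(k, n)$conf.int)
}

#' Confusion-matrix metrics with exact intervals
#'
#' From the four cells of a binary confusion matrix computes accuracy,
#' sensitivity, specificity, PPV and NPV, each with its exact 95%
#' Clopper-Pearson interval, plus Cohen's kappa (chance-corrected agreement
#' with marginal-product expected accuracy) and the F1 score (harmonic mean
#' of PPV and sensitivity). Metrics whose margin is empty are reported as
#' `NA`.
#'
#' @param tp,fn,fp,tn nonnegative integer cell counts (predictions in rows:
#'   `tp` = true positives, `fn` = positives predicted negative, `fp` =
#'   negatives predicted positive, `tn` = true negatives).
#' @return object of class `"confusionMetrics"`: a list with elements
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv` (each a vector
#'   `c(estimate, lower, upper)`), `kappa`, `f1`, and the cell counts.
#' @examples
#' m <- confusionMetrics(tp = 78, fn = 2, fp = 23, tn = 99)
#' round(c(m$kappa, m$f1, m$accuracy[1]), 3)
#' @export
confusionMetrics <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  n <- tp + fn + fp + tn
  if (n == 0) stop("empty confusion matrix")
  est <- function(k, m) {
    if (m == 0) return(c(NA_real_, NA_real_, NA_real_))
    c(k / m, .exactCi(k, m))
  }
  accuracy    <- est(tp + tn, n)
  sensitivity <- est(tp, tp + fn)
  specificity <- est(tn, tn + fp)
  ppv         <- est(tp, tp + fp)
  npv         <- est(tn, tn + fn)
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < .Machine$double.eps) 1 else (po - pe) / (1 - pe)
  f1 <- if (is.na(ppv[1]) || is.na(sensitivity[1]) ||
            ppv[1] + sensitivity[1] == 0) NA_real_
        else 2 * ppv[1] * sensitivity[1] / (ppv[1] + sensitivity[1])
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, n = n,
                 accuracy = accuracy, sensitivity = sensitivity,
                 specificity = specificity, ppv = ppv, npv = npv,
                 kappa = kappa, f1 = f1),
            class = "confusionMetrics")
}

#' @export
print.confusionMetrics <- function(x, ...) {
  cat(sprintf("confusionMetrics (n = %d): tp %d, fn %d, fp %d, tn %d\n",
              x$n, x$tp, x$fn, x$fp, x$tn))
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    cat(sprintf("  %-12s %.3f (95%% CI %.3f-%.3f)\n", nm, x[[nm]][1],
                x[[nm]][2], x[[nm]][3]))
  cat(sprintf("  %-12s %.3f\n  %-12s %.3f\n", "kappa", x$kappa, "F1", x$f1))
  invisible(x)
}

#' Hand-Till multiclass AUROC
#'
#' For every unordered pair of classes (i, j) computes the symmetrized
#' pairwise AUC \eqn{\hat A(i,j) = [A(i|j) + A(j|i)]/2}, where A(i|j) is the
#' AUC of the class-i probability column restricted to samples of classes i
#' and j, and averages: \eqn{M = \frac{2}{c(c-1)} \sum_{i<j} \hat A(i,j)}.
#' Classes absent from `labels` are excluded from the pairing and recorded.
#'
#' @param probs samples x classes matrix of class probabilities (rows sum to
#'   1 within 1e-6; column names are the class labels).
#' @param labels per-sample true class labels.
#' @return list with `M`, the `pairwise` matrix of \eqn{\hat A(i,j)}, the
#'   `classes` used, and `excluded` (classes without samples).
#' @export
handTillMulticlassAuc <- function(probs, labels) {
  probs <- as.matrix(probs)
  if (is.null(colnames(probs))) stop("probs must have class column names")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must sum to 1 (tolerance 1e-6)")
  labels <- as.character(labels)
  classes <- colnames(probs)
  present <- classes[classes %in% labels]
  excluded <- setdiff(classes, present)
  if (length(present) < 2) stop("need at least two classes with samples")
  c <- length(present)
  A <- matrix(NA_real_, c, c, dimnames = list(present, present))
  for (i in seq_len(c - 1)) for (j in (i + 1):c) {
    ci <- present[i]; cj <- present[j]
    sel <- labels %in% c(ci, cj)
    aij <- mannWhitneyAuc(probs[sel, ci], as.integer(labels[sel] == ci))
    aji <- mannWhitneyAuc(probs[sel, cj], as.integer(labels[sel] == cj))
    A[i, j] <- A[j, i] <- (aij + aji) / 2
  }
  M <- 2 / (c * (c - 1)) * sum(A[upper.tri(A)])
  list(M = M, pairwise = A, classes = present, excluded = excluded)
}

#' Leave-one-out cross-validated evaluation
#'
#' Performs n model fits, each holding out one sample; the held-out decision
#' values are pooled into a single ROC curve, and hard labels at the SVM
#' decision boundary (0) feed the confusion metrics. When a `selector` is
#' supplied it is re-run inside every fold on the training portion only, so
#' feature selection cannot leak the held-out label.
#'
#' @param expr expression matrix, genes x samples.
#' @param labels two-level class labels (second factor level = positive).
#' @param panel fixed gene panel ([FeaturePanel-class] /
#'   [BpsoResult][FeaturePanel-class] / character), or `NULL` when
#'   `selector` is given.
#' @param selector optional `function(exprTrain, labelsTrain)` returning the
#'   gene ids to use for that fold.
#' @param extra optional samples x features matrix of extra features.
#' @param kernel,cost SVM settings.
#' @return list with `roc` ([RocCurve-class]), `confusion`
#'   (`confusionMetrics`), `scores`, `predicted` (0/1), and `nFits`.
#' @export
loocvEvaluate <- function(expr, labels, panel = NULL, selector = NULL,
                          extra = NULL, kernel = "radial", cost = 1) {
  y <- binaryLabels(labels)
  n <- length(y)
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  genesFixed <- if (!is.null(panel)) {
    if (is.character(panel)) panel else panelGenes(panel)
  } else if (is.null(selector)) {
    stop("supply a panel or a selector")
  } else NULL
  scores <- numeric(n)
  nFits <- 0L
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    genes <- if (is.null(genesFixed))
      selector(expr[, tr, drop = FALSE], y[tr]) else genesFixed
    clf <- buildFinalClassifier(
      expr[, tr, drop = FALSE], y[tr], genes,
      extra = if (is.null(extra)) NULL else extra[tr, , drop = FALSE],
      kernel = kernel, cost = cost)
    scores[i] <- predictScores(
      clf, expr[, i, drop = FALSE],
      extra = if (is.null(extra)) NULL else extra[i, , drop = FALSE])
    nFits <- nFits + 1L
  }
  pred <- as.integer(scores > 0)
  conf <- confusionMetrics(tp = sum(pred == 1 & y == 1),
                           fn = sum(pred == 0 & y == 1),
                           fp = sum(pred == 1 & y == 0),
                           tn = sum(pred == 0 & y == 0))
  list(roc = rocAuc(scores, y), confusion = conf, scores = scores,
       predicted = pred, nFits = nFits)
}

#' Sensitivity of cancer detection by tumor stage
#'
#' Among true positives, tabulates per-stage sensitivity TP/(TP+FN),
#' reporting both the fraction as `"k/n"` and the percentage. Empty strata
#' are omitted.
#'
#' @param predicted 0/1 predicted labels.
#' @param truth 0/1 true labels (1 = cancer).
#' @param stage per-sample stage labels (used for the positives).
#' @return data.frame with columns `stage`, `detected`, `total`, `fraction`,
#'   `sensitivityPct`.
#' @examples
#' sensitivityByStratum(c(1, 1, 0, 1), c(1, 1, 1, 1),
#'                      c("I", "I", "I", "II"))
#' @export
sensitivityByStratum <- function(predicted, truth, stage) {
  pos <- truth == 1
  st <- stage[pos]; pr <- predicted[pos]
  out <- do.call(rbind, lapply(sort(unique(st[!is.na(st)])), function(s) {
    k <- sum(pr[st == s & !is.na(st)] == 1)
    n <- sum(st == s, na.rm = TRUE)
    data.frame(stage = s, detected = k, total = n,
               fraction = sprintf("%d/%d", k, n),
               sensitivityPct = 100 * k / n)
  }))
  out
}
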