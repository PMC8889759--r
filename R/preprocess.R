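## Count-matrix preprocessing: low-count filtering, median-of-ratios size
## factors, method-of-moments dispersion with a 1/mu trend, the closed-form
## NB variance-stabilizing transformation, age-correlation gene exclusion,
## and surrogate-variable removal. The fixed pipeline order is
## filter -> size factors -> dispersion -> vst -> age filter -> sva.

#' Drop genes that never reach a minimum read count
#'
#' Excludes transcripts with fewer than `threshold` reads in every sample,
#' i.e. retains exactly the genes whose maximum count over samples is at
#' least `threshold`. Gene order and the sample set are preserved; the
#' operation is idempotent.
#'
#' @param cohort a [TepCohort-class] (or bare count matrix).
#' @param threshold minimum read count a gene must reach in at least one
#'   sample (default 5).
#' @return the filtered object, same class as the input.
#' @export
filterLowCounts <- function(cohort, threshold = 5) {
  cts <- if (is(cohort, "SummarizedExperiment")) cohortCounts(cohort) else cohort
  keep <- apply(cts, 1, max) >= threshold
  if (!any(keep)) warning("low-count filter removed every gene")
  cohort[keep, ]
}

#' Median-of-ratios size factors
#'
#' For each sample the size factor is the median, over genes with strictly
#' positive counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean. The factors are rescaled to have geometric mean 1,
#' so normalized counts stay on the raw-count scale.
#'
#' @param cohort a [TepCohort-class] or count matrix.
#' @param fallback if `TRUE`, when no gene is positive in every sample the
#'   pseudo-reference is computed from positive counts only (over genes
#'   positive in at least half the samples) instead of erroring.
#' @return named numeric vector of size factors (geometric mean 1).
#' @export
estimateSizeFactorsMoR <- function(cohort, fallback = FALSE) {
  cts <- if (is(cohort, "SummarizedExperiment")) cohortCounts(cohort) else cohort
  allPos <- rowSums(cts == 0) == 0
  if (!any(allPos)) {
    if (!fallback)
      stop("no gene has positive counts in every sample; rerun with ",
           "fallback = TRUE to use a positive-count pseudo-reference")
    use <- rowSums(cts > 0) >= ncol(cts) / 2
    if (!any(use)) stop("no gene is positive in at least half the samples")
    logRef <- apply(cts[use, , drop = FALSE], 1,
                    function(x) mean(log(x[x > 0])))
    logRatios <- log(cts[use, , drop = FALSE])
    logRatios[!is.finite(logRatios)] <- NA
    sf <- exp(apply(logRatios - logRef, 2, stats::median, na.rm = TRUE))
  } else {
    sub <- cts[allPos, , drop = FALSE]
    logRef <- rowMeans(log(sub))
    sf <- exp(apply(log(sub) - logRef, 2, stats::median))
  }
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(cts))
}

#' Method-of-moments dispersion estimates with a robust 1/mu trend
#'
#' Per gene, on size-factor-normalized counts with mean \eqn{m_g} and
#' variance \eqn{s^2_g}, the NB dispersion is estimated as
#' \eqn{\hat\alpha_g = \max(0, (s^2_g - m_g)/m_g^2)}. The mean-dispersion
#' trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} is then fitted by robust
#' regression (Huber M-estimation) of \eqn{\hat\alpha_g} on \eqn{1/m_g} over
#' genes with positive estimates. When every gene looks Poisson the fit
#' degenerates to \eqn{a_0 = a_1 = 0} with a `poissonLike` flag.
#'
#' @param cohort a [TepCohort-class] or count matrix.
#' @param sizeFactors size factors from [estimateSizeFactorsMoR()].
#' @return a [DispersionFit-class].
#' @export
fitDispersionTrend <- function(cohort, sizeFactors) {
  cts <- if (is(cohort, "SummarizedExperiment")) cohortCounts(cohort) else cohort
  if (ncol(cts) < 2) stop("dispersion estimation needs at least 2 samples")
  q <- sweep(cts, 2, sizeFactors, "/")
  m <- rowMeans(q)
  v <- apply(q, 1, stats::var)
  alpha <- pmax(0, (v - m) / m^2)
  alpha[!is.finite(alpha)] <- 0
  use <- alpha > 0 & m > 0
  if (!any(use))
    return(new("DispersionFit", alphaGene = stats::setNames(alpha, rownames(cts)),
               geneMeans = stats::setNames(m, rownames(cts)),
               a0 = 0, a1 = 0, poissonLike = TRUE))
  co <- tryCatch(
    stats::coef(MASS::rlm(alpha[use] ~ I(1 / m[use]), maxit = 100)),
    error = function(e) tryCatch(
      stats::coef(stats::lm(alpha[use] ~ I(1 / m[use]))),
      error = function(e2) c(stats::median(alpha[use]), 0)))
  if (any(is.na(co))) co <- c(stats::median(alpha[use]), 0)
  a0 <- max(unname(co[1]), 1e-8)
  a1 <- max(unname(co[2]), 0)
  new("DispersionFit", alphaGene = stats::setNames(alpha, rownames(cts)),
      geneMeans = stats::setNames(m, rownames(cts)),
      a0 = a0, a1 = a1, poissonLike = FALSE)
}

## Closed-form variance-stabilizing map for NB counts with dispersion trend
## alpha(mu) = a0 + a1/mu, applied to a normalized count q, scaled so it
## approaches log2(q) for large q.
.vstMap <- function(q, a0, a1) {
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Variance-stabilizing transformation of NB counts
#'
#' Applies the closed-form variance-stabilizing map for the fitted dispersion
#' trend \eqn{\alpha(\mu) = a_0 + a_1/\mu} to size-factor-normalized counts.
#' The map is monotone in the raw count for fixed size factor and approaches
#' `log2` for large counts, so transformed values live on a log2-like scale
#' whose spread is approximately independent of the mean. When the trend has
#' no asymptotic dispersion (`a0 = 0`, Poisson-like fit) the transform falls
#' back to `log2(q + 1)` and the provenance records it.
#'
#' @param cohort a [TepCohort-class] or count matrix.
#' @param sizeFactors size factors from [estimateSizeFactorsMoR()].
#' @param fit a [DispersionFit-class] from [fitDispersionTrend()].
#' @return numeric matrix of transformed expression (genes x samples) with
#'   attribute `provenance` set to `"vst"` or `"log2-fallback"`.
#' @export
vstTransform <- function(cohort, sizeFactors, fit) {
  cts <- if (is(cohort, "SummarizedExperiment")) cohortCounts(cohort) else cohort
  if (any(cts < 0)) stop("counts must be nonnegative")
  q <- sweep(cts, 2, sizeFactors, "/")
  if (fit@poissonLike || fit@a0 <= 0) {
    out <- log2(q + 1)
    attr(out, "provenance") <- "log2-fallback"
  } else {
    out <- .vstMap(q, fit@a0, fit@a1)
    attr(out, "provenance") <- "vst"
  }
  out
}

#' Exclude genes whose expression correlates with age
#'
#' Tests each gene's expression against donor age (Pearson by default),
#' adjusts the p-values (Benjamini-Hochberg by default) and removes genes
#' significant at `alpha`. Constant genes get p = 1 by convention. The
#' removal list is returned for audit.
#'
#' @param expr expression matrix (genes x samples), e.g. from
#'   [vstTransform()].
#' @param age numeric vector of donor ages, aligned with the columns.
#' @param alpha significance level after adjustment (default 0.05).
#' @param method correlation test, `"pearson"` or `"spearman"`.
#' @param adjust multiplicity adjustment, `"BH"` or `"none"`.
#' @return list with `expr` (the filtered matrix), `removed` (gene ids) and
#'   `pvalues` (adjusted, named per gene).
#' @export
ageCorrelationFilter <- function(expr, age, alpha = 0.05,
                                 method = c("pearson", "spearman"),
                                 adjust = c("BH", "none")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (length(age) != ncol(expr)) stop("age must align with samples")
  if (any(is.na(age))) stop("ages must be present for all samples")
  pv <- apply(expr, 1, function(y) {
    if (stats::sd(y) == 0) return(1)
    suppressWarnings(stats::cor.test(y, age, method = method)$p.value)
  })
  padj <- stats::p.adjust(pv, method = if (adjust == "BH") "BH" else "none")
  removed <- rownames(expr)[padj < alpha]
  list(expr = expr[!(rownames(expr) %in% removed), , drop = FALSE],
       removed = removed, pvalues = padj)
}

#' Estimate and remove surrogate variables
#'
#' Captures latent structure (e.g. processing batches) not explained by the
#' diagnosis groups: the expression matrix is residualized on the group
#' factor, the residuals are decomposed by SVD, and the number of surrogate
#' variables k is chosen by permutation parallel analysis -- each of `B`
#' permutations scrambles every gene's residuals across samples
#' independently, and a component is kept while its singular value exceeds
#' the 95th percentile of the permuted singular values of the same rank.
#' Each gene is then regressed on group and the k surrogate variables
#' jointly, and only the surrogate contribution is subtracted, so group-mean
#' differences are preserved exactly for genes whose surrogate coefficients
#' are zero.
#'
#' @param expr expression matrix (genes x samples).
#' @param group factor of protected diagnosis labels per sample.
#' @param k number of surrogate variables, or `"auto"` (default) for the
#'   permutation choice.
#' @param B number of permutations for the auto choice (default 20).
#' @param seed RNG seed for the permutations.
#' @return list with `expr` (cleaned matrix), `sv` (samples x k matrix,
#'   mean-zero columns), `k`, and `record` (singular values and permutation
#'   thresholds).
#' @export
removeSurrogateVariables <- function(expr, group, k = "auto", B = 20,
                                     seed = 1L) {
  group <- droplevels(as.factor(group))
  n <- ncol(expr)
  X <- stats::model.matrix(~group)
  resid <- t(stats::lm.fit(X, t(expr))$residuals)   # genes x samples
  maxK <- n - nlevels(group) - 1L
  if (!identical(k, "auto") && k >= n - nlevels(group))
    stop("k must be below the residual rank (", n - nlevels(group), ")")
  sv <- svd(t(resid), nv = 0)   # samples x genes: u spans sample space
  record <- list(singular = sv$d)
  if (identical(k, "auto")) {
    ## permuted singular values via the n x n Gram matrix (cheap for many
    ## genes): sv(t(M)) = sqrt(eig(crossprod(M))) for M genes x samples
    permD <- withSeed(seed, {
      vapply(seq_len(B), function(b) {
        perm <- t(apply(resid, 1, sample))
        d2 <- eigen(crossprod(perm), symmetric = TRUE,
                    only.values = TRUE)$values
        sqrt(pmax(d2, 0))[seq_along(sv$d)]
      }, numeric(length(sv$d)))
    })
    thr <- apply(permD, 1, stats::quantile, probs = 0.95)
    record$threshold <- thr
    keep <- sv$d > thr
    k <- if (all(keep)) length(keep) else which.min(keep) - 1L
    k <- min(k, maxK)
  }
  k <- as.integer(max(k, 0L))
  record$k <- k
  if (k == 0)
    return(list(expr = expr, sv = matrix(numeric(0), n, 0), k = 0L,
                record = record))
  SV <- sv$u[, seq_len(k), drop = FALSE]
  SV <- sweep(SV, 2, colMeans(SV))
  design <- cbind(X, SV)
  coefs <- stats::lm.fit(design, t(expr))$coefficients
  svPart <- SV %*% coefs[ncol(X) + seq_len(k), , drop = FALSE]
  cleaned <- expr - t(svPart)
  list(expr = cleaned, sv = SV, k = k, record = record)
}

#' Reference per-stratum training-set sizes of the emulated design
#'
#' The 202-sample training split: 80 CRC patients (stages I/II/III/IV =
#' 15/30/34/1) and 122 controls (HD 17, CD 24, UC 14, polyps 31, adenomas
#' 36); the complementary 120 samples form the internal validation set
#' (52 CRC at stages I/II/III = 10/18/24 plus 68 controls).
#'
#' @return named integer vector of training counts per group-stage stratum.
#' @export
referenceTrainCounts <- function() {
  c(HD = 17L, CD = 24L, UC = 14L, Polyp = 31L, Adenoma = 36L,
    "CRC-I" = 15L, "CRC-II" = 30L, "CRC-III" = 34L, "CRC-IV" = 1L)
}

## Stratum label of each sample: group, with CRC refined by stage.
.stratumOf <- function(md) {
  ifelse(md$group == "CRC", paste0("CRC-", md$stage), md$group)
}

#' Stratified train / validation split
#'
#' Splits samples into disjoint, exhaustive training and validation sets,
#' stratified by group-by-stage stratum. Either a fraction (scalar or named
#' per stratum) or exact per-stratum training counts may be requested;
#' fractions are honored within one sample per stratum. Strata with fewer
#' than 2 samples go wholly to training with a warning. Deterministic given
#' the seed.
#'
#' @param metadata data.frame / DataFrame with `sample_id`, `group`, `stage`.
#' @param trainFraction fraction of each stratum assigned to training
#'   (scalar, or named vector per stratum). Ignored when `trainCounts` given.
#' @param trainCounts named integer vector of exact training counts per
#'   stratum (e.g. [referenceTrainCounts()]).
#' @param seed RNG seed.
#' @return list with character vectors `train` and `validation` of sample
#'   ids.
#' @export
splitTrainValidation <- function(metadata, trainFraction = 0.627,
                                 trainCounts = NULL, seed = 1L) {
  md <- as.data.frame(metadata)
  strat <- .stratumOf(md)
  train <- character(0)
  withSeed(seed, {
    for (s in sort(unique(strat))) {
      ids <- md$sample_id[strat == s]
      if (!is.null(trainCounts)) {
        if (!s %in% names(trainCounts))
          stop("no training count given for stratum ", s)
        nTrain <- min(trainCounts[[s]], length(ids))
      } else {
        frac <- if (length(trainFraction) > 1) trainFraction[[s]] else trainFraction
        nTrain <- round(frac * length(ids))
      }
      if (length(ids) < 2) {
        warning("stratum ", s, " has fewer than 2 samples; placed in training")
        nTrain <- length(ids)
      }
      train <- c(train, sample(ids)[seq_len(nTrain)])
    }
  })
  list(train = md$sample_id[md$sample_id %in% train],
       validation = md$sample_id[!md$sample_id %in% train])
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: low-count filter, size factors, dispersion trend,
#' variance-stabilizing transformation, age-correlation filter, and
#' surrogate-variable removal. Every stage logs genes in/out.
#'
#' @param cohort a [TepCohort-class].
#' @param threshold low-count threshold (default 5).
#' @param ageAlpha significance level of the age filter.
#' @param svK surrogate-variable count or `"auto"`.
#' @param seed seed for the surrogate-variable permutations.
#' @return list with `expr` (cleaned expression matrix), `sizeFactors`,
#'   `dispersion` fit, `removedAgeGenes`, `sv` record, and `log` (per-stage
#'   gene/sample accounting).
#' @export
preprocessCohort <- function(cohort, threshold = 5, ageAlpha = 0.05,
                             svK = "auto", seed = 1L) {
  log <- list()
  note <- function(stage, ng, ns)
    log[[stage]] <<- list(genes = ng, samples = ns)
  note("input", nrow(cohort), ncol(cohort))
  filtered <- filterLowCounts(cohort, threshold)
  note("filter_low_counts", nrow(filtered), ncol(filtered))
  sf <- estimateSizeFactorsMoR(filtered, fallback = TRUE)
  fit <- fitDispersionTrend(filtered, sf)
  expr <- vstTransform(filtered, sf, fit)
  note("vst", nrow(expr), ncol(expr))
  md <- sampleInfo(cohort)
  af <- ageCorrelationFilter(expr, md$age)
  note("age_filter", nrow(af$expr), ncol(af$expr))
  sva <- removeSurrogateVariables(af$expr, md$group, k = svK,
                                  seed = childSeed(seed, "sva"))
  note("sva", nrow(sva$expr), ncol(sva$expr))
  list(expr = sva$expr, sizeFactors = sf, dispersion = fit,
       removedAgeGenes = af$removed, sv = sva[c("sv", "k", "record")],
       vstProvenance = attr(expr, "provenance"), log = log)
}
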