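#' Accessors for cohort and result objects
#'
#' `cohortCounts()` returns the integer count matrix, `sampleInfo()` the
#' clinical covariate table as a `DataFrame`, and `cohortTruth()` the planted
#' ground truth of a synthetic cohort (or `NULL` for a real one).
#' `panelGenes()` and `panelFitness()` read a [FeaturePanel-class];
#' `swarmTrajectory()` returns the per-iteration global-best record of a
#' [BpsoResult][FeaturePanel-class].
#'
#' @param x a `TepCohort`, `FeaturePanel` or `BpsoResult`.
#' @return See each function's description.
#' @name accessors
#' @examples
#' spec <- cohortSpec(nPerGroup = c(HD = 4, CD = 0, UC = 0, Polyp = 0,
#'                                  Adenoma = 0, "CRC-I" = 4, "CRC-II" = 0,
#'                                  "CRC-III" = 0, "CRC-IV" = 0),
#'                    nGenes = 50, seed = 1)
#' co <- simulateCohort(spec)
#' dim(cohortCounts(co))
#' head(sampleInfo(co))
NULL

#' @rdname accessors
#' @export
cohortCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname accessors
#' @export
sampleInfo <- function(x) SummarizedExperiment::colData(x)

#' @rdname accessors
#' @export
cohortTruth <- function(x) S4Vectors::metadata(x)$truth

#' @rdname accessors
#' @export
panelGenes <- function(x) {
  if (is(x, "BpsoResult")) x@panel@geneIds else x@geneIds
}

#' @rdname accessors
#' @export
panelFitness <- function(x) {
  if (is(x, "BpsoResult")) x@panel@fitness else x@fitness
}

#' @rdname accessors
#' @export
swarmTrajectory <- function(x) x@trajectory

#' @rdname accessors
#' @export
rocAucValue <- function(x) x@auc

#' @rdname accessors
#' @export
rocCi <- function(x) c(lower = x@ciLow, upper = x@ciHigh)

setMethod("show", "CohortSpec", function(object) {
  n <- sum(object@nPerGroup)
  cat(sprintf("CohortSpec: %d samples, %d genes (seed %d)\n",
              n, object@nGenes, object@seed))
  cat("  groups: ", paste(sprintf("%s=%d", names(object@nPerGroup),
                                  object@nPerGroup), collapse = " "), "\n")
  cat(sprintf("  signal: %d informative genes at |log2FC| %.2f (%.0f%% up)\n",
              object@nInformative, object@effectLog2FC, 100 * object@propUp))
  cat(sprintf("  confounding: %d age genes (%.3f log2/yr), %d batch(es) sd %.2f\n",
              object@nAgeGenes, object@ageSlope, object@nBatches, object@batchSD))
  cat(sprintf("  NB dispersion %.3f\n", object@dispersion))
})

setMethod("show", "TepCohort", function(object) {
  cat(sprintf("TepCohort: %d genes x %d samples\n", nrow(object), ncol(object)))
  grp <- table(sampleInfo(object)$group)
  cat("  groups: ", paste(sprintf("%s=%d", names(grp), grp), collapse = " "), "\n")
  if (!is.null(cohortTruth(object)))
    cat(sprintf("  synthetic truth: %d informative, %d age-correlated genes\n",
                length(cohortTruth(object)$informative_genes),
                length(cohortTruth(object)$age_genes)))
})

setMethod("show", "FeaturePanel", function(object) {
  cat(sprintf("FeaturePanel: %d genes, CV AUROC %.3f (iteration %d)\n",
              length(object@geneIds), object@fitness, object@iterationFound))
})

setMethod("show", "BpsoResult", function(object) {
  cat(sprintf("BpsoResult: %d iterations, %d fitness evaluations (%d cached)\n",
              max(object@trajectory$iteration), object@nEvaluations,
              object@nCacheHits))
  show(object@panel)
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUROC %.3f (95%% CI %.3f-%.3f), n+ = %d, n- = %d\n",
              object@auc, object@ciLow, object@ciHigh,
              sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "DispersionFit", function(object) {
  cat(sprintf("DispersionFit: %d genes, trend alpha(mu) = %.4f + %.3f/mu%s\n",
              length(object@alphaGene), object@a0, object@a1,
              if (object@poissonLike) " [Poisson-like]" else ""))
})
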