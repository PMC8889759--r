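#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Diagnosis groups of the cohort design. CRC samples additionally carry a
## TNM stage; all other groups have stage NA.
.GROUPS <- c("HD", "CD", "UC", "Polyp", "Adenoma", "CRC")
.STAGES <- c("I", "II", "III", "IV")
.SPEC_GROUPS <- c("HD", "CD", "UC", "Polyp", "Adenoma",
                  "CRC-I", "CRC-II", "CRC-III", "CRC-IV")

#' Specification of a synthetic platelet RNA cohort
#'
#' A `CohortSpec` fixes every parameter of the synthetic cohort generator:
#' the per-group sample sizes (CRC broken down by TNM stage), the size of the
#' gene universe, the planted group signal, age confounding, latent batch
#' structure, the negative-binomial dispersion and the library-size range.
#' Use [cohortSpec()] to construct one; the defaults emulate the 322-sample
#' colorectal study design the package targets.
#'
#' @slot nPerGroup named integer; samples per group, CRC split by stage.
#' @slot nGenes integer; genes in the simulated universe.
#' @slot nInformative integer; genes carrying a CRC-vs-rest effect.
#' @slot effectLog2FC numeric; magnitude of the planted log2 fold-change.
#' @slot propUp numeric in (0,1); fraction of informative genes upregulated.
#' @slot nAgeGenes integer; genes whose expression drifts with age.
#' @slot ageSlope numeric; log2-units of expression per year for age genes.
#' @slot nBatches integer >= 1; latent batches crossed with group.
#' @slot batchSD numeric >= 0; SD of the per-gene log2 batch offsets.
#' @slot dispersion numeric > 0; NB dispersion alpha in var = mu + alpha mu^2.
#' @slot baseMeanRange numeric(2); log-uniform range of baseline gene means.
#' @slot libsizeRange numeric(2); range of per-sample size-factor multipliers.
#' @slot seed integer; RNG seed, fully determines the cohort.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(
    nPerGroup     = "integer",
    nGenes        = "integer",
    nInformative  = "integer",
    effectLog2FC  = "numeric",
    propUp        = "numeric",
    nAgeGenes     = "integer",
    ageSlope      = "numeric",
    nBatches      = "integer",
    batchSD       = "numeric",
    dispersion    = "numeric",
    baseMeanRange = "numeric",
    libsizeRange  = "numeric",
    seed          = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!identical(sort(names(object@nPerGroup)), sort(.SPEC_GROUPS)))
    msg <- c(msg, sprintf("nPerGroup must be named exactly by: %s",
                          paste(.SPEC_GROUPS, collapse = ", ")))
  if (any(object@nPerGroup < 0)) msg <- c(msg, "group sizes must be >= 0")
  if (object@nGenes < 1) msg <- c(msg, "nGenes must be positive")
  if (object@nInformative < 0 || object@nInformative > object@nGenes)
    msg <- c(msg, "nInformative must lie in [0, nGenes]")
  if (object@nAgeGenes < 0 || object@nAgeGenes > object@nGenes)
    msg <- c(msg, "nAgeGenes must lie in [0, nGenes]")
  if (!is.finite(object@effectLog2FC)) msg <- c(msg, "effectLog2FC must be finite")
  if (object@propUp < 0 || object@propUp > 1) msg <- c(msg, "propUp must be in [0,1]")
  if (object@nBatches < 1) msg <- c(msg, "nBatches must be >= 1")
  if (object@batchSD < 0) msg <- c(msg, "batchSD must be >= 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (length(object@baseMeanRange) != 2 || any(object@baseMeanRange <= 0) ||
      diff(object@baseMeanRange) < 0)
    msg <- c(msg, "baseMeanRange must be an increasing positive pair")
  if (length(object@libsizeRange) != 2 || any(object@libsizeRange <= 0) ||
      diff(object@libsizeRange) < 0)
    msg <- c(msg, "libsizeRange must be an increasing positive pair")
  if (length(msg)) msg else TRUE
})

#' Platelet RNA cohort container
#'
#' A `TepCohort` is a [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding the gene-by-sample integer count matrix in the `"counts"` assay and
#' the per-sample clinical covariates (diagnosis group, TNM stage, age, sex,
#' serum CEA and CA199) as `colData`. For synthetic cohorts the planted ground
#' truth (informative genes and directions, age genes, batch assignment) is
#' kept in `metadata(x)$truth` and retrieved with [cohortTruth()].
#'
#' @exportClass TepCohort
setClass("TepCohort", contains = "SummarizedExperiment")

setValidity("TepCohort", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(is.na(cts))) msg <- c(msg, "counts must not contain NA")
  else {
    if (any(cts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(cts != round(cts))) msg <- c(msg, "counts must be integral")
  }
  if (anyDuplicated(rownames(object))) msg <- c(msg, "gene ids must be unique")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "sample ids must be unique")
  cd <- SummarizedExperiment::colData(object)
  need <- c("group", "stage", "age", "sex")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(c(msg, sprintf("colData lacks column(s): %s", paste(miss, collapse = ", "))))
  if (!all(cd$group %in% .GROUPS))
    msg <- c(msg, sprintf("group must be one of: %s", paste(.GROUPS, collapse = ", ")))
  crc <- cd$group == "CRC"
  if (any(crc & is.na(cd$stage)))
    msg <- c(msg, "CRC samples must carry a TNM stage")
  if (any(!crc & !is.na(cd$stage)))
    msg <- c(msg, "non-CRC samples must have stage NA")
  if (!all(is.na(cd$stage) | cd$stage %in% .STAGES))
    msg <- c(msg, "stage must be I, II, III, IV or NA")
  if (any(!is.na(cd$age) & cd$age <= 0)) msg <- c(msg, "age must be > 0")
  if (length(msg)) msg else TRUE
})

#' Result of a binary-PSO feature selection run
#'
#' `FeaturePanel` holds the selected gene identifiers together with the
#' cross-validated AUROC the panel achieved at selection time and the
#' iteration at which the swarm first reached it. `BpsoResult` additionally
#' carries the full swarm trajectory (global-best fitness per iteration), the
#' resolved configuration, and evaluation accounting.
#'
#' @slot geneIds character; selected gene identifiers, in input order.
#' @slot fitness numeric; CV AUROC of the panel at selection time.
#' @slot iterationFound integer; iteration at which this panel became gbest
#'   (0 = initial swarm).
#' @slot configHash character; fingerprint of the resolved configuration.
#' @aliases BpsoResult-class
#' @exportClass FeaturePanel
setClass("FeaturePanel",
  representation(geneIds = "character", fitness = "numeric",
                 iterationFound = "integer", configHash = "character")
)

setValidity("FeaturePanel", function(object) {
  msg <- character()
  if (length(object@geneIds) == 0) msg <- c(msg, "panel must be nonempty")
  if (anyDuplicated(object@geneIds)) msg <- c(msg, "panel gene ids must be unique")
  if (length(object@fitness) != 1 || is.na(object@fitness) ||
      object@fitness < 0 || object@fitness > 1)
    msg <- c(msg, "fitness must be a single value in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @exportClass BpsoResult
setClass("BpsoResult",
  representation(panel = "FeaturePanel", trajectory = "data.frame",
                 gbestMask = "logical", geneIds = "character",
                 config = "list", nEvaluations = "integer",
                 nCacheHits = "integer")
)

setValidity("BpsoResult", function(object) {
  msg <- character()
  if (length(object@gbestMask) != length(object@geneIds))
    msg <- c(msg, "gbestMask length must equal geneIds length")
  fit <- object@trajectory$gbestFit
  if (length(fit) && any(diff(fit) < 0))
    msg <- c(msg, "gbest fitness must be non-decreasing over iterations")
  if (length(msg)) msg else TRUE
})

#' Empirical ROC curve with AUROC and DeLong interval
#'
#' Produced by [rocAuc()]. The `fpr`/`tpr` arrays trace the empirical ROC
#' (ties grouped, so the trapezoidal area equals the Mann-Whitney U-statistic
#' normalization exactly); `auc` is that common value, and `ciLow`/`ciHigh`
#' bracket it with the DeLong 95% interval.
#'
#' @slot scores numeric; classifier decision values.
#' @slot labels integer; 0/1 class labels aligned with `scores`.
#' @slot fpr,tpr numeric; ROC coordinates from (0,0) to (1,1).
#' @slot thresholds numeric; score cutoffs, one per ROC vertex.
#' @slot auc numeric; area under the curve.
#' @slot ciLow,ciHigh numeric; DeLong 95% confidence bounds.
#' @slot delongVar numeric; DeLong variance of the AUC estimate.
#' @exportClass RocCurve
setClass("RocCurve",
  representation(scores = "numeric", labels = "integer",
                 fpr = "numeric", tpr = "numeric", thresholds = "numeric",
                 auc = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 delongVar = "numeric")
)

setValidity("RocCurve", function(object) {
  msg <- character()
  if (any(diff(object@fpr) < 0) || any(diff(object@tpr) < 0))
    msg <- c(msg, "fpr and tpr must be nondecreasing")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Per-gene dispersion estimates with a 1/mu trend
#'
#' Method-of-moments negative-binomial dispersions on size-factor-normalized
#' counts, plus robust trend coefficients of alpha(mu) = a0 + a1/mu. Feeds
#' the closed-form variance-stabilizing transformation ([vstTransform()]).
#'
#' @slot alphaGene numeric; per-gene dispersion estimates (>= 0), named.
#' @slot geneMeans numeric; normalized per-gene means, named.
#' @slot a0,a1 numeric; trend coefficients.
#' @slot poissonLike logical; TRUE when every gene looked Poisson (all
#'   alpha-hat zero) and the trend degenerates to a0 = a1 = 0.
#' @exportClass DispersionFit
setClass("DispersionFit",
  representation(alphaGene = "numeric", geneMeans = "numeric",
                 a0 = "numeric", a1 = "numeric", poissonLike = "logical")
)

setValidity("DispersionFit", function(object) {
  msg <- character()
  if (any(object@alphaGene < 0)) msg <- c(msg, "dispersions must be >= 0")
  if (object@a0 < 0) msg <- c(msg, "a0 must be >= 0")
  if (length(msg)) msg else TRUE
})
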