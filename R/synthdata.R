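## Synthetic cohort generation.
##
## The generator emulates the statistical structure the downstream analysis
## assumes: negative-binomial counts over a log-uniform range of baseline
## means, a planted CRC-vs-rest signal in a subset of genes (mostly
## downregulated, as in platelet transcriptomes of cancer patients),
## age-correlated genes, a latent batch variable crossed with diagnosis, and
## per-sample library-size multipliers.

## Per-group age distributions (mean, SD, min, max in years) of the cohort
## design emulated by the defaults.
.AGE_TABLE <- data.frame(
  group = c("HD", "CRC", "CD", "UC", "Polyp", "Adenoma"),
  mean  = c(54.6, 59.3, 30.6, 42.9, 56.2, 54.9),
  sd    = c(11.3, 12.5, 13.2, 11.9, 12.9, 10.1),
  lo    = c(31, 24, 15, 18, 18, 30),
  hi    = c(72, 89, 69, 65, 85, 76)
)

## Serum marker locations (log2 scale): CRC sits higher than controls for
## both CEA and CA199.
.SERUM <- list(
  cea   = c(control = 0.77, crc = 2.08, sd = 1.5),
  ca199 = c(control = 2.68, crc = 3.16, sd = 1.5)
)

.MALE_PROB <- c(crc = 0.606, control = 0.327)

#' Default per-group sample sizes of the emulated cohort design
#'
#' 322 samples: 21 healthy donors, 40 Crohn's disease, 22 ulcerative colitis,
#' 48 polyps, 59 adenomas and 132 colorectal cancers split over TNM stages
#' I-IV as 25/48/58/1.
#'
#' @return named integer vector over the nine design strata.
#' @export
defaultGroupSizes <- function() {
  c(HD = 21L, CD = 40L, UC = 22L, Polyp = 48L, Adenoma = 59L,
    "CRC-I" = 25L, "CRC-II" = 48L, "CRC-III" = 58L, "CRC-IV" = 1L)
}

#' Construct a synthetic-cohort specification
#'
#' Builds a validated [CohortSpec-class]. Defaults reproduce the emulated
#' study design: 322 samples across six diagnosis groups, 16300 genes of
#' which 863 carry a CRC effect (20% up, 80% down), 300 age-correlated genes,
#' two latent batches crossed with diagnosis, and NB dispersion 0.2.
#'
#' @param nPerGroup named integer vector over
#'   `c("HD","CD","UC","Polyp","Adenoma","CRC-I","CRC-II","CRC-III","CRC-IV")`.
#' @param nGenes number of genes to simulate.
#' @param nInformative number of genes with a CRC-vs-rest effect.
#' @param effectLog2FC magnitude of the planted log2 fold-change.
#' @param propUp fraction of informative genes upregulated in CRC.
#' @param nAgeGenes number of age-correlated genes (disjoint from the
#'   informative set).
#' @param ageSlope log2 expression units per year for age genes.
#' @param nBatches number of latent batches (>= 1; 1 disables batch effects).
#' @param batchSD SD of per-gene log2 batch offsets.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param baseMeanRange log-uniform sampling range for baseline gene means.
#' @param libsizeRange range of per-sample size-factor multipliers.
#' @param seed integer seed; the cohort is a deterministic function of the
#'   spec including this seed.
#' @return a [CohortSpec-class] object.
#' @seealso [simulateCohort()]
#' @export
cohortSpec <- function(nPerGroup = defaultGroupSizes(),
                       nGenes = 16300L,
                       nInformative = 863L,
                       effectLog2FC = 1.0,
                       propUp = 0.2,
                       nAgeGenes = 300L,
                       ageSlope = 0.02,
                       nBatches = 2L,
                       batchSD = 0.25,
                       dispersion = 0.2,
                       baseMeanRange = c(2, 5000),
                       libsizeRange = c(0.5, 2),
                       seed = 1L) {
  new("CohortSpec",
      nPerGroup = as.integer(nPerGroup[.SPEC_GROUPS]) |>
        stats::setNames(.SPEC_GROUPS),
      nGenes = as.integer(nGenes), nInformative = as.integer(nInformative),
      effectLog2FC = as.numeric(effectLog2FC), propUp = as.numeric(propUp),
      nAgeGenes = as.integer(nAgeGenes), ageSlope = as.numeric(ageSlope),
      nBatches = as.integer(nBatches), batchSD = as.numeric(batchSD),
      dispersion = as.numeric(dispersion),
      baseMeanRange = as.numeric(baseMeanRange),
      libsizeRange = as.numeric(libsizeRange), seed = as.integer(seed))
}

#' Assemble a cohort container from its parts
#'
#' @param counts integer gene-by-sample matrix with row and column names.
#' @param metadata data.frame or DataFrame with columns `sample_id`, `group`,
#'   `stage`, `age`, `sex` and optionally `cea`, `ca199`; one row per column
#'   of `counts`, matched by `sample_id`.
#' @param truth optional ground-truth list for synthetic cohorts.
#' @return a validated [TepCohort-class].
#' @export
TepCohort <- function(counts, metadata, truth = NULL) {
  metadata <- as.data.frame(metadata)
  if (!identical(colnames(counts), as.character(metadata$sample_id)))
    stop("metadata sample_id must match count matrix columns in order")
  cd <- S4Vectors::DataFrame(metadata, row.names = metadata$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  obj <- new("TepCohort", se)
  if (!is.null(truth)) S4Vectors::metadata(obj)$truth <- truth
  validObject(obj)
  obj
}

#' Simulate a synthetic platelet RNA cohort
#'
#' Draws a gene-by-sample count matrix from the negative-binomial model
#' \deqn{K_{gj} \sim NB(\mu_{gj}, \alpha), \quad
#'   \mu_{gj} = s_j\,\mu_g\,2^{\beta_g I[\mathrm{CRC}_j]}\,
#'   2^{\gamma_g (a_j - \bar a)}\, 2^{\delta_{g,b_j}}}
#' where \eqn{s_j} is the per-sample library-size multiplier, \eqn{\mu_g}
#' the baseline mean, \eqn{\beta_g = \pm}`effectLog2FC` for informative
#' genes, \eqn{\gamma_g} = `ageSlope` for age genes, and
#' \eqn{\delta_{g,b}} the latent batch offset. Ages are drawn per diagnosis
#' group from truncated normals matching the emulated cohort; serum CEA and
#' CA199 are log2-normal with a higher location in CRC. The result is a
#' deterministic function of the spec (including its seed).
#'
#' @param spec a [CohortSpec-class] from [cohortSpec()].
#' @return a [TepCohort-class]; `cohortTruth()` on it returns the planted
#'   ground truth (informative genes with directions, age genes, batch
#'   assignment).
#' @examples
#' spec <- cohortSpec(nPerGroup = c(HD = 10, CD = 0, UC = 0, Polyp = 0,
#'                                  Adenoma = 0, "CRC-I" = 10, "CRC-II" = 0,
#'                                  "CRC-III" = 0, "CRC-IV" = 0),
#'                    nGenes = 200, nInformative = 10, nAgeGenes = 5, seed = 7)
#' co <- simulateCohort(spec)
#' co
#' @export
simulateCohort <- function(spec) {
  validObject(spec)
  nPer <- spec@nPerGroup
  n <- sum(nPer)
  if (n == 0) stop("cohort has zero samples")
  withSeed(spec@seed, {
    ## sample frame -----------------------------------------------------
    stratum <- rep(names(nPer), nPer)
    group <- ifelse(startsWith(stratum, "CRC"), "CRC", stratum)
    stage <- ifelse(startsWith(stratum, "CRC"), sub("^CRC-", "", stratum), NA)
    sampleId <- sprintf("S%03d", seq_len(n))
    age <- numeric(n)
    for (g in unique(group)) {
      row <- .AGE_TABLE[.AGE_TABLE$group == g, ]
      idx <- which(group == g)
      age[idx] <- round(rtruncnorm(length(idx), row$mean, row$sd, row$lo, row$hi))
    }
    isCrc <- group == "CRC"
    pMale <- ifelse(isCrc, .MALE_PROB["crc"], .MALE_PROB["control"])
    sex <- ifelse(stats::runif(n) < pMale, "M", "F")
    cea <- 2^stats::rnorm(n, ifelse(isCrc, .SERUM$cea["crc"],
                                    .SERUM$cea["control"]), .SERUM$cea["sd"])
    ca199 <- 2^stats::rnorm(n, ifelse(isCrc, .SERUM$ca199["crc"],
                                      .SERUM$ca199["control"]),
                            .SERUM$ca199["sd"])
    ## latent batches, crossed with group: deal within each group -------
    batch <- integer(n)
    for (g in unique(group)) {
      idx <- sample(which(group == g))
      batch[idx] <- rep_len(seq_len(spec@nBatches), length(idx))
    }
    ## gene frame -------------------------------------------------------
    geneId <- sprintf("G%05d", seq_len(spec@nGenes))
    lr <- log(spec@baseMeanRange)
    baseMean <- exp(stats::runif(spec@nGenes, lr[1], lr[2]))
    pick <- sample(spec@nGenes, spec@nInformative + spec@nAgeGenes)
    infIdx <- pick[seq_len(spec@nInformative)]
    ageIdx <- pick[spec@nInformative + seq_len(spec@nAgeGenes)]
    nUp <- round(spec@propUp * spec@nInformative)
    dirUp <- rep(FALSE, spec@nInformative)
    if (nUp > 0) dirUp[sample(spec@nInformative, nUp)] <- TRUE
    beta <- numeric(spec@nGenes)
    beta[infIdx] <- ifelse(dirUp, spec@effectLog2FC, -spec@effectLog2FC)
    gamma <- numeric(spec@nGenes)
    gamma[ageIdx] <- spec@ageSlope
    ## batch offsets: batch 1 is the reference
    delta <- matrix(0, spec@nGenes, spec@nBatches)
    if (spec@nBatches > 1 && spec@batchSD > 0)
      delta[, -1] <- stats::rnorm(spec@nGenes * (spec@nBatches - 1),
                                  0, spec@batchSD)
    ## counts -----------------------------------------------------------
    ll <- log(spec@libsizeRange)
    sizeFac <- exp(stats::runif(n, ll[1], ll[2]))
    ageCentered <- age - 50
    log2mu <- outer(log2(baseMean), log2(sizeFac), "+") +
      outer(beta, as.numeric(isCrc)) +
      outer(gamma, ageCentered) +
      delta[, batch, drop = FALSE]
    counts <- matrix(
      stats::rnbinom(spec@nGenes * n, mu = 2^log2mu, size = 1 / spec@dispersion),
      nrow = spec@nGenes, dimnames = list(geneId, sampleId))
    storage.mode(counts) <- "integer"
    md <- data.frame(sample_id = sampleId, group = group, stage = stage,
                     age = age, sex = sex, cea = cea, ca199 = ca199,
                     stringsAsFactors = FALSE)
    truth <- list(
      informative_genes = geneId[infIdx],
      direction = stats::setNames(ifelse(dirUp, "up", "down"), geneId[infIdx]),
      age_genes = geneId[ageIdx],
      batch = stats::setNames(batch, sampleId),
      true_group = stats::setNames(group, sampleId))
    TepCohort(counts, md, truth)
  })
}

#' Write / read a cohort as plain-text files
#'
#' `writeCohort()` stores a cohort as `counts.tsv` (first column `gene_id`,
#' then one integer column per sample), `metadata.csv` (columns `sample_id`,
#' `group`, `stage`, `age`, `sex`, `cea`, `ca199`) and, when ground truth is
#' present, `truth.json`. `readCohort()` restores the identical object;
#' the round trip preserves ordering byte-for-byte.
#'
#' @param cohort a [TepCohort-class].
#' @param dir directory to write to / read from (created if needed).
#' @return `writeCohort()` returns `dir` invisibly; `readCohort()` a
#'   [TepCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- cohortCounts(cohort)
  df <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
  utils::write.table(df, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- as.data.frame(sampleInfo(cohort))
  cols <- c("sample_id", "group", "stage", "age", "sex", "cea", "ca199")
  for (cc in setdiff(cols, colnames(md))) md[[cc]] <- NA
  md <- md[, cols]
  ## serum markers at full precision so the text round trip is exact
  for (cc in c("age", "cea", "ca199"))
    if (is.numeric(md[[cc]]))
      md[[cc]] <- ifelse(is.na(md[[cc]]), NA, sprintf("%.17g", md[[cc]]))
  utils::write.csv(md, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  truth <- cohortTruth(cohort)
  if (!is.null(truth)) {
    ## named vectors go through as.list so names survive JSON round trip
    tr <- list(informative_genes = truth$informative_genes,
               direction = as.list(truth$direction),
               age_genes = truth$age_genes,
               batch = as.list(truth$batch),
               true_group = as.list(truth$true_group))
    jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  cf <- file.path(dir, "counts.tsv")
  mf <- file.path(dir, "metadata.csv")
  if (!file.exists(cf)) stop("missing counts.tsv in ", dir)
  if (!file.exists(mf)) stop("missing metadata.csv in ", dir)
  tab <- utils::read.delim(cf, check.names = FALSE,
                           colClasses = c(gene_id = "character"))
  cts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(cts) <- tab$gene_id
  bad <- which(is.na(cts) | cts < 0 | cts != round(cts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts.tsv line %d (gene %s): invalid count '%s'",
                 bad[1, 1] + 1L, rownames(cts)[bad[1, 1]],
                 cts[bad[1, , drop = FALSE]]))
  storage.mode(cts) <- "integer"
  md <- utils::read.csv(mf, stringsAsFactors = FALSE,
                        colClasses = c(sample_id = "character",
                                       stage = "character",
                                       age = "numeric", cea = "numeric",
                                       ca199 = "numeric"))
  md$stage[!is.na(md$stage) & md$stage == ""] <- NA
  truthFile <- file.path(dir, "truth.json")
  truth <- NULL
  if (file.exists(truthFile)) {
    tr <- jsonlite::read_json(truthFile, simplifyVector = TRUE)
    truth <- list(
      informative_genes = as.character(tr$informative_genes),
      direction = unlist(tr$direction),
      age_genes = as.character(tr$age_genes),
      batch = unlist(tr$batch),
      true_group = unlist(tr$true_group))
  }
  TepCohort(cts, md, truth)
}
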