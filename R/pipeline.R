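## End-to-end orchestration: preprocess -> split -> swarm feature selection
## (training only) -> final classifier -> LOOCV on training + validation
## evaluation, with per-stage provenance and a JSON report writer.

#' Class labels for a classification task
#'
#' Maps sample metadata to the labels of the three supported tasks:
#' `"cancer-vs-control"` (CRC vs everything else),
#' `"hd-vs-noncancer-vs-crc"` (healthy donors vs noncancerous diseases vs
#' CRC), and `"stage"` (early, I-II, vs late, III-IV, among CRC samples
#' only; returns NA for non-CRC samples).
#'
#' @param metadata data.frame / DataFrame with `group` and `stage`.
#' @param task one of the three task names.
#' @return character vector of labels (the last alphabetical level is the
#'   positive class for binary tasks: `"crc"` and `"late"`).
#' @export
taskLabels <- function(metadata,
                       task = c("cancer-vs-control", "hd-vs-noncancer-vs-crc",
                                "stage")) {
  task <- match.arg(task)
  md <- as.data.frame(metadata)
  switch(task,
    "cancer-vs-control" = ifelse(md$group == "CRC", "crc", "control"),
    "hd-vs-noncancer-vs-crc" = ifelse(md$group == "CRC", "crc",
                                      ifelse(md$group == "HD", "hd",
                                             "noncancer")),
    "stage" = ifelse(md$group != "CRC", NA_character_,
                     ifelse(md$stage %in% c("I", "II"), "early", "late")))
}

#' Run the full classification pipeline on a cohort
#'
#' Executes, in order: preprocessing ([preprocessCohort()]), a stratified
#' train/validation split, binary-PSO feature selection on the training set
#' only ([runBpso()]), final SVM training ([buildFinalClassifier()]),
#' leave-one-out evaluation of the training set, and held-out evaluation of
#' the validation set, including per-stage sensitivities for the
#' cancer-vs-control task. Every stochastic stage derives its seed from the
#' global `seed`, so reruns with an identical configuration are
#' bit-identical.
#'
#' @param cohort a [TepCohort-class].
#' @param task classification task, see [taskLabels()].
#' @param psoCfg a [psoConfig()] list (its `seed` is overridden by `seed`).
#' @param trainCounts optional exact per-stratum training counts
#'   (e.g. [referenceTrainCounts()]); otherwise `trainFraction` is used.
#' @param trainFraction fraction of each stratum used for training.
#' @param useSerumMarkers if `TRUE`, standardized CEA and CA199 columns are
#'   appended to the panel features of the final classifier.
#' @param threshold,ageAlpha,svK preprocessing settings, see
#'   [preprocessCohort()].
#' @param seed global seed; fans out to per-stage child seeds.
#' @return a `"tepRunReport"` list: `panel`, `bpso`, `classifier`,
#'   `training` (LOOCV roc + confusion + per-stage sensitivities),
#'   `validation` (ditto), `preprocess` log, `split`, and `config` echo.
#' @export
runPipeline <- function(cohort, task = "cancer-vs-control",
                        psoCfg = psoConfig(), trainCounts = NULL,
                        trainFraction = 0.627, useSerumMarkers = FALSE,
                        threshold = 5, ageAlpha = 0.05, svK = "auto",
                        seed = 1L) {
  md <- as.data.frame(sampleInfo(cohort))
  labels <- taskLabels(md, task)
  keep <- !is.na(labels)
  if (length(unique(labels[keep])) < 2)
    stop("task '", task, "' needs at least two label classes in the cohort")
  cohort <- cohort[, keep]
  md <- md[keep, , drop = FALSE]
  labels <- labels[keep]

  prep <- preprocessCohort(cohort, threshold = threshold, ageAlpha = ageAlpha,
                           svK = svK, seed = childSeed(seed, "preprocess"))
  split <- splitTrainValidation(md, trainFraction = trainFraction,
                                trainCounts = trainCounts,
                                seed = childSeed(seed, "split"))
  trIdx <- md$sample_id %in% split$train
  exprTr <- prep$expr[, trIdx, drop = FALSE]
  exprVa <- prep$expr[, !trIdx, drop = FALSE]
  yTr <- labels[trIdx]; yVa <- labels[!trIdx]

  psoCfg$seed <- childSeed(seed, "bpso")
  bpso <- runBpso(exprTr, yTr, psoCfg)
  panel <- bpso@panel

  extraTr <- extraVa <- NULL
  if (useSerumMarkers) {
    extraTr <- cbind(cea = log2(md$cea[trIdx] + 1),
                     ca199 = log2(md$ca199[trIdx] + 1))
    extraVa <- cbind(cea = log2(md$cea[!trIdx] + 1),
                     ca199 = log2(md$ca199[!trIdx] + 1))
  }
  binary <- length(unique(yTr)) == 2
  clf <- buildFinalClassifier(exprTr, yTr, panel, extra = extraTr,
                              kernel = psoCfg$kernel, cost = psoCfg$cost)

  training <- validation <- NULL
  if (binary) {
    pos <- sort(unique(yTr))[2]
    training <- loocvEvaluate(exprTr, yTr, panel = panel, extra = extraTr,
                              kernel = psoCfg$kernel, cost = psoCfg$cost)
    if (task == "cancer-vs-control")
      training$byStage <- sensitivityByStratum(
        training$predicted, as.integer(yTr == pos), md$stage[trIdx])
    if (length(unique(yVa)) == 2) {
      sVa <- predictScores(clf, exprVa, extra = extraVa)
      pVa <- as.integer(sVa > 0)
      y01 <- as.integer(yVa == pos)
      validation <- list(
        roc = rocAuc(sVa, y01),
        confusion = confusionMetrics(tp = sum(pVa == 1 & y01 == 1),
                                     fn = sum(pVa == 0 & y01 == 1),
                                     fp = sum(pVa == 1 & y01 == 0),
                                     tn = sum(pVa == 0 & y01 == 0)),
        scores = sVa, predicted = pVa)
      if (task == "cancer-vs-control")
        validation$byStage <- sensitivityByStratum(pVa, y01, md$stage[!trIdx])
    }
  } else {
    ## multiclass: Hand-Till M on softmaxed one-vs-rest scores
    training <- list(
      multiclass = handTillMulticlassAuc(predictScores(clf, exprTr), yTr))
    if (length(unique(yVa)) >= 2)
      validation <- list(
        multiclass = handTillMulticlassAuc(
          predictScores(clf, exprVa, extra = extraVa), yVa))
  }
  structure(list(task = task, panel = panel, bpso = bpso, classifier = clf,
                 training = training, validation = validation,
                 preprocess = prep[c("sizeFactors", "removedAgeGenes",
                                     "vstProvenance", "log")],
                 svK = prep$sv$k, split = split,
                 config = list(psoCfg = psoCfg, threshold = threshold,
                               ageAlpha = ageAlpha, svK = svK, seed = seed,
                               useSerumMarkers = useSerumMarkers)),
            class = "tepRunReport")
}

#' @export
print.tepRunReport <- function(x, ...) {
  cat(sprintf("tepRunReport: task %s\n", x$task))
  show(x$panel)
  if (!is.null(x$training$roc))
    cat(sprintf("  training LOOCV AUROC %.3f\n", x$training$roc@auc))
  if (!is.null(x$training$multiclass))
    cat(sprintf("  training Hand-Till M %.3f\n", x$training$multiclass$M))
  if (!is.null(x$validation$roc))
    cat(sprintf("  validation AUROC %.3f\n", x$validation$roc@auc))
  if (!is.null(x$validation$multiclass))
    cat(sprintf("  validation Hand-Till M %.3f\n", x$validation$multiclass$M))
  invisible(x)
}

#' Evaluate a frozen panel on an unseen cohort
#'
#' Retrains the final SVM on the training cohort restricted to the panel
#' genes available in the test cohort and scores the test samples. By
#' default any missing panel gene fails the evaluation; with
#' `onMissing = "drop"` up to `maxMissingFrac` of the panel may be dropped
#' (reported in the result).
#'
#' @param panel [FeaturePanel-class], [BpsoResult][FeaturePanel-class] or
#'   character gene ids.
#' @param trainExpr,trainLabels training expression (genes x samples) and
#'   two-level labels.
#' @param testExpr,testLabels test cohort expression and labels.
#' @param onMissing `"fail"` (default) or `"drop"`.
#' @param maxMissingFrac maximum droppable fraction of the panel (0.2).
#' @param kernel,cost SVM settings.
#' @return list with `roc`, `confusion`, `scores`, `missingGenes`.
#' @export
evaluatePanel <- function(panel, trainExpr, trainLabels, testExpr, testLabels,
                          onMissing = c("fail", "drop"), maxMissingFrac = 0.2,
                          kernel = "radial", cost = 1) {
  onMissing <- match.arg(onMissing)
  genes <- if (is.character(panel)) panel else panelGenes(panel)
  if (length(genes) == 0) stop("empty panel")
  miss <- setdiff(genes, intersect(rownames(trainExpr), rownames(testExpr)))
  if (length(miss) / length(genes) > maxMissingFrac)
    stop(sprintf("%d/%d panel genes missing from the cohort (limit %.0f%%)",
                 length(miss), length(genes), 100 * maxMissingFrac))
  if (length(miss) > 0 && onMissing == "fail")
    stop("panel genes missing from the cohort: ",
         paste(utils::head(miss, 5), collapse = ", "),
         " (use onMissing = \"drop\")")
  genes <- setdiff(genes, miss)
  y <- binaryLabels(trainLabels)
  clf <- buildFinalClassifier(trainExpr, y, genes, kernel = kernel,
                              cost = cost)
  s <- predictScores(clf, testExpr)
  yTe <- binaryLabels(testLabels)
  pred <- as.integer(s > 0)
  list(roc = rocAuc(s, yTe),
       confusion = confusionMetrics(tp = sum(pred == 1 & yTe == 1),
                                    fn = sum(pred == 0 & yTe == 1),
                                    fp = sum(pred == 1 & yTe == 0),
                                    tn = sum(pred == 0 & yTe == 0)),
       scores = s, missingGenes = miss)
}

#' Write a run report as JSON
#'
#' Serializes the scalar outcomes of a [runPipeline()] report (panel, AUROCs
#' with intervals, confusion metrics, per-stage sensitivities, preprocessing
#' log and resolved configuration) to a JSON file.
#'
#' @param report a `"tepRunReport"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  rocJson <- function(rc) if (is.null(rc)) NULL else
    list(auc = rc@auc, ciLow = rc@ciLow, ciHigh = rc@ciHigh)
  confJson <- function(cm) if (is.null(cm)) NULL else
    list(tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
         accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv,
         kappa = cm$kappa, f1 = cm$f1)
  sideJson <- function(side) if (is.null(side)) NULL else
    list(roc = rocJson(side$roc), confusion = confJson(side$confusion),
         byStage = side$byStage,
         multiclassM = if (is.null(side$multiclass)) NULL
                       else side$multiclass$M)
  out <- list(
    task = report$task,
    panel = list(genes = panelGenes(report$panel),
                 fitness = panelFitness(report$panel)),
    training = sideJson(report$training),
    validation = sideJson(report$validation),
    preprocess = list(log = report$preprocess$log,
                      vst = report$preprocess$vstProvenance,
                      removedAgeGenes = report$preprocess$removedAgeGenes,
                      svK = report$svK),
    split = report$split,
    config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
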