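## Binary particle swarm optimization over gene-inclusion bitmasks.
##
## Each particle is a bit vector over the gene universe; its velocity is a
## real vector mapped through the logistic function to per-bit inclusion
## probabilities. Fitness is the stratified cross-validated AUROC of an SVM
## restricted to the selected genes. The velocity update is
##   v_d <- v_d + phi1_d (pbest_d - x_d) + phi2_d (gbest_d - x_d)
## with phi ~ Uniform(0, phiMax) drawn per particle, per term and per
## dimension, followed by clamping to [-vMax, vMax]; the position update sets
## each bit to 1 with probability S(v_d).

#' Logistic transfer of a velocity to a bit-inclusion probability
#'
#' \eqn{S(v) = 1 / (1 + e^{-v})}, mapping any finite velocity into (0, 1).
#'
#' @param v numeric vector of velocities.
#' @return probabilities in (0, 1), same length as `v`.
#' @examples
#' sigmoidTransfer(0)        # 0.5
#' sigmoidTransfer(log(3))   # 0.75
#' @export
sigmoidTransfer <- function(v) 1 / (1 + exp(-v))

#' One velocity update of a particle
#'
#' Applies the swarm velocity rule with attraction toward the particle's
#' personal best and the global best, then clamps to `[-vMax, vMax]`.
#'
#' @param v current velocity vector.
#' @param x current bit vector (0/1).
#' @param pbest personal-best bit vector.
#' @param gbest global-best bit vector.
#' @param phi1,phi2 nonnegative random coefficient vectors (one per
#'   dimension) for the personal and global attraction terms.
#' @param vMax velocity clamp (default 4).
#' @return the updated, clamped velocity vector.
#' @export
updateVelocity <- function(v, x, pbest, gbest, phi1, phi2, vMax = 4) {
  len <- length(v)
  if (any(c(length(x), length(pbest), length(gbest), length(phi1),
            length(phi2)) != len))
    stop("velocity update: vector lengths differ")
  if (any(phi1 < 0) || any(phi2 < 0)) stop("phi draws must be nonnegative")
  pmin(pmax(v + phi1 * (pbest - x) + phi2 * (gbest - x), -vMax), vMax)
}

#' One position update of a particle
#'
#' Sets each bit to 1 independently with probability `sigmoidTransfer(v)`,
#' using the supplied uniform draws. A particle is never left empty: if all
#' bits come out 0, the bit with the largest inclusion probability is forced
#' on (ties broken by the first index), keeping the fitness contract
#' (empty masks score 0) from trapping the swarm.
#'
#' @param v velocity vector.
#' @param u uniform(0,1) draws, one per dimension; drawn internally when
#'   omitted.
#' @return integer 0/1 vector.
#' @export
updatePosition <- function(v, u = stats::runif(length(v))) {
  x <- as.integer(u < sigmoidTransfer(v))
  if (!any(x == 1L)) x[which.max(v)] <- 1L
  x
}

#' Swarm-search configuration
#'
#' Collects every tunable of [runBpso()] with its default. The defaults run
#' 100 iterations of a 50-particle swarm with 10-fold stratified CV fitness
#' and an RBF SVM; initialization is sparse (each bit on with probability
#' 0.05) and ties in fitness prefer smaller panels.
#'
#' @param nParticles swarm size.
#' @param nIterations number of velocity/position/fitness sweeps.
#' @param phiMax upper bound of the uniform attraction coefficients.
#' @param vMax velocity clamp.
#' @param initProb Bernoulli probability of a bit being on at initialization.
#' @param vInit velocity initialization: `"prior"` (default) starts every
#'   velocity at `logit(initProb)`, so with no attraction the position
#'   distribution is stationary at the sparse prior; `"zero"` starts at 0,
#'   under which the first resampling flips each bit with probability 1/2.
#' @param cvFolds stratified CV folds of the fitness.
#' @param kernel SVM kernel, `"radial"` or `"linear"`.
#' @param cost SVM cost parameter.
#' @param seed RNG seed; fully determines the run.
#' @param parsimonyTiebreak prefer fewer genes at exactly equal fitness.
#' @return a named list of resolved settings.
#' @export
psoConfig <- function(nParticles = 50L, nIterations = 100L, phiMax = 2,
                      vMax = 4, initProb = 0.05,
                      vInit = c("prior", "zero"), cvFolds = 10L,
                      kernel = c("radial", "linear"), cost = 1,
                      seed = 1L, parsimonyTiebreak = TRUE) {
  kernel <- match.arg(kernel)
  vInit <- match.arg(vInit)
  stopifnot(nParticles >= 1, nIterations >= 0, phiMax >= 0, vMax > 0,
            initProb > 0, initProb < 1, cvFolds >= 2, cost > 0)
  list(nParticles = as.integer(nParticles),
       nIterations = as.integer(nIterations), phiMax = phiMax, vMax = vMax,
       initProb = initProb, vInit = vInit, cvFolds = as.integer(cvFolds),
       kernel = kernel, cost = cost, seed = as.integer(seed),
       parsimonyTiebreak = isTRUE(parsimonyTiebreak))
}

## Standardize train columns, apply to test; constant columns get sd 1.
.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sd <- apply(Xtr, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sd, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sd, "/"))
}

## Fit an SVM on (Xtr, ytr in {0,1}) and return decision values for Xte,
## oriented so larger = more likely class 1.
.svmDecision <- function(Xtr, ytr, Xte, kernel, cost) {
  z <- .standardize(Xtr, Xte)
  yf <- factor(ytr, levels = c(0L, 1L))
  fit <- e1071::svm(z$train, yf, kernel = kernel, cost = cost, scale = FALSE)
  pr <- stats::predict(fit, z$test, decision.values = TRUE)
  dv <- attr(pr, "decision.values")[, 1]
  ## libsvm orients the decision column "A/B" with positive values for A
  if (strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1] == "0")
    dv <- -dv
  unname(dv)
}

## Pooled held-out decision values over CV folds for the selected columns.
.cvDecisionValues <- function(X, y, folds, kernel, cost) {
  dv <- numeric(length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    dv[te] <- .svmDecision(X[!te, , drop = FALSE], y[!te],
                           X[te, , drop = FALSE], kernel, cost)
  }
  dv
}

## Cross-validated fitness of a mask: AUROC for binary labels; for >2
## classes, the mean over classes of the one-vs-rest AUROC on the same folds.
.maskFitness <- function(mask, X, y, folds, kernel, cost) {
  if (!any(mask == 1L)) return(0)
  Xs <- X[, mask == 1L, drop = FALSE]
  classes <- sort(unique(y))
  if (length(classes) == 2) {
    y01 <- as.integer(y == classes[2])
    return(mannWhitneyAuc(.cvDecisionValues(Xs, y01, folds, kernel, cost), y01))
  }
  mean(vapply(classes, function(cl) {
    y01 <- as.integer(y == cl)
    mannWhitneyAuc(.cvDecisionValues(Xs, y01, folds, kernel, cost), y01)
  }, numeric(1)))
}

#' Cross-validated AUROC fitness of a gene mask
#'
#' Fits an SVM on the genes selected by `mask` within each stratified CV
#' training fold, pools the held-out decision values, and returns the single
#' pooled AUROC (for more than two classes, the average one-vs-rest AUROC).
#' Empty masks score 0 by convention. Deterministic given `config$seed`.
#'
#' @param mask 0/1 vector over the rows (genes) of `expr`.
#' @param expr expression matrix, genes x samples.
#' @param labels per-sample class labels.
#' @param config a [psoConfig()] list.
#' @return fitness in `[0, 1]`.
#' @export
evaluateFitness <- function(mask, expr, labels, config = psoConfig()) {
  X <- t(expr)
  y <- as.character(labels)
  folds <- withSeed(childSeed(config$seed, "folds"),
                    stratifiedFolds(y, config$cvFolds))
  .maskFitness(as.integer(mask), X, y, folds, config$kernel, config$cost)
}

#' Binary particle swarm search for a predictive gene panel
#'
#' Runs the swarm over gene-inclusion bitmasks: positions initialize as
#' sparse Bernoulli(`initProb`) draws with zero velocity; each iteration
#' updates velocities toward personal and global bests (coefficients
#' Uniform(0, `phiMax`) per dimension, clamp `vMax`), resamples positions
#' through the logistic transfer, and re-evaluates the CV-SVM-AUROC fitness.
#' Fitness values are cached by mask, so revisited masks cost nothing. The
#' global best is monotone non-decreasing by construction and is returned as
#' the selected panel together with the full trajectory.
#'
#' @param expr expression matrix, genes x samples (e.g. from
#'   [preprocessCohort()]).
#' @param labels per-sample class labels (two classes, or more for the
#'   one-vs-rest averaged fitness).
#' @param config a [psoConfig()] list.
#' @return a [BpsoResult][FeaturePanel-class]; `panelGenes()` gives the
#'   selected genes and `swarmTrajectory()` the per-iteration record.
#' @export
runBpso <- function(expr, labels, config = psoConfig()) {
  X <- t(expr)
  D <- ncol(X)
  y <- as.character(labels)
  if (length(y) != nrow(X)) stop("labels must align with samples")
  cache <- new.env(parent = emptyenv())
  nEval <- 0L; nHit <- 0L
  folds <- withSeed(childSeed(config$seed, "folds"),
                    stratifiedFolds(y, config$cvFolds))
  evalMask <- function(mask) {
    key <- paste(which(mask == 1L), collapse = ",")
    if (!is.null(cache[[key]])) { nHit <<- nHit + 1L; return(cache[[key]]) }
    nEval <<- nEval + 1L
    f <- .maskFitness(mask, X, y, folds, config$kernel, config$cost)
    cache[[key]] <- f
    f
  }
  withSeed(childSeed(config$seed, "swarm"), {
    P <- config$nParticles
    xs <- matrix(0L, P, D)
    for (i in seq_len(P)) {
      xi <- as.integer(stats::runif(D) < config$initProb)
      if (!any(xi == 1L)) xi[sample.int(D, 1)] <- 1L
      xs[i, ] <- xi
    }
    v0 <- if (config$vInit == "prior") stats::qlogis(config$initProb) else 0
    vs <- matrix(v0, P, D)
    fits <- apply(xs, 1, evalMask)
    pbestX <- xs; pbestFit <- fits
    gi <- which.max(pbestFit)
    gbestX <- pbestX[gi, ]; gbestFit <- pbestFit[gi]
    foundAt <- 0L
    traj <- data.frame(iteration = 0L, gbestFit = gbestFit,
                       gbestSize = sum(gbestX))
    better <- function(f, size, bestF, bestSize)
      f > bestF || (config$parsimonyTiebreak && f == bestF && size < bestSize)
    for (it in seq_len(config$nIterations)) {
      for (i in seq_len(P)) {
        phi1 <- stats::runif(D, 0, config$phiMax)
        phi2 <- stats::runif(D, 0, config$phiMax)
        vs[i, ] <- updateVelocity(vs[i, ], xs[i, ], pbestX[i, ], gbestX,
                                  phi1, phi2, config$vMax)
        xs[i, ] <- updatePosition(vs[i, ], stats::runif(D))
        f <- evalMask(xs[i, ])
        if (better(f, sum(xs[i, ]), pbestFit[i], sum(pbestX[i, ]))) {
          pbestX[i, ] <- xs[i, ]; pbestFit[i] <- f
        }
        if (better(f, sum(xs[i, ]), gbestFit, sum(gbestX))) {
          gbestX <- xs[i, ]; gbestFit <- f; foundAt <- it
        }
      }
      stopifnot(gbestFit >= traj$gbestFit[nrow(traj)])  # gbest contract
      traj <- rbind(traj, data.frame(iteration = it, gbestFit = gbestFit,
                                     gbestSize = sum(gbestX)))
    }
    panel <- new("FeaturePanel", geneIds = rownames(expr)[gbestX == 1L],
                 fitness = gbestFit, iterationFound = foundAt,
                 configHash = hashConfig(config))
    new("BpsoResult", panel = panel, trajectory = traj,
        gbestMask = gbestX == 1L, geneIds = rownames(expr),
        config = config, nEvaluations = nEval, nCacheHits = nHit)
  })
}

#' Train the final SVM on a selected panel
#'
#' Fits the production classifier on the panel genes, optionally augmented
#' with standardized serum-marker columns (e.g. CEA / CA199). Missing serum
#' values are imputed with the training median and flagged.
#' Standardization parameters are frozen from the training data, so the
#' handle can score unseen cohorts reproducibly via [predictScores()].
#'
#' @param expr training expression matrix, genes x samples.
#' @param labels per-sample class labels (two or more classes).
#' @param panel a [FeaturePanel-class], [BpsoResult][FeaturePanel-class], or
#'   character vector of gene ids.
#' @param extra optional numeric matrix/data.frame of additional per-sample
#'   features (samples x features), e.g. `cbind(cea = ..., ca199 = ...)`.
#' @param kernel,cost SVM settings (defaults match [psoConfig()]).
#' @return an object of class `"tepClassifier"`.
#' @export
buildFinalClassifier <- function(expr, labels, panel, extra = NULL,
                                 kernel = "radial", cost = 1) {
  genes <- if (is.character(panel)) panel else panelGenes(panel)
  miss <- setdiff(genes, rownames(expr))
  if (length(miss))
    stop("panel genes absent from expression matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  X <- t(expr[genes, , drop = FALSE])
  imputed <- character(0)
  extraMedians <- numeric(0)
  if (!is.null(extra)) {
    extra <- as.matrix(extra)
    ids <- rownames(extra)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(extra)))
    extraMedians <- apply(extra, 2, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(extra))) {
      nas <- is.na(extra[, j])
      if (any(nas)) {
        extra[nas, j] <- extraMedians[j]
        imputed <- union(imputed, ids[nas])
      }
    }
    X <- cbind(X, extra)
  }
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd); sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, "/")
  y <- if (is.factor(labels)) droplevels(labels) else as.factor(labels)
  classes <- levels(y)
  if (length(classes) < 2) stop("need at least two classes")
  models <- if (length(classes) == 2) {
    list(e1071::svm(Xs, factor(as.integer(y == classes[2]), levels = 0:1),
                    kernel = kernel, cost = cost, scale = FALSE))
  } else {
    lapply(classes, function(cl)
      e1071::svm(Xs, factor(as.integer(y == cl), levels = 0:1),
                 kernel = kernel, cost = cost, scale = FALSE))
  }
  structure(list(models = models, classes = classes, genes = genes,
                 nExtra = if (is.null(extra)) 0L else ncol(extra),
                 extraNames = colnames(extra), extraMedians = extraMedians,
                 center = mu, scale = sd,
                 kernel = kernel, cost = cost, imputedSamples = imputed),
            class = "tepClassifier")
}

#' Score samples with a trained classifier
#'
#' For binary tasks returns the SVM decision value per sample (larger =
#' more likely the positive/second class). For multiclass tasks returns a
#' samples x classes matrix of softmaxed one-vs-rest decision values
#' (rows sum to 1), suitable for [handTillMulticlassAuc()].
#'
#' @param object a classifier from [buildFinalClassifier()].
#' @param expr expression matrix, genes x samples, containing the panel.
#' @param extra extra feature matrix matching the training one, if used.
#' @return numeric vector (binary) or matrix (multiclass).
#' @export
predictScores <- function(object, expr, extra = NULL) {
  X <- t(expr[object$genes, , drop = FALSE])
  if (object$nExtra > 0) {
    if (is.null(extra)) stop("classifier was trained with extra features")
    extra <- as.matrix(extra)
    for (j in seq_len(ncol(extra)))
      extra[is.na(extra[, j]), j] <- object$extraMedians[j]
    X <- cbind(X, extra)
  }
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  dvOf <- function(m) {
    pr <- stats::predict(m, Xs, decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    if (strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1] == "0")
      dv <- -dv
    unname(dv)
  }
  if (length(object$classes) == 2) return(dvOf(object$models[[1]]))
  dvs <- vapply(object$models, dvOf, numeric(nrow(Xs)))
  probs <- exp(dvs - apply(dvs, 1, max))
  probs <- probs / rowSums(probs)
  colnames(probs) <- object$classes
  rownames(probs) <- rownames(Xs)
  probs
}

#' @export
print.tepClassifier <- function(x, ...) {
  cat(sprintf("tepClassifier: %s SVM, %d genes + %d extra feature(s), %s\n",
              x$kernel, length(x$genes), x$nExtra,
              paste(x$classes, collapse = " vs ")))
  invisible(x)
}
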