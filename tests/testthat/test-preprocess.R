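makeCounts <- function(m) {
  storage.mode(m) <- "integer"
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  m
}

test_that("low-count filter keeps exactly the genes reaching the threshold", {
  m <- makeCounts(rbind(c(4, 4, 4),    # never reaches 5 -> out
                        c(0, 0, 5),    # reaches 5 once -> in
                        c(10, 0, 0),
                        c(0, 0, 0)))
  kept <- filterLowCounts(m, 5)
  expect_identical(rownames(kept), c("g2", "g3"))
  ## threshold 0 is the identity; the filter is idempotent
  expect_identical(filterLowCounts(m, 0), m)
  expect_identical(filterLowCounts(kept, 5), kept)
  expect_warning(filterLowCounts(m, 100), "every gene")
})

test_that("median-of-ratios size factors: symmetry, doubling, equivariance", {
  base <- makeCounts(matrix(rep(c(10L, 20L, 40L, 100L, 7L), 4), 5, 4))
  expect_equal(unname(estimateSizeFactorsMoR(base)), rep(1, 4))

  ## doubling one column doubles its factor relative to the others:
  ## computed directly from the estimator definition on a 5-gene toy
  m <- base
  m[, 3] <- m[, 3] * 2L
  geo <- exp(rowMeans(log(m)))
  raw <- apply(m, 2, function(col) median(col / geo))
  expected <- raw / exp(mean(log(raw)))
  sf <- estimateSizeFactorsMoR(m)
  expect_equal(unname(sf), unname(expected))
  expect_equal(sf[["s3"]] / sf[["s1"]], 2)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)

  ## permuting samples permutes the factors identically
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(estimateSizeFactorsMoR(m[, perm])), unname(sf[perm]))
})

test_that("size factors agree with the DESeq2 estimator up to rescaling", {
  skip_if_not_installed("DESeq2")
  co <- simulateCohort(twoGroupSpec(8, 8, 300, seed = 31))
  cts <- cohortCounts(co)
  mine <- estimateSizeFactorsMoR(cts, fallback = TRUE)
  ref <- DESeq2::estimateSizeFactorsForMatrix(cts)
  expect_equal(unname(mine / exp(mean(log(mine)))),
               unname(ref / exp(mean(log(ref)))), tolerance = 1e-8)
})

test_that("all-zero-overlap matrix errors unless the fallback is requested", {
  m <- makeCounts(rbind(c(5, 0), c(0, 7)))
  expect_error(estimateSizeFactorsMoR(m), "fallback")
})

test_that("dispersion estimation: Poisson limit, NB recovery, determinism", {
  set.seed(101)
  n <- 400
  pois <- matrix(rpois(200 * n, lambda = rep(exp(runif(200, 2, 6)), n)),
                 200, n)
  pois <- makeCounts(pois)
  sf <- rep(1, n); names(sf) <- colnames(pois)
  fitP <- fitDispersionTrend(pois, sf)
  expect_lt(median(fitP@alphaGene), 0.01)

  nb <- matrix(rnbinom(200 * n, mu = rep(exp(runif(200, 3, 7)), n),
                       size = 1 / 0.2), 200, n)
  nb <- makeCounts(nb)
  fitN <- fitDispersionTrend(nb, sf)
  expect_gt(fitN@a0, 0.1)
  expect_lt(fitN@a0, 0.3)

  ## identical rows get identical estimates
  dup <- makeCounts(rbind(nb[1, ], nb[1, ]))
  fitD <- fitDispersionTrend(dup, sf[1:n])
  expect_equal(fitD@alphaGene[[1]], fitD@alphaGene[[2]])
})

test_that("vst is monotone, flattens variance, and is scale-equivariant", {
  set.seed(55)
  n <- 60
  mu <- exp(runif(400, 1, 8))
  cts <- makeCounts(matrix(rnbinom(400 * n, mu = rep(mu, n), size = 1 / 0.2),
                           400, n))
  sf <- estimateSizeFactorsMoR(cts, fallback = TRUE)
  fit <- fitDispersionTrend(cts, sf)
  v <- vstTransform(cts, sf, fit)
  expect_identical(attr(v, "provenance"), "vst")

  ## monotone in the raw count at fixed size factor
  grid <- makeCounts(matrix(c(0:20, rep(0L, 21)), 21, 2))
  vg <- vstTransform(grid, c(s1 = 1, s2 = 1), fit)
  expect_true(all(diff(vg[, 1]) > 0))
  expect_equal(min(vg[, 1]), vg[1, 1])

  ## variance flatness: max/min SD over 10 mean-ordered bins beats log2(x+1)
  flatness <- function(m) {
    sds <- apply(m, 1, sd)
    bins <- cut(rank(rowMeans(m), ties.method = "first"), 10)
    ratio <- tapply(sds, bins, median)
    max(ratio) / min(ratio)
  }
  lg <- log2(sweep(cts, 2, sf, "/") + 1)
  expect_lt(flatness(v), flatness(lg))

  ## multiplying counts and size factors together leaves the vst unchanged
  v2 <- vstTransform(cts * 3L, sf * 3, fit)
  expect_equal(unclass(v2), unclass(v), tolerance = 1e-12,
               ignore_attr = TRUE)

  ## large-count limit approaches log2 up to an additive constant
  big <- makeCounts(matrix(c(2L^(10:19), rep(1L, 10)), 10, 2))
  vb <- vstTransform(big, c(s1 = 1, s2 = 1), fit)
  diffs <- vb[, 1] - log2(as.numeric(big[, 1]))
  expect_lt(max(diffs) - min(diffs), 0.05)
})

test_that("age filter removes planted confounders and keeps noise genes", {
  set.seed(77)
  n <- 200
  age <- runif(n, 20, 80)
  expr <- matrix(rnorm(100 * n), 100, n,
                 dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:n)))
  expr[1, ] <- 0.1 * age + rnorm(n, sd = 0.01)   # planted confounder
  expr[2, ] <- 5                                  # constant: p = 1
  res <- ageCorrelationFilter(expr, age)
  expect_true("g1" %in% res$removed)
  expect_false("g2" %in% res$removed)
  expect_equal(res$pvalues[["g2"]], 1)
  ## pure-noise genes survive at close to the nominal rate
  expect_lt(length(res$removed), 10)
  ## idempotence: running again on the filtered matrix removes nothing
  res2 <- ageCorrelationFilter(res$expr, age)
  expect_length(res2$removed, 0)
})

test_that("age filter recovers planted age genes on a synthetic cohort", {
  spec <- cohortSpec(nGenes = 400, nInformative = 20, nAgeGenes = 30,
                     seed = 33)
  co <- simulateCohort(spec)
  prep <- preprocessCohort(co, seed = 2)
  truth <- cohortTruth(co)
  recall <- mean(truth$age_genes %in% prep$removedAgeGenes)
  expect_gte(recall, 0.9)
})

test_that("surrogate-variable analysis: null, planted batch, forced k", {
  set.seed(91)
  expr <- matrix(rnorm(300 * 60), 300, 60,
                 dimnames = list(sprintf("g%d", 1:300), sprintf("s%d", 1:60)))
  grp <- rep(c("a", "b"), 30)
  ## no structure -> k = 0 and the matrix is untouched
  null <- removeSurrogateVariables(expr, grp, seed = 5)
  expect_equal(null$k, 0L)
  expect_identical(null$expr, expr)
  ## forced k = 0 is the identity
  forced <- removeSurrogateVariables(expr, grp, k = 0)
  expect_identical(forced$expr, expr)
  ## strong planted batch -> k = 1, SV tracks the batch indicator
  batch <- rep(1:2, each = 30)
  expr2 <- expr + outer(rnorm(300, 0, 1), as.numeric(batch == 2))
  rec <- removeSurrogateVariables(expr2, grp, seed = 5)
  expect_equal(rec$k, 1L)
  expect_gt(abs(cor(rec$sv[, 1], batch)), 0.9)
  expect_lt(max(abs(colMeans(rec$sv))), 1e-10)
  ## k at or above the residual rank is rejected
  expect_error(removeSurrogateVariables(expr, grp, k = 59), "rank")
})

test_that("surrogate variable agrees with the sva package on a planted batch", {
  skip_if_not_installed("sva")
  set.seed(19)
  expr <- matrix(rnorm(200 * 40), 200, 40,
                 dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:40)))
  grp <- rep(c("a", "b"), 20)
  batch <- rep(1:2, each = 20)
  expr <- expr + outer(rnorm(200, 0, 1.5), as.numeric(batch == 2))
  mine <- removeSurrogateVariables(expr, grp, k = 1)
  mod <- model.matrix(~grp)
  ref <- suppressMessages(suppressWarnings(
    sva::sva(expr, mod, mod0 = matrix(1, ncol(expr), 1), n.sv = 1)))
  expect_gt(abs(cor(mine$sv[, 1], ref$sv[, 1])), 0.95)
})

test_that("group means survive surrogate removal for unaffected genes", {
  set.seed(23)
  expr <- matrix(rnorm(100 * 40), 100, 40,
                 dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:40)))
  grp <- rep(c("a", "b"), 20)
  expr[1, grp == "b"] <- expr[1, grp == "b"] + 3   # pure group effect
  res <- removeSurrogateVariables(expr, grp, k = 2, seed = 7)
  before <- mean(expr[1, grp == "b"]) - mean(expr[1, grp == "a"])
  after <- mean(res$expr[1, grp == "b"]) - mean(res$expr[1, grp == "a"])
  ## the group contrast is protected (SV columns are orthogonalized against
  ## the residual space of the group design)
  expect_equal(after, before, tolerance = 0.2)
})

test_that("train/validation split: determinism, fractions, reference counts", {
  co <- simulateCohort(cohortSpec(nGenes = 12, nInformative = 0,
                                  nAgeGenes = 0, seed = 41))
  md <- as.data.frame(sampleInfo(co))
  s1 <- suppressWarnings(
    splitTrainValidation(md, trainCounts = referenceTrainCounts(), seed = 9))
  expect_length(s1$train, 202)
  expect_length(s1$validation, 120)
  expect_length(intersect(s1$train, s1$validation), 0)
  expect_setequal(c(s1$train, s1$validation), md$sample_id)
  ## stratum counts are honored exactly
  tr <- md[md$sample_id %in% s1$train, ]
  expect_equal(sum(tr$group == "CRC" & tr$stage == "I"), 15)
  expect_equal(sum(tr$group == "HD"), 17)
  expect_equal(sum(tr$group == "UC"), 14)
  ## determinism, and a different seed reshuffles membership
  s2 <- suppressWarnings(
    splitTrainValidation(md, trainCounts = referenceTrainCounts(), seed = 9))
  expect_identical(s1, s2)
  s3 <- suppressWarnings(
    splitTrainValidation(md, trainCounts = referenceTrainCounts(), seed = 10))
  expect_false(identical(s1$train, s3$train))
  ## degenerate fraction puts everything in training
  s4 <- suppressWarnings(splitTrainValidation(md, trainFraction = 1, seed = 1))
  expect_length(s4$validation, 0)
  ## fraction honored within one sample per stratum
  s5 <- suppressWarnings(splitTrainValidation(md, trainFraction = 0.5, seed = 1))
  strat <- ifelse(md$group == "CRC", paste0("CRC-", md$stage), md$group)
  for (s in unique(strat)) {
    ids <- md$sample_id[strat == s]
    got <- sum(ids %in% s5$train)
    expect_lte(abs(got - 0.5 * length(ids)), 1)
  }
})

test_that("tiny strata go wholly to training with a warning", {
  co <- simulateCohort(cohortSpec(nGenes = 10, nInformative = 0,
                                  nAgeGenes = 0, seed = 43))
  md <- as.data.frame(sampleInfo(co))   # CRC-IV has a single sample
  expect_warning(s <- splitTrainValidation(md, trainFraction = 0.5, seed = 2),
                 "CRC-IV")
  iv <- md$sample_id[md$group == "CRC" & md$stage == "IV"]
  expect_true(all(iv %in% s$train))
})

test_that("the preprocessing chain logs every stage", {
  co <- simulateCohort(twoGroupSpec(10, 10, 120, nInformative = 5,
                                    effectLog2FC = 1, seed = 47))
  prep <- preprocessCohort(co, seed = 3)
  expect_named(prep$log, c("input", "filter_low_counts", "vst",
                           "age_filter", "sva"))
  expect_lte(prep$log$sva$genes, prep$log$input$genes)
  expect_equal(prep$log$input$samples, 20)
  expect_equal(nrow(prep$expr), prep$log$sva$genes)
})
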