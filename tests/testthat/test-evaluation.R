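test_that("AUROC agrees with pair enumeration on hand-built cases", {
  ## 3 positives vs 1 negative: 2 of 3 pairs are concordant
  rc <- rocAuc(c(0.9, 0.8, 0.3, 0.4), c(1, 1, 1, 0))
  expect_equal(rocAucValue(rc), 2 / 3)
  ## perfect separation and total ties
  expect_equal(rocAucValue(rocAuc(c(5, 4, 1, 0), c(1, 1, 0, 0))), 1)
  expect_equal(rocAucValue(rocAuc(rep(2, 6), c(1, 1, 1, 0, 0, 0))), 0.5)
  ## curve anchors
  expect_equal(rc@fpr[1], 0); expect_equal(rc@tpr[1], 0)
  expect_equal(rc@fpr[length(rc@fpr)], 1)
  expect_equal(rc@tpr[length(rc@tpr)], 1)
  expect_error(rocAuc(1:3, c(1, 1, 1)), "class")
})

test_that("trapezoidal area equals the Mann-Whitney statistic with ties", {
  set.seed(61)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    ## coarse scores force plenty of ties
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    rc <- rocAuc(s, y)
    expect_equal(rocAucValue(rc), mannWhitneyAuc(s, y), tolerance = 1e-12)
    expect_equal(mannWhitneyAuc(s, y), bruteForceAuc(s, y),
                 tolerance = 1e-12)
  }
})

test_that("complement symmetry: auc(scores) + auc(-scores) = 1 (no ties)", {
  set.seed(62)
  for (i in 1:20) {
    s <- rnorm(30)
    y <- c(0, 1, rbinom(28, 1, 0.4))
    expect_equal(rocAucValue(rocAuc(s, y)) + rocAucValue(rocAuc(-s, y)), 1,
                 tolerance = 1e-12)
  }
})

test_that("AUROC and DeLong interval agree with pROC", {
  skip_if_not_installed("pROC")
  set.seed(63)
  s <- rnorm(80) + c(0, 1)[rbinom(80, 1, 0.5) + 1]
  y <- as.integer(s + rnorm(80) > 0.5)
  y[1:2] <- c(0, 1)
  rc <- rocAuc(s, y)
  ref <- pROC::roc(y, s, quiet = TRUE, direction = "<")
  expect_equal(rocAucValue(rc), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  ci <- pROC::ci.auc(ref, method = "delong")
  expect_equal(unname(rocCi(rc)), as.numeric(ci[c(1, 3)]), tolerance = 1e-9)
})

test_that("confusion metrics reproduce the reconstructed training column", {
  m <- confusionMetrics(tp = 78, fn = 2, fp = 23, tn = 99)
  expect_equal(round(m$kappa, 3), 0.752)
  expect_equal(round(m$f1, 3), 0.862)
  expect_equal(round(m$accuracy[1], 3), 0.876)
  expect_equal(round(m$ppv[1], 3), 0.772)
  expect_equal(round(m$npv[1], 3), 0.980)
  expect_equal(round(m$sensitivity[1], 3), 0.975)
  expect_equal(round(m$specificity[1], 3), 0.811)
  ## Clopper-Pearson intervals bracket the estimates within [0, 1]
  for (nm in c("accuracy", "sensitivity", "specificity", "ppv", "npv")) {
    expect_gte(m[[nm]][1], m[[nm]][2])
    expect_lte(m[[nm]][1], m[[nm]][3])
    expect_gte(m[[nm]][2], 0); expect_lte(m[[nm]][3], 1)
  }
})

test_that("kappa: perfect, chance-level, and ordering against accuracy", {
  expect_equal(confusionMetrics(50, 0, 0, 50)$kappa, 1)
  expect_equal(confusionMetrics(50, 0, 0, 50)$f1, 1)
  ## independence with equal margins: kappa exactly 0
  expect_equal(confusionMetrics(25, 25, 25, 25)$kappa, 0)
  set.seed(64)
  for (i in 1:50) {
    cells <- rmultinom(1, 60, rep(0.25, 4))
    m <- confusionMetrics(cells[1], cells[2], cells[3], cells[4])
    expect_lte(m$kappa, m$accuracy[1] + 1e-12)
  }
  ## empty margin reported as missing
  m0 <- confusionMetrics(tp = 0, fn = 0, fp = 5, tn = 5)
  expect_true(is.na(m0$sensitivity[1]))
})

test_that("Hand-Till M matches brute force and collapses to AUC for 2 classes", {
  set.seed(65)
  ## two classes: M equals the plain AUROC of the positive column
  p2 <- matrix(runif(40), 20, 2); p2 <- p2 / rowSums(p2)
  colnames(p2) <- c("neg", "pos")
  y2 <- c("neg", "pos")[rbinom(20, 1, 0.5) + 1]; y2[1:2] <- c("neg", "pos")
  ht2 <- handTillMulticlassAuc(p2, y2)
  expect_equal(ht2$M, mannWhitneyAuc(p2[, "pos"], as.integer(y2 == "pos")),
               tolerance = 1e-12)
  ## random 3-5 class instances against the enumeration oracle
  for (i in 1:30) {
    c <- sample(3:5, 1); n <- sample(20:40, 1)
    pr <- matrix(rexp(n * c), n, c); pr <- pr / rowSums(pr)
    colnames(pr) <- LETTERS[1:c]
    y <- sample(LETTERS[1:c], n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(LETTERS[1:c], n, replace = TRUE)
    expect_equal(handTillMulticlassAuc(pr, y)$M, bruteForceHandTill(pr, y),
                 tolerance = 1e-12)
  }
})

test_that("Hand-Till M is invariant under class relabeling and separable = 1", {
  set.seed(66)
  pr <- matrix(rexp(90), 30, 3); pr <- pr / rowSums(pr)
  colnames(pr) <- c("A", "B", "C")
  y <- sample(c("A", "B", "C"), 30, replace = TRUE)
  perm <- c("C", "A", "B")
  pr2 <- pr[, perm]
  y2 <- y
  ht <- handTillMulticlassAuc(pr, y)
  ht2 <- handTillMulticlassAuc(pr2, y2)
  expect_equal(ht$M, ht2$M, tolerance = 1e-12)
  ## perfectly separated 3-class problem
  y3 <- rep(c("A", "B", "C"), each = 5)
  p3 <- matrix(0.01, 15, 3, dimnames = list(NULL, c("A", "B", "C")))
  p3[cbind(1:15, rep(1:3, each = 5))] <- 0.98
  expect_equal(handTillMulticlassAuc(p3, y3)$M, 1)
})

test_that("Hand-Till matches pROC's multiclass implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  pr <- matrix(rexp(120), 40, 3); pr <- pr / rowSums(pr)
  colnames(pr) <- c("A", "B", "C")
  y <- sample(c("A", "B", "C"), 40, replace = TRUE)
  mine <- handTillMulticlassAuc(pr, y)$M
  ref <- suppressMessages(pROC::multiclass.roc(y, data.frame(pr)))
  expect_equal(mine, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
})

test_that("DeLong comparison: identity, symmetry, strong separation", {
  set.seed(68)
  y <- c(rep(1, 100), rep(0, 100))
  s1 <- c(rnorm(100, 3), rnorm(100))      # near-perfect
  s2 <- rnorm(200)                         # useless
  r1 <- rocAuc(s1, y); r2 <- rocAuc(s2, y)
  self <- compareAucDelong(r1, r1)
  expect_equal(self$delta, 0); expect_equal(self$p, 1)
  cmp <- compareAucDelong(r1, r2, paired = TRUE)
  expect_lt(cmp$p, 1e-6)
  swap <- compareAucDelong(r2, r1, paired = TRUE)
  expect_equal(swap$delta, -cmp$delta)
  expect_equal(swap$p, cmp$p)
  expect_error(compareAucDelong(r1, rocAuc(s2[1:50], y[c(1:25, 101:125)])),
               "identical")
})

test_that("paired DeLong p-value agrees with pROC's roc.test", {
  skip_if_not_installed("pROC")
  set.seed(69)
  y <- rbinom(120, 1, 0.5); y[1:2] <- 0:1
  s1 <- rnorm(120) + 1.2 * y
  s2 <- rnorm(120) + 0.4 * y
  mine <- compareAucDelong(rocAuc(s1, y), rocAuc(s2, y), paired = TRUE)
  ref <- pROC::roc.test(pROC::roc(y, s1, quiet = TRUE, direction = "<"),
                        pROC::roc(y, s2, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
})

test_that("LOOCV: separable case, fit accounting, pooled ROC", {
  sep <- separableExpr(n = 24, nGenes = 6)
  y <- factor(sep$labels, levels = c("ctrl", "case"))
  res <- loocvEvaluate(sep$expr, y, panel = rownames(sep$expr))
  expect_equal(res$nFits, 24L)
  expect_equal(rocAucValue(res$roc), 1)
  expect_equal(res$confusion$accuracy[1], 1)
})

test_that("per-stage sensitivities reproduce the printed fractions", {
  ## training set: 14/15 at stage I, 29/30 at II, 34/34 at III
  stage <- rep(c("I", "II", "III"), c(15, 30, 34))
  pred <- rep(1, 79)
  pred[c(1, 16)] <- 0    # one miss at I, one at II
  tab <- sensitivityByStratum(pred, rep(1, 79), stage)
  expect_equal(tab$fraction, c("14/15", "29/30", "34/34"))
  expect_equal(round(tab$sensitivityPct, 1), c(93.3, 96.7, 100))
  ## internal validation: 8/10, 16/18, 22/24
  stage2 <- rep(c("I", "II", "III"), c(10, 18, 24))
  pred2 <- rep(1, 52)
  pred2[c(1, 2, 11, 12, 29, 30)] <- 0
  tab2 <- sensitivityByStratum(pred2, rep(1, 52), stage2)
  expect_equal(tab2$fraction, c("8/10", "16/18", "22/24"))
  expect_equal(round(tab2$sensitivityPct, 1), c(80, 88.9, 91.7))
  ## all-correct edge
  tab3 <- sensitivityByStratum(rep(1, 4), rep(1, 4), c("I", "I", "II", "II"))
  expect_true(all(tab3$sensitivityPct == 100))
})
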