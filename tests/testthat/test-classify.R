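test_that("metrics reproduce every internally consistent published-style row", {
  # 10-fold cross-validation rows (TP, FN, TN, FP -> SN, PPV, MCC, TPC)
  rows <- list(
    list(c(7603, 1190, 34354, 332), c(86.47, 95.82, 0.89, 0.04)),
    list(c(7638, 1155, 34252, 434), c(86.86, 94.62, 0.88, 0.06)),
    list(c(7626, 1167, 34921, 395), c(86.73, 95.08, 0.89, 0.05)),
    list(c(7153, 1640, 34198, 488), c(81.35, 93.61, 0.84, 0.07)),
    # independent test-set rows
    list(c(2593, 387, 11385, 96), c(87.01, 96.43, 0.90, 0.04)),
    list(c(2594, 386, 11356, 125), c(87.05, 95.40, 0.89, 0.05)),
    list(c(2599, 381, 11349, 132), c(87.21, 95.17, 0.89, 0.05)),
    list(c(2391, 589, 11332, 149), c(80.23, 94.13, 0.84, 0.06)))
  for (r in rows) {
    m <- evalMetrics(r[[1]][1], r[[1]][2], r[[1]][3], r[[1]][4])
    expect_equal(round(c(m$sn, m$ppv, m$mcc, m$tpc), 2), r[[2]])
  }
  # external-program rows: PPV/MCC/TPC are consistent (their printed SN
  # disagrees with TP/(TP+FN) and is not asserted)
  ep <- evalMetrics(2581, 399, 9633, 1848)
  expect_equal(round(c(ep$ppv, ep$mcc, ep$tpc), 2), c(58.28, 0.62, 0.72))
  ps <- evalMetrics(2563, 417, 8817, 2664)
  expect_equal(round(c(ps$sn, ps$ppv, ps$mcc, ps$tpc), 2),
               c(86.01, 49.03, 0.53, 1.04))
  fe <- evalMetrics(1714, 1226, 11402, 79)
  expect_equal(round(fe$ppv, 1), 95.6)
  expect_equal(round(fe$tpc, 2), 0.05)
})

test_that("metric edge cases: perfect classifier, degenerate denominators", {
  perfect <- evalMetrics(tp = 50, fn = 0, tn = 200, fp = 0)
  expect_equal(c(perfect$sn, perfect$ppv, perfect$mcc, perfect$tpc),
               c(100, 100, 1, 0))
  deg <- evalMetrics(tp = 0, fn = 0, tn = 10, fp = 0)
  expect_setequal(deg$degenerate, c("sn", "ppv", "mcc", "tpc"))
  expect_equal(c(deg$sn, deg$ppv, deg$mcc, deg$tpc), c(0, 0, 0, 0))
})

test_that("metrics are scale-free and MCC is swap-symmetric", {
  set.seed(30)
  for (i in 1:20) {
    cm <- sample(1:500, 4)
    a <- evalMetrics(cm[1], cm[2], cm[3], cm[4])
    b <- evalMetrics(7 * cm[1], 7 * cm[2], 7 * cm[3], 7 * cm[4])
    expect_equal(c(a$sn, a$ppv, a$mcc, a$tpc), c(b$sn, b$ppv, b$mcc, b$tpc))
    swapped <- evalMetrics(cm[3], cm[4], cm[1], cm[2])  # tp<->tn, fn<->fp
    expect_equal(swapped$mcc, a$mcc)
  }
})

# linearly separable toy features used by several blocks
.separable <- function(n = 120, seed = 31) {
  set.seed(seed)
  lab <- rep(c("promoter", "nonpromoter"), each = n / 2)
  data.frame(x1 = rnorm(n, ifelse(lab == "promoter", 4, -4)),
             x2 = rnorm(n), x3 = rnorm(n), label = lab)
}

test_that("training is deterministic and prediction guards feature order", {
  d <- .separable()
  m1 <- trainModel(d[1:3], d$label, "random_forest", ntree = 50, seed = 5)
  m2 <- trainModel(d[1:3], d$label, "random_forest", ntree = 50, seed = 5)
  p1 <- predictPromoter(m1, d[1:3])
  p2 <- predictPromoter(m2, d[1:3])
  expect_identical(p1$score, p2$score)

  # same columns in another order are accepted and reordered
  p3 <- predictPromoter(m1, d[c(3, 1, 2)])
  expect_identical(p3$score, p1$score)
  # missing/renamed columns are refused
  bad <- d[1:3]; names(bad)[1] <- "other"
  expect_error(predictPromoter(m1, bad), "do not match")

  # bagging uses every feature per split
  mb <- trainModel(d[1:3], d$label, "bagging", ntree = 20, seed = 5)
  expect_equal(mb@hyperparameters$mtry, 3L)
  expect_error(trainModel(d[1:3], rep("promoter", nrow(d))), "both classes")
})

test_that("cross-validation separates the separable and pools all records", {
  d <- .separable(200)
  cv <- crossValidate(d[1:3], d$label, k = 10, ntree = 50, seed = 6)
  expect_equal(cv$report$mcc, 1)
  expect_equal(sum(cv$confusion), 200)
  cv2 <- crossValidate(d[1:3], d$label, k = 10, ntree = 50, seed = 6)
  expect_identical(cv$confusion, cv2$confusion)
})

test_that("label-shuffled features give near-zero cross-validated MCC", {
  set.seed(32)
  n <- 5000
  x <- data.frame(matrix(rnorm(n * 8), n, 8))
  lab <- sample(rep(c("promoter", "nonpromoter"), each = n / 2))
  cv <- crossValidate(x, lab, k = 10, ntree = 30, seed = 7)
  expect_lt(abs(cv$report$mcc), 0.05)
})

test_that("trapezoid AUC matches the pairwise-comparison oracle", {
  expect_equal(rocPoints(c(0.9, 0.8, 0.2, 0.1),
                         c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocPoints(c(0.1, 0.2, 0.8, 0.9),
                         c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
  expect_equal(rocPoints(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  set.seed(33)
  for (i in 1:5) {
    n <- 200
    lab <- runif(n) < 0.4
    score <- round(rnorm(n, mean = lab), 2)   # rounding induces ties
    expect_equal(rocPoints(score, lab)$auc, pairwiseAuc(score, lab),
                 tolerance = 1e-12)
  }
})

test_that("a planted informative feature ranks first in importance", {
  set.seed(34)
  n <- 300
  lab <- rep(c("promoter", "nonpromoter"), each = n / 2)
  x <- data.frame(matrix(rnorm(n * 38), n, 38))
  x$signal <- rnorm(n, ifelse(lab == "promoter", 2, -2))
  vi <- variableImportance(x, lab, nRepeats = 3, ntree = 60, seed = 8)
  expect_equal(vi$feature[1], "signal")
  expect_gt(vi$meanDecreaseAccuracy[1], 3 * max(vi$meanDecreaseAccuracy[-1]))
})

test_that("pure-noise importances hover near zero and averaging tightens them", {
  set.seed(35)
  n <- 200
  lab <- sample(rep(c("promoter", "nonpromoter"), each = n / 2))
  x <- data.frame(matrix(rnorm(n * 10), n, 10))
  vi1 <- variableImportance(x, lab, nRepeats = 2, ntree = 50, seed = 9)
  # normalized importances are z-scores; under the null they stay small
  expect_lt(max(abs(vi1$meanDecreaseAccuracy)), 3)
  expect_lt(abs(mean(vi1$meanDecreaseAccuracy)), 1)

  # averaging over more repeats shrinks the spread across repeated estimates
  spread <- function(reps, seedBase) {
    ests <- vapply(seq_len(6), function(j) {
      vi <- variableImportance(x, lab, nRepeats = reps, ntree = 50,
                               seed = seedBase + 100 * j)
      vi$meanDecreaseAccuracy[vi$feature == "X1"]
    }, numeric(1))
    stats::sd(ests)
  }
  expect_lt(spread(4, 10), spread(1, 10))
})

test_that("model archives round-trip and refuse unknown formats", {
  d <- .separable()
  m <- trainModel(d[1:3], d$label, ntree = 30, seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  savePromoterModel(m, path)
  m2 <- loadPromoterModel(path)
  expect_identical(predictPromoter(m2, d[1:3])$score,
                   predictPromoter(m, d[1:3])$score)
  saveRDS(list(format = "other"), path)
  expect_error(loadPromoterModel(path), "unrecognized")
})
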