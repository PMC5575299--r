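test_that("metric formulas match instance-level recomputation", {
  expect_equal(unname(classificationMetrics(c(TP = 10, FP = 0, FN = 0, TN = 10))),
               c(100, 100, 100, 100, 1))
  expect_equal(unname(classificationMetrics(c(TP = 0, FP = 10, FN = 10, TN = 0))),
               c(0, 0, 0, 0, -1))
  got <- classificationMetrics(c(TP = 52, FP = 9, FN = 11, TN = 128))
  expect_equal(got, metricsFromInstances(52, 9, 11, 128), tolerance = 1e-12)
  # MCC zero-denominator convention
  expect_identical(unname(classificationMetrics(c(TP = 0, FP = 0, FN = 0,
                                                  TN = 5))["MCC"]), 0)
  expect_error(classificationMetrics(c(TP = 0, FP = 0, FN = 0, TN = 0)),
               "no evaluated")
})

test_that("accuracy decomposes as the prevalence-weighted TPR/TNR mixture", {
  set.seed(61)
  for (i in 1:50) {
    cnt <- c(TP = rpois(1, 20) + 1, FP = rpois(1, 10) + 1,
             FN = rpois(1, 10) + 1, TN = rpois(1, 30) + 1)
    m <- classificationMetrics(cnt)
    prev <- (cnt["TP"] + cnt["FN"]) / sum(cnt)
    expect_equal(unname(m["ACC"]),
                 unname(prev * m["TPR"] + (1 - prev) * m["TNR"]),
                 tolerance = 1e-9)
  }
})

test_that("cross-validation partitions records and stays deterministic", {
  tb <- randomBinaryTable(n = 60, p = 12, seed = 62, planted = 2L,
                          labels = factor(rep(c("1", "2", "3"), each = 20)))
  rownames(tb$X) <- sprintf("r%02d", 1:60)
  cv <- crossValidate(tb$X, tb$labels, folds = 10, seed = 8, ntree = 100)
  # each record appears in exactly one test fold
  expect_identical(sort(cv$predictions$id), sort(rownames(tb$X)))
  expect_true(all(table(cv$predictions$id) == 1L))
  # stratification: every fold holds 2 of each class
  expect_true(all(table(cv$predictions$fold, cv$predictions$truth) == 2L))
  cv2 <- crossValidate(tb$X, tb$labels, folds = 10, seed = 8, ntree = 100)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(crossValidate(tb$X, tb$labels, folds = 1), "folds")
  # leave-one-out on a 12-record set is a valid protocol
  sub <- c(1:4, 21:24, 41:44)
  loo <- suppressWarnings(
    crossValidate(tb$X[sub, ], droplevels(tb$labels[sub]), folds = 12,
                  seed = 8, sampling = "without_upsampling", ntree = 50))
  expect_true(all(table(loo$predictions$fold) == 1L))
})

test_that("75/25 split is stratified, disjoint and deterministic", {
  tb <- randomBinaryTable(n = 80, p = 10, seed = 63, planted = 2L,
                          labels = factor(rep(c("1", "2"), each = 40)))
  rownames(tb$X) <- sprintf("r%02d", 1:80)
  sp <- splitAndTest(tb$X, tb$labels, seed = 9, ntree = 100)
  expect_length(intersect(sp$trainIds, sp$testIds), 0L)
  expect_identical(sort(c(sp$trainIds, sp$testIds)), sort(rownames(tb$X)))
  expect_identical(length(sp$trainIds), 60L)   # 30 per class
  sp2 <- splitAndTest(tb$X, tb$labels, seed = 9, ntree = 100)
  expect_identical(sp$trainIds, sp2$trainIds)
})

test_that("blind allocation reproduces the 10% per-class arithmetic", {
  # a 1,609-record class profile with the documented skew: 65.75% in the
  # two dominant classes, 6.83% in the two rare ones
  sizes <- c(`1` = 529L, `2` = 529L, `3` = 221L, `4` = 220L,
             `5` = 55L, `6` = 55L)
  expect_identical(sum(sizes), 1609L)
  y <- factor(rep(names(sizes), sizes))
  mask <- blindAllocation(y, frac = 0.10, seed = 1)
  expect_identical(sum(mask), 162L)            # round-half-up per class
  perClass <- table(y[mask])
  expect_identical(as.integer(perClass), c(53L, 53L, 22L, 22L, 6L, 6L))
  # singleton classes contribute no blind member
  y2 <- factor(c(rep("1", 9), "2"))
  expect_identical(sum(blindAllocation(y2, 0.10, 1) & y2 == "2"), 0L)
})

test_that("blind protocol keeps the blind set out of training", {
  tb <- randomBinaryTable(n = 60, p = 10, seed = 64, planted = 2L,
                          labels = factor(rep(c("1", "2", "3"), each = 20)))
  rownames(tb$X) <- sprintf("r%02d", 1:60)
  bl <- blindProtocol(tb$X, tb$labels, seed = 10, ntree = 100)
  expect_identical(length(bl$blindIds), 6L)    # 10% of 20, x3 classes
  expect_length(intersect(bl$blindIds, bl$predictions$id), length(bl$blindIds))
  expect_s3_class(bl$finalModel, "randomForest")
  # the final production forest saw all 60 records (upsampled multiset)
  expect_gte(sum(bl$finalModel$y == "1"), 20L)
})

test_that("PCA diagnostic agrees with a direct eigendecomposition", {
  set.seed(65)
  X <- matrix(rnorm(48), 6, 8)
  got <- pcaDiagnostic(X, nComponents = 2)
  ev <- eigen(stats::cov(scale(X, center = TRUE, scale = FALSE)))$values
  ev <- ev[ev > 1e-12]
  expect_equal(got$varianceFraction[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-9)
  expect_equal(sum(got$varianceFraction), 1, tolerance = 1e-9)
  expect_true(all(diff(got$varianceFraction) <= 1e-12))
  # two well-separated clusters: PC1 dominates
  Y <- rbind(matrix(rnorm(40, 0, 0.1), 10, 4),
             matrix(rnorm(40, 5, 0.1), 10, 4))
  pf <- pcaDiagnostic(Y)$varianceFraction
  expect_gt(pf[1], pf[2])
  expect_error(pcaDiagnostic(matrix(1, 5, 3)), "constant")
})
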