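test_that("upsampling balances every class to the majority, keeping originals", {
  set.seed(51)
  X <- matrix(rbinom(14 * 5, 1, 0.5), 14, 5,
              dimnames = list(sprintf("r%02d", 1:14), sprintf("f:%d", 0:4)))
  y <- factor(c(rep("A", 10), rep("B", 4)))
  bal <- upsampleBalance(X, y, seed = 5)
  expect_identical(unname(table(bal$y)["A"]), 10L)
  expect_identical(unname(table(bal$y)["B"]), 10L)
  # all original B rows present in the balanced multiset
  rowKey <- function(M) unname(apply(M, 1, paste, collapse = ""))
  for (i in 11:14)
    expect_true(paste(X[i, ], collapse = "") %in%
                  rowKey(bal$X[bal$y == "B", , drop = FALSE]))
  # already balanced input: row multiset unchanged
  yb <- factor(rep(c("A", "B"), each = 7))
  balb <- upsampleBalance(X, yb, seed = 5)
  expect_identical(dim(balb$X), dim(X))
  expect_identical(sort(rowKey(balb$X)), sort(rowKey(X)))
  expect_error(upsampleBalance(X, factor(rep("A", 14))), "two classes")
})

test_that("three-class upsampling duplicates only within each class", {
  set.seed(52)
  n <- c(A = 100L, B = 7L, C = 3L)
  y <- factor(rep(names(n), n))
  # encode the class into the features so provenance of duplicates is checkable
  X <- cbind(clsA = as.integer(y == "A"), clsB = as.integer(y == "B"),
             noise = rbinom(110, 1, 0.5))
  bal <- upsampleBalance(X, y, seed = 9)
  expect_true(all(table(bal$y) == 100L))
  expect_true(all(bal$X[bal$y == "B", "clsB"] == 1L))
  expect_true(all(bal$X[bal$y == "C", "clsA"] + bal$X[bal$y == "C", "clsB"] == 0L))
})

test_that("mtry search starts at round(sqrt(p)) and minimizes trace OOB", {
  tb <- randomBinaryTable(n = 150, p = 219, seed = 53, planted = 2L)
  colnames(tb$X) <- sprintf("f:%d", seq_len(ncol(tb$X)) - 1L)
  X219 <- tb$X[, 1:219]                          # p = 219 as in the hybrid
  tun <- tuneMtry(X219, tb$labels, seed = 3)
  start <- 15L                                   # round(sqrt(219)) = 15
  expect_true(start %in% tun$trace$mtry)
  # every probe reachable from the start by the step factor 2
  steps <- log2(tun$trace$mtry / start)
  expect_true(all(abs(steps - round(steps)) < 0.2))
  expect_equal(tun$oob_error_percent, min(tun$trace$oob_error_percent))
  expect_true(tun$mtry %in%
                tun$trace$mtry[tun$trace$oob_error_percent ==
                                 min(tun$trace$oob_error_percent)])
  # determinism: identical rerun, identical trace
  expect_identical(tuneMtry(X219, tb$labels, seed = 3)$trace, tun$trace)
  # single-column table
  t1 <- tuneMtry(X219[, 1, drop = FALSE], tb$labels, seed = 3)
  expect_identical(t1$mtry, 1L)
})

test_that("ntree selection scans the saturation grid with ties toward 500", {
  tb <- randomBinaryTable(n = 80, p = 30, seed = 54, planted = 3L)
  # perfectly separable -> flat zero OOB -> tie -> 500
  sep <- cbind(sig = as.integer(tb$labels == "a"),
               tb$X[, 1:10])
  expect_identical(as.integer(selectNtree(sep, tb$labels, mtry = 2, seed = 4)),
                   500L)
  expect_identical(as.integer(selectNtree(tb$X, tb$labels, mtry = 3,
                                          grid = 250L, seed = 4)), 250L)
  # exhaustive grid scan oracle at the same seed
  nt <- selectNtree(tb$X, tb$labels, mtry = 3, seed = 4)
  trace <- attr(nt, "trace")
  best <- trace$ntree[trace$oob_error_percent == min(trace$oob_error_percent)]
  expect_identical(as.integer(nt), max(best))
})

test_that("cascade trains one class model plus per-class subclass models", {
  b <- fixtureBundle("tiny", 7L)
  spec <- buildHybrid(b$M, b$labels$group)
  model <- trainCascade(b$db, spec, seed = 11, features = b$M, tune = FALSE)
  expect_s4_class(model, "CascadeModel")
  expect_setequal(names(model@subclassModels),
                  as.character(sort(unique(as.integer(as.character(b$labels$class))))))
  # without upsampling the training counts equal the raw per-model subsets
  raw <- trainCascade(b$db, spec, sampling = "without_upsampling", seed = 11,
                      features = b$M, tune = FALSE)
  expect_identical(
    unlist(raw@trainingCounts$class),
    unlist(as.list(table(b$labels$class))))
  # with upsampling every per-model class count equals the maximum
  up <- model@trainingCounts
  for (nm in names(up))
    expect_true(all(unlist(up[[nm]]) == max(unlist(up[[nm]]))), info = nm)
})

test_that("class prediction returns coherent probabilities and thresholds", {
  b <- fixtureBundle("tiny", 7L)
  spec <- buildHybrid(b$M, b$labels$group)
  model <- trainCascade(b$db, spec, seed = 11, features = b$M, tune = FALSE)
  fp <- b$M[5, ]
  out <- predictClass(model, fp)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_identical(out$classDigit,
                   as.integer(as.character(b$labels$class[5])))
  # training molecule: own class probability is the maximum
  expect_gte(out$probs[as.character(out$classDigit)], max(out$probs) - 1e-12)
  # impossible threshold -> unclassified
  expect_true(is.na(predictClass(model, fp, threshold = 1.01)$classDigit))
  sub <- predictSubclass(model, out$classDigit, fp)
  expect_identical(sub$outcome, "ok")
  expect_equal(sum(sub$probs), 1, tolerance = 1e-9)
  expect_identical(predictSubclass(model, 6L, fp)$outcome, "no-subclass-model")
})

test_that("identical seed and inputs reproduce the cascade exactly", {
  b <- fixtureBundle("tiny", 7L)
  spec <- buildHybrid(b$M, b$labels$group)
  m1 <- trainCascade(b$db, spec, seed = 11, features = b$M, tune = FALSE)
  m2 <- trainCascade(b$db, spec, seed = 11, features = b$M, tune = FALSE)
  fp <- b$M[1, ]
  expect_identical(predictClass(m1, fp), predictClass(m2, fp))
  expect_identical(m1@trainingCounts, m2@trainingCounts)
})
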