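test_that("remove-useless drops constant and near-constant bits", {
  set.seed(21)
  n <- 1000L
  X <- cbind(
    allzero = rep(0L, n),
    allone = rep(1L, n),
    onehot = c(1L, rep(0L, n - 1L)),          # dominance 0.999 > 0.99
    balanced = rbinom(n, 1L, 0.5),
    skew98 = rbinom(n, 1L, 0.02) | c(1L, 1L, rep(0L, n - 2L))
  )
  colnames(X) <- c("f:0", "f:1", "f:2", "f:3", "f:4")
  surv <- removeUseless(X, maxDominance = 0.99)
  # oracle: direct per-column frequency scan
  freq <- apply(X, 2, function(c) max(mean(c), 1 - mean(c)))
  expect_identical(surv, colnames(X)[freq <= 0.99])
  expect_false(any(c("f:0", "f:1", "f:2") %in% surv))
  expect_error(removeUseless(X[, 1:2], maxDominance = 0.99), "eliminated all")
})

test_that("symmetric uncertainty and CFS merit follow their closed forms", {
  set.seed(22)
  y <- factor(rep(c("a", "b"), each = 30))
  perfect <- as.integer(y == "a")
  X <- cbind("s:0" = perfect, "s:1" = perfect,
             "s:2" = rbinom(60, 1, 0.5))
  # SU(x, x) = 1 for a non-constant column; merit of a single perfectly
  # class-aligned column is therefore 1
  expect_equal(symmetricUncertainty(perfect, y), 1)
  expect_equal(cfsMerit("s:0", X, y), 1)
  # duplicating a perfect column: the k-fold numerator gain is exactly
  # cancelled by the feature-feature redundancy term, so merit stays 1
  expect_equal(cfsMerit(c("s:0", "s:1"), X, y), 2 / sqrt(2 + 2 * 1 * 1))
  expect_equal(cfsMerit(c("s:0", "s:1"), X, y), cfsMerit("s:0", X, y))
  # a weaker, partially redundant partner strictly lowers the merit
  set.seed(26)
  noisyCopy <- as.integer(xor(perfect, rbinom(60, 1, 0.3)))
  X2 <- cbind("s:0" = perfect, "s:3" = noisyCopy)
  expect_lt(cfsMerit(c("s:0", "s:3"), X2, y), cfsMerit("s:0", X2, y))
  # independent oracle: SU recomputed from raw entropy definitions
  suOracle <- function(x, y) {
    H <- function(v) { p <- table(v) / length(v); -sum(p * log2(p)) }
    Hj <- function(x, y) { p <- table(x, y) / length(x); p <- p[p > 0]
                           -sum(p * log2(p)) }
    mi <- H(x) + H(y) - Hj(x, y)
    if (H(x) == 0 || H(y) == 0) 0 else 2 * mi / (H(x) + H(y))
  }
  for (j in colnames(X))
    expect_equal(symmetricUncertainty(X[, j], y), suOracle(X[, j], y),
                 tolerance = 1e-12, info = j)
})

test_that("best-first search recovers planted signal and matches exhaustive
           search on a small table", {
  # planted: one perfect column among 60 noise columns
  tb <- randomBinaryTable(n = 120, p = 60, seed = 23, planted = 1L)
  sel <- bestFirstSelect(tb$X, tb$labels)
  expect_true("signal:0" %in% sel)
  # merit of the winner is at least that of every singleton
  singles <- vapply(colnames(tb$X), function(j) cfsMerit(j, tb$X, tb$labels),
                    numeric(1))
  expect_gte(attr(sel, "merit") + 1e-12, max(singles))
  # determinism
  expect_identical(sel, bestFirstSelect(tb$X, tb$labels))

  # exhaustive-search oracle on a 10-column table
  set.seed(24)
  y <- factor(rep(c("a", "b"), each = 25))
  X <- cbind(
    sapply(1:3, function(i) {                 # noisy informative bits
      z <- as.integer(y == "a"); flip <- rbinom(50, 1, 0.12)
      as.integer(xor(z, flip))
    }),
    matrix(rbinom(50 * 7, 1, 0.5), 50, 7))
  colnames(X) <- sprintf("t:%d", 0:9)
  sel <- bestFirstSelect(X, y)
  allSubsets <- unlist(lapply(1:10, function(k)
    utils::combn(colnames(X), k, simplify = FALSE)), recursive = FALSE)
  merits <- vapply(allSubsets, function(s) cfsMerit(s, X, y), numeric(1))
  expect_equal(attr(sel, "merit"), max(merits), tolerance = 1e-9)
  expect_setequal(sel, allSubsets[[which.max(merits)]])
})

test_that("hybrid concatenates per-family selections and projects exactly", {
  set.seed(25)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  mkFam <- function(fam, planted) {
    P <- sapply(seq_len(planted), function(i)
      as.integer(y == levels(y)[1 + (i %% 3)]))
    X <- cbind(P, matrix(rbinom(60 * 20, 1, 0.5), 60, 20))
    colnames(X) <- paste0(fam, ":", seq_len(ncol(X)) - 1L)
    X
  }
  X <- cbind(mkFam("fp2like", 3), mkFam("maccslike", 3))
  spec <- buildHybrid(X, y)
  planted <- c(paste0("fp2like:", 0:2), paste0("maccslike:", 0:2))
  expect_true(all(planted %in% hybridBits(spec)))
  # family blocks stay in registration order
  fams <- sub(":.*", "", hybridBits(spec))
  expect_identical(fams, fams[order(match(fams, c("fp2like", "maccslike")))])
  # single family: hybrid equals that family's own selection
  X1 <- mkFam("fp4like", 2)
  spec1 <- buildHybrid(X1, y)
  surv <- removeUseless(X1, y)
  expect_identical(hybridBits(spec1),
                   as.character(bestFirstSelect(X1[, surv, drop = FALSE], y)))
  # projection has exactly the selected columns; row order never matters
  P <- projectHybrid(X, spec)
  expect_identical(colnames(P), hybridBits(spec))
  perm <- sample(nrow(X))
  expect_identical(hybridBits(buildHybrid(X[perm, ], y[perm])),
                   hybridBits(spec))
  # JSON round trip
  tmp <- tempfile(fileext = ".json")
  writeHybridSpec(spec, tmp)
  expect_identical(hybridBits(readHybridSpec(tmp)), hybridBits(spec))
})
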