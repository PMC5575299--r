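# Shared, lazily-built fixture bundles. Built once per test run; every
# downstream assertion reads the generator's ground truth, never re-derived
# labels.

.bundleCache <- new.env(parent = emptyenv())

fixtureBundle <- function(preset = "tiny", seed = 7L) {
  key <- paste(preset, seed, sep = "_")
  if (is.null(.bundleCache[[key]])) {
    fx <- fixturePreset(preset, seed = seed)
    sub <- generateSubstrates(fx)
    db <- suppressWarnings(buildSubstrateDB(sub$raw))
    rec <- substrateRecords(db)
    M <- fingerprintMatrix(stats::setNames(rec$smiles, rec$id))
    labels <- substrateLabels(db)
    .bundleCache[[key]] <- list(fx = fx, sub = sub, db = db, M = M,
                                labels = labels)
  }
  .bundleCache[[key]]
}

# separable6 bundle extended with hybrid spec and trained cascade
trainedBundle <- function(seed = 42L) {
  key <- paste0("trained_", seed)
  if (is.null(.bundleCache[[key]])) {
    b <- fixtureBundle("separable6", seed)
    spec <- buildHybrid(b$M, b$labels$group)
    model <- trainCascade(b$db, spec, seed = seed, features = b$M)
    ew <- generateEnzymeWorld(b$sub, seed = seed)
    edb <- buildEnzymeDB(filterBestHits(ew$hits), ew$protein2genome,
                         ew$taxonomy)
    .bundleCache[[key]] <- c(b, list(spec = spec, model = model, ew = ew,
                                     edb = edb))
  }
  .bundleCache[[key]]
}

# independent instance-level metric recomputation (oracle for Eqs-style
# formulas): builds explicit truth/pred label vectors from counts and
# recomputes every metric from first principles
metricsFromInstances <- function(TP, FP, FN, TN) {
  truth <- c(rep(1, TP), rep(0, FP), rep(1, FN), rep(0, TN))
  pred  <- c(rep(1, TP), rep(1, FP), rep(0, FN), rep(0, TN))
  tp <- sum(truth == 1 & pred == 1); fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0); tn <- sum(truth == 0 & pred == 0)
  den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(TPR = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    TNR = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    PPV = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    ACC = 100 * (tp + tn) / (tp + fp + fn + tn),
    MCC = if (den == 0) 0 else (tp * tn - fp * fn) / den)
}

# random binary feature table with an optional planted predictive column
randomBinaryTable <- function(n, p, seed, planted = 0L, labels = NULL) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1L, 0.4), n, p)
  colnames(X) <- sprintf("noise:%d", seq_len(p) - 1L)
  if (is.null(labels)) labels <- factor(rep(c("a", "b"), length.out = n))
  if (planted > 0L) {
    P <- sapply(seq_len(planted), function(i) as.integer(labels == levels(labels)[1L]))
    colnames(P) <- sprintf("signal:%d", seq_len(planted) - 1L)
    X <- cbind(P, X)
  }
  list(X = X, labels = labels)
}
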