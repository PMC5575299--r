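#' Model evaluation: metrics, validation protocols, PCA diagnostic
#'
#' Performance is summarised per class (one-vs-rest) by five quantities of
#' the confusion counts TP/FP/FN/TN:
#' `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `ACC = (TP+TN)/(TP+FP+FN+TN)` (all reported as percentages) and the
#' Matthews correlation coefficient
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero MCC denominator yields MCC = 0 (the standard convention); a zero
#' denominator of a rate yields NA. Multi-class results are one-vs-rest per
#' class and macro-averaged.
#'
#' Three validation protocols are provided: stratified ten-fold
#' cross-validation, a stratified 75/25 split, and a blind protocol that
#' withdraws 10 % of each class before any training, evaluates once on the
#' withdrawn set, and then retrains the production model on all data.
#' Upsampling, when requested, is always applied inside the training
#' partition only, so no held-out instance is ever duplicated into
#' training.
#'
#' @name evaluation
NULL

#' Confusion counts for a one-vs-rest class
#'
#' @param truth,pred label vectors of equal length.
#' @param positive the class treated as positive.
#' @return named integer vector `TP`, `FP`, `FN`, `TN`.
#' @export
confusionCounts <- function(truth, pred, positive) {
  stopifnot(length(truth) == length(pred))
  t1 <- truth == positive
  p1 <- pred == positive
  c(TP = sum(t1 & p1), FP = sum(!t1 & p1),
    FN = sum(t1 & !p1), TN = sum(!t1 & !p1))
}

#' Classification metrics from confusion counts
#'
#' @param counts named vector with `TP`, `FP`, `FN`, `TN` (or four numbers
#'   in that order).
#' @return named numeric vector: `TPR`, `TNR`, `PPV`, `ACC` (percent) and
#'   `MCC`.
#' @export
classificationMetrics <- function(counts) {
  if (is.null(names(counts))) names(counts) <- c("TP", "FP", "FN", "TN")
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  FN <- as.numeric(counts[["FN"]]); TN <- as.numeric(counts[["TN"]])
  total <- TP + FP + FN + TN
  if (total <= 0) stop("no evaluated instances")
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (mccDen == 0) 0 else (TP * TN - FP * FN) / mccDen
  c(TPR = rate(TP, TP + FN), TNR = rate(TN, TN + FP),
    PPV = rate(TP, TP + FP), ACC = 100 * (TP + TN) / total, MCC = mcc)
}

# one-vs-rest metrics per class + macro summary from pooled label vectors
.metricReport <- function(truth, pred) {
  classes <- sort(unique(as.character(truth)))
  per <- t(vapply(classes, function(k)
    classificationMetrics(confusionCounts(as.character(truth),
                                          as.character(pred), k)),
    numeric(5L)))
  macro <- colMeans(per, na.rm = TRUE)
  overall <- 100 * mean(as.character(truth) == as.character(pred))
  list(perClass = as.data.frame(per),
       macro = macro,
       overallAccuracy = overall)
}

# stratified fold assignment: per class, seeded shuffle then round-robin;
# a running offset keeps all folds evenly filled even when classes are
# smaller than the fold count (e.g. leave-one-out)
.stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  offset <- 0L
  withSeed(seed, {
    for (k in unique(y)) {
      idx <- which(y == k)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% folds) + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a random-forest classifier
#'
#' @param X feature matrix (rows named by instance id).
#' @param y class labels aligned with rows.
#' @param folds number of folds (default 10; must be >= 2).
#' @param seed integer seed (fold assignment, upsampling, forests).
#' @param sampling `"with_upsampling"` or `"without_upsampling"`; upsampling
#'   is applied to each training partition only.
#' @param mtry,ntree forest hyperparameters (defaults `round(sqrt(p))`, 500).
#' @return list: `perClass` (one-vs-rest metrics on counts pooled over
#'   folds), `macro`, `overallAccuracy`, `predictions` (data.frame `id`,
#'   `fold`, `truth`, `pred`).
#' @export
crossValidate <- function(X, y, folds = 10L, seed = 1L,
                          sampling = c("with_upsampling", "without_upsampling"),
                          mtry = NULL, ntree = 500L) {
  sampling <- match.arg(sampling)
  if (folds < 2L) stop("folds must be >= 2")
  y <- droplevels(factor(y))
  small <- names(which(table(y) < folds))
  if (length(small))
    warning("class(es) with fewer members than folds: ",
            paste(small, collapse = ", "))
  if (is.null(mtry)) mtry <- max(1L, as.integer(roundHalfUp(sqrt(ncol(X)))))
  fold <- .stratifiedFolds(as.character(y), folds, seed)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (f in seq_len(folds)) {
    if (!any(fold == f)) next
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- droplevels(y[tr])
    if (sampling == "with_upsampling" && nlevels(ytr) >= 2L) {
      bal <- upsampleBalance(Xtr, ytr, seed = seed + f)
      Xtr <- bal$X; ytr <- bal$y
    }
    rf <- withSeed(seed + f, {
      randomForest::randomForest(x = Xtr, y = ytr,
                                 mtry = min(mtry, ncol(X)), ntree = ntree)
    })
    pred[fold == f] <- stats::predict(rf, X[fold == f, , drop = FALSE])
  }
  rep <- .metricReport(y, pred)
  rep$predictions <- data.frame(
    id = rownames(X) %||% seq_along(y), fold = fold,
    truth = as.character(y), pred = as.character(pred),
    stringsAsFactors = FALSE)
  rep
}

#' Stratified train/test split evaluation
#'
#' @param X,y,seed,sampling,mtry,ntree as in [crossValidate()].
#' @param trainFrac fraction of each class used for training (default 0.75).
#' @return list as in [crossValidate()] plus `trainIds`/`testIds`.
#' @export
splitAndTest <- function(X, y, trainFrac = 0.75, seed = 1L,
                         sampling = c("with_upsampling", "without_upsampling"),
                         mtry = NULL, ntree = 500L) {
  sampling <- match.arg(sampling)
  stopifnot(trainFrac > 0, trainFrac < 1)
  y <- droplevels(factor(y))
  if (is.null(mtry)) mtry <- max(1L, as.integer(roundHalfUp(sqrt(ncol(X)))))
  train <- logical(length(y))
  withSeed(seed, {
    for (k in levels(y)) {
      idx <- which(y == k)
      nTr <- max(1L, as.integer(roundHalfUp(trainFrac * length(idx))))
      nTr <- min(nTr, length(idx))
      train[sample(idx, nTr)] <- TRUE
    }
  })
  emptyTest <- levels(y)[!levels(y) %in% y[!train]]
  if (length(emptyTest))
    warning("class(es) with no test members, excluded from per-class report: ",
            paste(emptyTest, collapse = ", "))
  Xtr <- X[train, , drop = FALSE]; ytr <- droplevels(y[train])
  if (sampling == "with_upsampling" && nlevels(ytr) >= 2L) {
    bal <- upsampleBalance(Xtr, ytr, seed = seed)
    Xtr <- bal$X; ytr <- bal$y
  }
  rf <- withSeed(seed, {
    randomForest::randomForest(x = Xtr, y = ytr,
                               mtry = min(mtry, ncol(X)), ntree = ntree)
  })
  pred <- stats::predict(rf, X[!train, , drop = FALSE])
  rep <- .metricReport(droplevels(y[!train]), pred)
  rep$trainIds <- rownames(X)[train]
  rep$testIds <- rownames(X)[!train]
  rep$predictions <- data.frame(id = rep$testIds %||% which(!train),
                                truth = as.character(y[!train]),
                                pred = as.character(pred),
                                stringsAsFactors = FALSE)
  rep
}

#' Per-class blind-set allocation
#'
#' Selects, per class, `round(frac * n)` members (round-half-up, at least
#' one where the class has two or more members; singleton classes
#' contribute none) for the blind set.
#'
#' @param y class labels.
#' @param frac per-class blind fraction in (0, 1).
#' @param seed integer seed.
#' @return logical mask over `y`: TRUE = withdrawn into the blind set.
#' @export
blindAllocation <- function(y, frac = 0.10, seed = 1L) {
  stopifnot(frac > 0, frac < 1)
  y <- droplevels(factor(y))
  blind <- logical(length(y))
  withSeed(seed, {
    for (k in levels(y)) {
      idx <- which(y == k)
      if (length(idx) < 2L) next   # singleton class: no blind member
      nB <- max(1L, as.integer(roundHalfUp(frac * length(idx))))
      nB <- min(nB, length(idx) - 1L)
      blind[sample(idx, nB)] <- TRUE
    }
  })
  blind
}

#' Blind-set protocol
#'
#' Withdraws a per-class fraction (round-half-up, at least one member where
#' the class has >= 2 records; singleton classes contribute none) before
#' any training, trains on the remainder, evaluates once on the blind set,
#' and finally retrains the production forest on the full data.
#'
#' @param X,y,seed,sampling,mtry,ntree as in [crossValidate()].
#' @param frac per-class blind fraction in (0, 1) (default 0.10).
#' @return list as in [crossValidate()] plus `blindIds` and `finalModel`
#'   (the forest retrained on all data).
#' @export
blindProtocol <- function(X, y, frac = 0.10, seed = 1L,
                          sampling = c("with_upsampling", "without_upsampling"),
                          mtry = NULL, ntree = 500L) {
  sampling <- match.arg(sampling)
  stopifnot(frac > 0, frac < 1)
  y <- droplevels(factor(y))
  if (is.null(mtry)) mtry <- max(1L, as.integer(roundHalfUp(sqrt(ncol(X)))))
  blind <- blindAllocation(y, frac, seed)
  Xtr <- X[!blind, , drop = FALSE]; ytr <- droplevels(y[!blind])
  if (sampling == "with_upsampling" && nlevels(ytr) >= 2L) {
    bal <- upsampleBalance(Xtr, ytr, seed = seed)
    Xtr <- bal$X; ytr <- bal$y
  }
  rf <- withSeed(seed, {
    randomForest::randomForest(x = Xtr, y = ytr,
                               mtry = min(mtry, ncol(X)), ntree = ntree)
  })
  pred <- stats::predict(rf, X[blind, , drop = FALSE])
  rep <- .metricReport(droplevels(y[blind]), pred)
  rep$blindIds <- rownames(X)[blind]
  rep$predictions <- data.frame(id = rep$blindIds %||% which(blind),
                                truth = as.character(y[blind]),
                                pred = as.character(pred),
                                stringsAsFactors = FALSE)
  # production model: retrained on the complete data
  Xall <- X; yall <- y
  if (sampling == "with_upsampling") {
    bal <- upsampleBalance(Xall, yall, seed = seed)
    Xall <- bal$X; yall <- bal$y
  }
  rep$finalModel <- withSeed(seed, {
    randomForest::randomForest(x = Xall, y = yall,
                               mtry = min(mtry, ncol(X)), ntree = ntree)
  })
  rep
}

#' PCA diversity diagnostic
#'
#' Principal component analysis (centred, unscaled) of a feature table, as
#' a diagnostic of the structural diversity spanned by the substrate
#' database under the hybrid fingerprint.
#'
#' @param X numeric matrix (>= 2 rows).
#' @param nComponents number of component coordinates to return (default 2).
#' @return list: `varianceFraction` (non-increasing, sums to 1 over full
#'   rank), `coordinates` (rows x `nComponents`), `prcomp` (the fit).
#' @export
pcaDiagnostic <- function(X, nComponents = 2L) {
  stopifnot(nrow(X) >= 2L)
  if (all(apply(X, 2L, function(c) length(unique(c)) == 1L)))
    stop("constant feature matrix: PCA undefined")
  fit <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  k <- min(nComponents, ncol(fit$x))
  list(varianceFraction = vf, coordinates = fit$x[, seq_len(k), drop = FALSE],
       prcomp = fit)
}
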