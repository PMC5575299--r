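#' The two-level random-forest cascade
#'
#' One random forest discriminates the six EC classes; six class-specific
#' forests discriminate each class's subclasses. All models train on
#' features projected through a shared [HybridSpec-class]. Class imbalance
#' is addressed by upsampling (random sampling with replacement of minority
#' classes up to the majority count); hyperparameters are tuned by
#' out-of-bag (OOB) error: `mtry` with an outward search from
#' `round(sqrt(p))` (step factor 2, relative-improvement threshold 0.05),
#' `ntree` over the grid 100..500 in steps of 100 with ties resolved toward
#' the larger, saturated value.
#'
#' @name models
NULL

#' Upsample minority classes to the majority count
#'
#' Random sampling with replacement within each minority class until every
#' class matches the majority class count. All original rows are retained;
#' duplicates come only from their own class.
#'
#' @param X feature matrix (rows = instances).
#' @param y class labels (>= 2 classes required).
#' @param seed integer seed making the resampling reproducible.
#' @return list with balanced `X` and `y`.
#' @export
upsampleBalance <- function(X, y, seed = 1L) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("upsampling requires at least two classes")
  y <- droplevels(y)
  withSeed(seed, {
    up <- caret::upSample(x = as.data.frame(X), y = y, list = TRUE)
  })
  Xb <- as.matrix(up$x)
  colnames(Xb) <- colnames(X)
  if (is.integer(X)) storage.mode(Xb) <- "integer"
  list(X = Xb, y = up$y)
}

#' Tune mtry by out-of-bag error
#'
#' Wraps the randomForest `tuneRF` search: starting from
#' `round(sqrt(p))` (round-half-up), `mtry` is multiplied/divided by
#' `stepFactor` and the search continues in a direction while the relative
#' OOB improvement is at least `improve`. Every probed value and its OOB
#' error is recorded in the trace; the returned `mtry` attains the trace
#' minimum.
#'
#' @param X feature matrix (p >= 1 columns).
#' @param y class labels.
#' @param ntreeProbe trees per probe forest (default 100).
#' @param stepFactor,improve search controls (defaults 2 and 0.05).
#' @param seed integer seed.
#' @return list: `mtry`, `ntree` (= `ntreeProbe`), `oob_error_percent`,
#'   `trace` (data.frame `mtry`, `oob_error_percent`).
#' @export
tuneMtry <- function(X, y, ntreeProbe = 100L, stepFactor = 2, improve = 0.05,
                     seed = 1L) {
  p <- ncol(X)
  if (is.null(p) || p < 1L) stop("feature table has no columns")
  y <- droplevels(factor(y))
  start <- max(1L, min(p, as.integer(roundHalfUp(sqrt(p)))))
  if (p == 1L) {
    oob <- withSeed(seed, {
      rf <- randomForest::randomForest(x = X, y = y, ntree = ntreeProbe, mtry = 1L)
      mean(rf$predicted != y) * 100
    })
    return(list(mtry = 1L, ntree = as.integer(ntreeProbe),
                oob_error_percent = oob,
                trace = data.frame(mtry = 1L, oob_error_percent = oob)))
  }
  res <- withSeed(seed, {
    utils::capture.output(
      tr <- try(randomForest::tuneRF(x = X, y = y, mtryStart = start,
                                     ntreeTry = ntreeProbe,
                                     stepFactor = stepFactor, improve = improve,
                                     trace = FALSE, plot = FALSE),
                silent = TRUE))
    tr
  })
  if (inherits(res, "try-error")) {
    # degenerate data (e.g. zero OOB error at the start value): fall back to
    # probing the start value alone
    oob <- withSeed(seed, {
      rf <- randomForest::randomForest(x = X, y = y, ntree = ntreeProbe,
                                       mtry = start)
      mean(rf$predicted != y) * 100
    })
    return(list(mtry = start, ntree = as.integer(ntreeProbe),
                oob_error_percent = oob,
                trace = data.frame(mtry = start, oob_error_percent = oob)))
  }
  trace <- data.frame(mtry = as.integer(res[, "mtry"]),
                      oob_error_percent = 100 * res[, "OOBError"],
                      row.names = NULL)
  bestAt <- which.min(trace$oob_error_percent)
  list(mtry = trace$mtry[bestAt], ntree = as.integer(ntreeProbe),
       oob_error_percent = trace$oob_error_percent[bestAt], trace = trace)
}

#' Select ntree over a saturation grid
#'
#' Fits a forest at each grid value and returns the one with the lowest OOB
#' error; ties are resolved toward the largest value (the saturated
#' reading).
#'
#' @param X,y training data.
#' @param mtry variables sampled per split.
#' @param grid candidate tree counts (default 100..500 step 100).
#' @param seed integer seed.
#' @return the chosen ntree (integer); attribute `"trace"` holds the grid
#'   scan.
#' @export
selectNtree <- function(X, y, mtry, grid = seq(100L, 500L, by = 100L),
                        seed = 1L) {
  stopifnot(length(grid) >= 1L)
  y <- droplevels(factor(y))
  oob <- vnapply(grid, function(nt) {
    withSeed(seed, {
      rf <- randomForest::randomForest(x = X, y = y, ntree = nt, mtry = mtry)
      unname(rf$err.rate[nt, "OOB"]) * 100
    })
  })
  best <- max(grid[oob == min(oob)])   # ties -> largest ntree
  out <- as.integer(best)
  attr(out, "trace") <- data.frame(ntree = as.integer(grid),
                                   oob_error_percent = oob)
  out
}

# fit one tuned forest; returns list(model, tuning)
.fitTunedForest <- function(X, y, sampling, seed, tune = TRUE,
                            ntreeGrid = seq(100L, 500L, by = 100L),
                            ntreeDefault = 500L) {
  y <- droplevels(factor(y))
  if (sampling == "with_upsampling" && nlevels(y) >= 2L) {
    bal <- upsampleBalance(X, y, seed = seed)
    X <- bal$X; y <- bal$y
  }
  if (tune) {
    tun <- tuneMtry(X, y, seed = seed)
    nt <- selectNtree(X, y, tun$mtry, grid = ntreeGrid, seed = seed)
    tuning <- list(mtry = tun$mtry, ntree = as.integer(nt),
                   oob_error_percent = tun$oob_error_percent,
                   trace = tun$trace, ntree_trace = attr(nt, "trace"))
  } else {
    tuning <- list(mtry = max(1L, as.integer(roundHalfUp(sqrt(ncol(X))))),
                   ntree = as.integer(ntreeDefault),
                   oob_error_percent = NA_real_, trace = NULL,
                   ntree_trace = NULL)
  }
  model <- withSeed(seed, {
    randomForest::randomForest(x = X, y = y, mtry = tuning$mtry,
                               ntree = tuning$ntree)
  })
  tuning$oob_error_percent <- unname(model$err.rate[tuning$ntree, "OOB"]) * 100
  list(model = model, tuning = tuning, counts = as.list(table(y)))
}

#' Train the EC class / subclass random-forest cascade
#'
#' Trains the class-level forest on all curated records labelled by their EC
#' class digit, and one subclass forest per class on that class's records
#' labelled by subclass digit. Subclasses with fewer than `minSubclassN`
#' records are excluded from subclass training (they remain in the
#' similarity database); a class left with fewer than two trainable
#' subclasses gets no subclass model and predictions into it fall back to
#' the class-level output.
#'
#' @param db a [SubstrateDB-class].
#' @param spec a [HybridSpec-class].
#' @param sampling `"with_upsampling"` (default) or `"without_upsampling"`.
#' @param seed integer seed governing upsampling, tuning and forests.
#' @param tune run OOB tuning per model (default TRUE); when FALSE, `mtry =
#'   round(sqrt(p))` and `ntree = 500` are used directly.
#' @param minSubclassN minimum records for a subclass to enter training
#'   (default 2).
#' @param features optional precomputed full feature matrix (rows named by
#'   record id) to avoid recomputing fingerprints.
#' @return a [CascadeModel-class].
#' @export
trainCascade <- function(db, spec,
                         sampling = c("with_upsampling", "without_upsampling"),
                         seed = 1L, tune = TRUE, minSubclassN = 2L,
                         features = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(is(db, "SubstrateDB"), is(spec, "HybridSpec"))
  rec <- db@records
  if (is.null(features)) {
    features <- fingerprintMatrix(stats::setNames(rec$smiles, rec$id),
                                  families = spec@families)
  }
  X <- projectHybrid(features, spec)[rec$id, , drop = FALSE]
  yClass <- factor(viapply(rec$ecTags, function(t) unique(ecClass(t))[1L]),
                   levels = 1:6)
  if (any(table(droplevels(yClass)) < 2L))
    warning("EC class with < 2 records; class model may be unreliable")
  cls <- .fitTunedForest(X, yClass, sampling, seed, tune = tune)
  tuning <- list(class = cls$tuning)
  counts <- list(class = cls$counts)
  subModels <- list()
  for (cd in sort(unique(as.integer(as.character(droplevels(yClass)))))) {
    sel <- which(as.integer(as.character(yClass)) == cd)
    ySub <- viapply(rec$ecTags[sel], function(t) {
      m <- ecParse(t)
      as.integer(m[1L, 2L])      # primary tag's subclass digit
    })
    tab <- table(ySub)
    keep <- ySub %in% as.integer(names(tab)[tab >= minSubclassN])
    if (length(unique(ySub[keep])) < 2L) {
      warning("class ", cd, ": fewer than 2 trainable subclasses; ",
              "no subclass model (falls back to class-level output)")
      next
    }
    fit <- .fitTunedForest(X[sel[keep], , drop = FALSE],
                           factor(ySub[keep]), sampling, seed, tune = tune)
    subModels[[as.character(cd)]] <- fit$model
    tuning[[paste0("subclass_", cd)]] <- fit$tuning
    counts[[paste0("subclass_", cd)]] <- fit$counts
  }
  new("CascadeModel", classModel = cls$model, subclassModels = subModels,
      hybridSpec = spec, sampling = sampling, tuning = tuning,
      seed = as.integer(seed), specKey = contentKey(spec@selected),
      trainingCounts = counts)
}

# query feature vector -> 1-row matrix in the model's training column order
.queryRow <- function(model, fp) {
  cols <- model@hybridSpec@selected
  if (is.matrix(fp)) {
    if (!all(cols %in% colnames(fp))) stop("query features lack hybrid columns")
    fp <- fp[1L, cols]
  } else {
    if (is.null(names(fp)) || !all(cols %in% names(fp)))
      stop("query features lack hybrid columns")
    fp <- fp[cols]
  }
  matrix(fp, nrow = 1L, dimnames = list(NULL, cols))
}

#' Predict the EC class of a query
#'
#' @param model a [CascadeModel-class].
#' @param fp named feature vector (or 1-row matrix) covering the model's
#'   hybrid columns; extra columns are ignored.
#' @param threshold minimum winning probability; below it the query is
#'   `"unclassified"` (`classDigit = NA`). Default 0 (always emit argmax).
#' @return list: `classDigit` (integer or NA), `probs` (named, sums to 1).
#' @export
predictClass <- function(model, fp, threshold = 0) {
  stopifnot(is(model, "CascadeModel"))
  row <- .queryRow(model, fp)
  probs <- stats::predict(model@classModel, row, type = "prob")[1L, ]
  top <- names(probs)[which.max(probs)]
  if (max(probs) < threshold)
    return(list(classDigit = NA_integer_, probs = probs))
  list(classDigit = as.integer(top), probs = probs)
}

#' Predict the EC subclass within a predicted class
#'
#' @param model a [CascadeModel-class].
#' @param classDigit the class whose subclass model to apply.
#' @param fp,threshold as in [predictClass()].
#' @return list: `subclassDigit` (integer or NA), `probs`, and `outcome`
#'   (`"ok"`, `"unclassified"` or `"no-subclass-model"`).
#' @export
predictSubclass <- function(model, classDigit, fp, threshold = 0) {
  stopifnot(is(model, "CascadeModel"))
  sub <- model@subclassModels[[as.character(classDigit)]]
  if (is.null(sub))
    return(list(subclassDigit = NA_integer_, probs = numeric(0),
                outcome = "no-subclass-model"))
  row <- .queryRow(model, fp)
  probs <- stats::predict(sub, row, type = "prob")[1L, ]
  top <- names(probs)[which.max(probs)]
  if (max(probs) < threshold)
    return(list(subclassDigit = NA_integer_, probs = probs,
                outcome = "unclassified"))
  list(subclassDigit = as.integer(top), probs = probs, outcome = "ok")
}
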