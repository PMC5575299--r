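#' Hybrid-fingerprint feature selection
#'
#' Builds the hybrid fingerprint in two stages, applied per family and then
#' concatenated in family registration order:
#'
#' 1. *Remove useless*: drop bits that are constant or nearly constant
#'    (majority-value frequency above a dominance threshold) -- such bits
#'    cannot discriminate EC classes.
#' 2. *Correlation-based feature-subset selection (CFS)* with best-first
#'    search: find a subset of bits that is highly associated with the class
#'    label while mutually non-redundant. The association measure is the
#'    symmetric uncertainty `SU(X, Y) = 2 I(X;Y) / (H(X) + H(Y))`, and a
#'    subset of size k is scored by the CFS merit
#'    `k * mean(SU(bit, class)) / sqrt(k + k (k-1) * mean(SU(bit, bit')))`.
#'
#' The search starts from the empty subset, expands states by single-bit
#' addition or removal, always expanding the best-merit open state, and
#' stops after `maxStale` consecutive non-improving expansions.
#'
#' @name feature-select
NULL

entropyBits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Symmetric uncertainty between two discrete vectors
#'
#' `SU = 2 I(X;Y) / (H(X) + H(Y))`, in `[0, 1]`; defined as 0 when either
#' variable has zero entropy (the zero-variance convention).
#'
#' @param x,y vectors of equal length (coerced to factors).
#' @return a single numeric value.
#' @export
symmetricUncertainty <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  px <- rowSums(tab) / n
  py <- colSums(tab) / n
  hx <- entropyBits(px)
  hy <- entropyBits(py)
  if (hx == 0 || hy == 0) return(0)
  p <- tab / n
  expd <- outer(px, py)
  nz <- p > 0
  mi <- sum(p[nz] * log2(p[nz] / expd[nz]))
  2 * mi / (hx + hy)
}

# vectorized SU of every column of binary X against factor y
.suColumnsClass <- function(X, y) {
  y <- factor(y)
  n <- nrow(X)
  Yind <- stats::model.matrix(~ y - 1)
  n1k <- crossprod(X, Yind)                    # p x K, counts X=1 & class k
  nk <- colSums(Yind)
  n0k <- matrix(nk, nrow = ncol(X), ncol = length(nk), byrow = TRUE) - n1k
  p1 <- colSums(X) / n
  pk <- nk / n
  hy <- entropyBits(pk)
  miTerm <- function(cnt, pxv) {
    p <- cnt / n
    expd <- outer(pxv, pk)
    t <- p * log2(p / expd)
    t[cnt == 0] <- 0
    rowSums(t)
  }
  mi <- miTerm(n1k, p1) + miTerm(n0k, 1 - p1)
  hx <- vnapply(p1, function(p) entropyBits(c(p, 1 - p)))
  su <- ifelse(hx == 0 | hy == 0, 0, 2 * mi / (hx + hy))
  stats::setNames(pmax(su, 0), colnames(X))
}

# vectorized pairwise SU matrix among the columns of binary X
.suColumnsPairwise <- function(X) {
  n <- nrow(X)
  c1 <- colSums(X)
  n11 <- crossprod(X)
  n10 <- matrix(c1, ncol(X), ncol(X)) - n11
  n01 <- t(n10)
  n00 <- n - n11 - n10 - n01
  p1 <- c1 / n
  term <- function(cnt, pxi, pyj) {
    p <- cnt / n
    expd <- outer(pxi, pyj)
    t <- p * log2(p / expd)
    t[cnt == 0] <- 0
    t
  }
  mi <- term(n11, p1, p1) + term(n10, p1, 1 - p1) +
        term(n01, 1 - p1, p1) + term(n00, 1 - p1, 1 - p1)
  hx <- vnapply(p1, function(p) entropyBits(c(p, 1 - p)))
  denom <- outer(hx, hx, "+")
  su <- 2 * mi / denom
  su[outer(hx == 0, hx == 0, "|")] <- 0
  dimnames(su) <- list(colnames(X), colnames(X))
  pmax(su, 0)
}

#' Remove uninformative fingerprint bits
#'
#' Drops constant columns and columns whose majority value occurs in more
#' than `maxDominance` of the rows. Survivors keep their original order.
#'
#' @param X binary 0/1 matrix with column names.
#' @param labels class labels (unused by the frequency scan; accepted so the
#'   two selection stages share one signature).
#' @param maxDominance maximum allowed majority-value frequency (default
#'   0.99); a column at exactly the threshold is retained.
#' @return character vector of surviving column ids.
#' @export
removeUseless <- function(X, labels = NULL, maxDominance = 0.99) {
  stopifnot(is.matrix(X), !is.null(colnames(X)))
  f1 <- colSums(X) / nrow(X)
  dominance <- pmax(f1, 1 - f1)
  keep <- dominance <= maxDominance
  if (!any(keep))
    stop("remove_useless eliminated all ", ncol(X), " columns ",
         "(max dominance threshold ", maxDominance, "); ",
         "most dominant column frequency = ", max(dominance))
  colnames(X)[keep]
}

#' CFS merit of a feature subset
#'
#' @param subset character vector of column ids (non-empty).
#' @param X binary 0/1 matrix.
#' @param labels class labels aligned with rows of `X`.
#' @return the CFS merit (numeric scalar).
#' @export
cfsMerit <- function(subset, X, labels) {
  stopifnot(length(subset) >= 1L, all(subset %in% colnames(X)))
  suCF <- .suColumnsClass(X[, subset, drop = FALSE], labels)
  k <- length(subset)
  rcf <- mean(suCF)
  if (k == 1L) return(rcf)
  suFF <- .suColumnsPairwise(X[, subset, drop = FALSE])
  rff <- mean(suFF[upper.tri(suFF)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

# merit from cached SU structures, by integer column indices
.meritCached <- function(idx, suCF, suFF) {
  k <- length(idx)
  if (k == 0L) return(0)
  rcf <- mean(suCF[idx])
  if (k == 1L) return(rcf)
  s <- suFF[idx, idx]
  rff <- mean(s[upper.tri(s)])
  k * rcf / sqrt(k + k * (k - 1) * rff)
}

#' Best-first CFS subset search
#'
#' Greedy best-first search over bit subsets scored by CFS merit: starts at
#' the empty subset, expands states by single-column addition or removal,
#' keeps an open list ordered by merit, and stops after `maxStale`
#' consecutive expansions that fail to improve on the best merit seen.
#' Deterministic: columns are scanned in order and merit ties favour the
#' earlier state.
#'
#' @param X binary 0/1 matrix with column names.
#' @param labels class labels aligned with rows.
#' @param maxStale consecutive non-improving expansions tolerated (default 5).
#' @return character vector of selected column ids, in original column
#'   order; attribute `"merit"` carries the winning merit.
#' @export
bestFirstSelect <- function(X, labels, maxStale = 5L) {
  stopifnot(is.matrix(X), ncol(X) >= 1L)
  suCF <- .suColumnsClass(X, labels)
  suFF <- .suColumnsPairwise(X)
  p <- ncol(X)
  keyOf <- function(idx) paste0("k", paste(idx, collapse = ","))
  closed <- new.env(hash = TRUE, parent = emptyenv())
  openIdx <- list(integer(0))
  openMerit <- 0
  assign(keyOf(integer(0)), TRUE, envir = closed)
  best <- integer(0)
  bestMerit <- 0
  stale <- 0L
  eps <- 1e-10
  while (length(openIdx) > 0L && stale < maxStale) {
    at <- which.max(openMerit)        # ties -> earliest inserted
    state <- openIdx[[at]]
    openIdx <- openIdx[-at]
    openMerit <- openMerit[-at]
    improved <- FALSE
    neighbours <- c(lapply(setdiff(seq_len(p), state), function(j) sort(c(state, j))),
                    if (length(state) > 1L) lapply(seq_along(state), function(i) state[-i]))
    for (nb in neighbours) {
      key <- keyOf(nb)
      if (!is.null(closed[[key]])) next
      assign(key, TRUE, envir = closed)
      m <- .meritCached(nb, suCF, suFF)
      openIdx[[length(openIdx) + 1L]] <- nb
      openMerit <- c(openMerit, m)
      if (m > bestMerit + eps) {
        bestMerit <- m
        best <- nb
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  out <- colnames(X)[sort(best)]
  attr(out, "merit") <- bestMerit
  out
}

#' Build the hybrid fingerprint specification
#'
#' For each family in registration order: restrict the feature table to that
#' family's columns, drop uninformative bits, run best-first CFS selection,
#' then concatenate the survivors. A family contributing zero bits is
#' allowed (and recorded).
#'
#' @param X full binary feature table with `"family:bit"` column names (as
#'   from [fingerprintMatrix()]).
#' @param labels class labels aligned with rows.
#' @param maxDominance passed to [removeUseless()].
#' @param maxStale passed to [bestFirstSelect()].
#' @return a [HybridSpec-class].
#' @export
buildHybrid <- function(X, labels, maxDominance = 0.99, maxStale = 5L) {
  stopifnot(is.matrix(X), !is.null(colnames(X)), nrow(X) == length(labels))
  fams <- sub(":.*$", "", colnames(X))
  famOrder <- names(.fpFamilies)[names(.fpFamilies) %in% unique(fams)]
  if (!length(famOrder)) famOrder <- unique(fams)
  selected <- character(0)
  perFamily <- integer(0)
  for (f in famOrder) {
    Xf <- X[, fams == f, drop = FALSE]
    surv <- tryCatch(removeUseless(Xf, labels, maxDominance),
                     error = function(e) character(0))
    sel <- if (length(surv))
      bestFirstSelect(Xf[, surv, drop = FALSE], labels, maxStale)
    else character(0)
    perFamily[f] <- length(sel)
    selected <- c(selected, as.character(sel))
  }
  new("HybridSpec", selected = selected, families = famOrder,
      params = list(maxDominance = maxDominance, maxStale = as.integer(maxStale),
                    perFamilyBits = as.list(perFamily)))
}

#' Project a feature table through a hybrid specification
#'
#' @param X feature matrix containing at least the spec's columns.
#' @param spec a [HybridSpec-class].
#' @return `X` restricted to exactly the spec's columns, in spec order.
#' @export
projectHybrid <- function(X, spec) {
  stopifnot(is(spec, "HybridSpec"))
  missing <- setdiff(spec@selected, colnames(X))
  if (length(missing))
    stop("feature table lacks hybrid columns: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  X[, spec@selected, drop = FALSE]
}

#' Serialize / restore a hybrid specification as JSON
#'
#' @param spec a [HybridSpec-class].
#' @param path file path.
#' @export
writeHybridSpec <- function(spec, path) {
  jsonlite::write_json(
    list(selected = spec@selected, families = spec@families,
         params = spec@params),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeHybridSpec
#' @export
readHybridSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("HybridSpec", selected = as.character(x$selected),
      families = as.character(x$families), params = as.list(x$params))
}
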