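#' Binary molecular fingerprint families
#'
#' Fixed-length binary substructure fingerprints are the feature substrate of
#' every downstream stage (feature selection, random-forest training,
#' Tanimoto similarity). Five complementary families are registered, mapped
#' to the implementations available in the Open Babel / ChemmineR stack:
#'
#' * `fp2like` -- path-based fingerprint of linear fragments up to 7 atoms,
#'   hashed to 1024 bits (Open Babel FP2);
#' * `fp3like` -- small SMARTS-pattern key set, 64 bits (Open Babel FP3);
#' * `fp4like` -- substructure/functional-group keys, 512 bits (Open Babel FP4);
#' * `maccslike` -- MACCS key set in a 256-bit container, 166 meaningful keys
#'   (Open Babel MACCS);
#' * `aplike` -- topological atom-pair descriptors hashed to 1024 bits
#'   (ChemmineR atom pairs).
#'
#' Every provider is a pure function of the canonical structure: the same
#' molecule always yields the same bits. Columns are identified by the
#' stable scheme `"family:bitindex"` with 0-based bit indices; this is the
#' identifier space that [HybridSpec-class] records.
#'
#' @name fingerprints
NULL

.fpFamilies <- list(
  fp2like   = list(length = 1024L, backend = "ob", obname = "FP2",
                   description = "path-based linear fragments (<=7 atoms), hashed"),
  fp3like   = list(length = 64L,   backend = "ob", obname = "FP3",
                   description = "small SMARTS key set"),
  fp4like   = list(length = 512L,  backend = "ob", obname = "FP4",
                   description = "substructure / functional-group keys"),
  maccslike = list(length = 256L,  backend = "ob", obname = "MACCS",
                   description = "MACCS keys (166 keys in a 256-bit container)"),
  aplike    = list(length = 1024L, backend = "ap",
                   description = "topological atom pairs, hashed")
)

#' @describeIn fingerprints Registered families with declared bit lengths.
#' @export
fingerprintFamilies <- function() {
  data.frame(
    family = names(.fpFamilies),
    length = viapply(.fpFamilies, function(f) f$length),
    backend = vcapply(.fpFamilies, function(f) f$backend),
    description = vcapply(.fpFamilies, function(f) f$description),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# the most frequent atom-pair descriptors shipped with ChemmineR, used as
# the fixed bit dictionary of the hashed atom-pair family
.apCache <- new.env(parent = emptyenv())
.apDescriptors <- function(n) {
  if (is.null(.apCache$desc)) {
    e <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = e)
    .apCache$desc <- as.character(e$apfp$AP)
  }
  .apCache$desc[seq_len(n)]
}

# smiles -> SDFset, keeping alignment; returns list(sdf, ok)
.smilesToSDF <- function(smiles, ids) {
  smi <- stats::setNames(smiles, ids)
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi)),
                  error = function(e) NULL)
  if (!is.null(sdf) && length(sdf) == length(smiles))
    return(list(sdf = sdf, ok = rep(TRUE, length(smiles))))
  # fall back to per-molecule conversion so one bad record cannot shift rows
  ok <- rep(FALSE, length(smiles))
  pieces <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    s <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smi[i])),
                  error = function(e) NULL)
    if (!is.null(s) && length(s) == 1L) { pieces[[i]] <- s; ok[i] <- TRUE }
  }
  keep <- pieces[ok]
  sdf <- if (length(keep)) do.call(c, keep) else NULL
  list(sdf = sdf, ok = ok)
}

# one family for a pre-built SDFset; returns 0/1 integer matrix
.familyMatrix <- function(sdf, family) {
  fam <- .fpFamilies[[family]]
  if (fam$backend == "ob") {
    m <- as.matrix(ChemmineR::fingerprintOB(sdf, fam$obname))
  } else {
    ap <- ChemmineR::sdf2ap(sdf, uniquePairs = TRUE)
    m <- as.matrix(ChemmineR::desc2fp(ap, descnames = .apDescriptors(fam$length),
                                      type = "FPset"))
  }
  if (ncol(m) != fam$length)
    stop("family ", family, " returned ", ncol(m), " bits, expected ", fam$length)
  storage.mode(m) <- "integer"
  colnames(m) <- paste0(family, ":", seq_len(ncol(m)) - 1L)
  m
}

#' Compute fingerprints for a set of molecules
#'
#' `fingerprintMatrix()` computes one or more families for a vector of
#' molecules and returns the column-bound binary feature table: rows in
#' input order, columns grouped by family in registration order with bit
#' indices ascending. Molecules that a provider cannot perceive are
#' excluded from the table and reported in the `"failures"` attribute; the
#' run continues.
#'
#' `computeFingerprint()` is the single-molecule, single-family form.
#'
#' @param smiles character vector of (canonical) SMILES.
#' @param families character vector of registered family names.
#' @param ids optional row identifiers (default: names of `smiles` or
#'   `m1..mN`).
#' @return integer 0/1 matrix with rownames `ids` and colnames
#'   `"family:bit"`; attribute `"failures"` holds a data.frame (`id`,
#'   `reason`) of excluded molecules.
#' @export
fingerprintMatrix <- function(smiles, families = names(.fpFamilies), ids = NULL) {
  unknown <- setdiff(families, names(.fpFamilies))
  if (length(unknown))
    stop("unregistered fingerprint family: ", paste(unknown, collapse = ", "))
  families <- names(.fpFamilies)[names(.fpFamilies) %in% families]
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("m%d", seq_along(smiles))
  if (!length(smiles)) {
    out <- matrix(0L, 0L,
                  sum(viapply(.fpFamilies[families], function(f) f$length)))
    colnames(out) <- unlist(lapply(families, function(f)
      paste0(f, ":", seq_len(.fpFamilies[[f]]$length) - 1L)))
    attr(out, "failures") <- data.frame(id = character(), reason = character())
    return(out)
  }
  conv <- .smilesToSDF(smiles, ids)
  failures <- data.frame(id = ids[!conv$ok],
                         reason = rep("structure perception failed", sum(!conv$ok)),
                         stringsAsFactors = FALSE)
  mats <- lapply(families, function(f) .familyMatrix(conv$sdf, f))
  out <- do.call(cbind, mats)
  rownames(out) <- ids[conv$ok]
  attr(out, "failures") <- failures
  out
}

#' @describeIn fingerprintMatrix single molecule, single family; returns a
#'   named integer 0/1 vector of length equal to the family's declared size.
#' @param family a single registered family name.
#' @export
computeFingerprint <- function(smiles, family) {
  stopifnot(length(smiles) == 1L, length(family) == 1L)
  m <- fingerprintMatrix(smiles, families = family,
                         ids = names(smiles) %||% "query")
  if (nrow(m) != 1L)
    stop("fingerprint computation failed for molecule: ",
         names(smiles) %||% smiles)
  stats::setNames(as.integer(m[1L, ]), colnames(m))
}
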