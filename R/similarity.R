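#' Consensus Tanimoto similarity search
#'
#' Assigns a four-digit EC to a query molecule by structural similarity to
#' the substrates of the predicted EC subclass, on the premise of enzyme
#' promiscuity: an enzyme tends to act on molecules structurally similar to
#' its canonical substrates. Similarity is the Tanimoto coefficient
#' `TC = z / (x + y - z)` of binary fingerprints (x, y = bits set in each
#' molecule, z = bits set in both), computed under three families --
#' path-based (`fp2like`), substructure-key (`fp4like`) and MACCS-key
#' (`maccslike`) -- with a consensus rule: if at least two families agree on
#' the top-ranked substrate, that substrate wins; if all three disagree,
#' the substrate with the globally highest coefficient wins.
#'
#' @name similarity
NULL

#' Tanimoto coefficient of two binary fingerprints
#'
#' @param x,y binary 0/1 vectors of equal length; an error is raised when
#'   both are all-zero (the coefficient is undefined).
#' @return numeric in `[0, 1]`.
#' @export
tanimoto <- function(x, y) {
  stopifnot(length(x) == length(y))
  x <- as.logical(x); y <- as.logical(y)
  z <- sum(x & y)
  den <- sum(x) + sum(y) - z
  if (den == 0) stop("Tanimoto undefined: both fingerprints are all-zero")
  z / den
}

# per-family TC of one query against candidate rows; NA where undefined
.familyTc <- function(qfp, C) {
  z <- as.vector(C %*% qfp)
  den <- rowSums(C) + sum(qfp) - z
  ifelse(den == 0, NA_real_, z / den)
}

#' Consensus top hit across three fingerprint families
#'
#' Ranks candidates per family by Tanimoto coefficient (ties broken by
#' lexicographic candidate id), then applies the consensus rule described
#' in [similarity].
#'
#' @param querySmiles single (canonical) SMILES of the query.
#' @param candidates data.frame with columns `id` and `smiles`.
#' @param families the three families searched (default
#'   `c("fp2like", "fp4like", "maccslike")`).
#' @return list: `substrate_id`, `per_family_tc` (named: this candidate's
#'   coefficient under each family), `consensus_family_count`, `winning_tc`
#'   (the candidate's highest coefficient), `family_top` (named: each
#'   family's own top candidate).
#' @export
consensusTopHit <- function(querySmiles, candidates,
                            families = c("fp2like", "fp4like", "maccslike")) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L,
            all(c("id", "smiles") %in% names(candidates)))
  all <- c(stats::setNames(querySmiles, ".query"),
           stats::setNames(candidates$smiles, candidates$id))
  M <- fingerprintMatrix(all, families = families)
  if (!".query" %in% rownames(M)) stop("query fingerprint computation failed")
  fams <- sub(":.*$", "", colnames(M))
  ids <- candidates$id[candidates$id %in% rownames(M)]
  if (!length(ids)) stop("no candidate fingerprints computable")
  tcByFam <- sapply(families, function(f) {
    cols <- fams == f
    .familyTc(M[".query", cols], M[ids, cols, drop = FALSE])
  })
  tcByFam <- matrix(tcByFam, nrow = length(ids),
                    dimnames = list(ids, families))
  consensusRule(tcByFam)
}

#' The two-of-three consensus rule on a Tanimoto matrix
#'
#' Pure decision rule, separated from fingerprint computation: given each
#' candidate's Tanimoto coefficient under each family, every family ranks
#' its own top candidate (ties broken by lexicographic candidate id); if
#' two or more families agree on one candidate it wins -- even when a
#' dissenting family holds a higher coefficient -- otherwise the candidate
#' with the globally highest coefficient wins.
#'
#' @param tcByFam numeric matrix, rows = candidate ids (rownames), columns
#'   = families; `NA` marks an undefined coefficient.
#' @return list as documented in [consensusTopHit()].
#' @export
consensusRule <- function(tcByFam) {
  stopifnot(is.matrix(tcByFam), !is.null(rownames(tcByFam)))
  if (all(is.na(tcByFam))) stop("Tanimoto undefined for every candidate/family")
  ids <- rownames(tcByFam)
  topOf <- vcapply(colnames(tcByFam) %||% as.character(seq_len(ncol(tcByFam))),
                   function(f) {
    tc <- tcByFam[, f]
    if (all(is.na(tc))) return(NA_character_)
    best <- max(tc, na.rm = TRUE)
    sort(ids[!is.na(tc) & tc == best])[1L]   # ties -> lexicographic id
  })
  votes <- table(topOf[!is.na(topOf)])
  if (length(votes) && max(votes) >= 2L) {
    winner <- names(votes)[which.max(votes)]
    consensus <- as.integer(max(votes))
  } else {
    best <- which(tcByFam == max(tcByFam, na.rm = TRUE), arr.ind = TRUE)
    winner <- sort(ids[best[, "row"]])[1L]
    consensus <- 1L
  }
  perFam <- tcByFam[winner, ]
  list(substrate_id = winner,
       per_family_tc = perFam,
       consensus_family_count = consensus,
       winning_tc = max(perFam, na.rm = TRUE),
       family_top = topOf)
}

#' Assign EC numbers by subclass-restricted similarity search
#'
#' Searches only the substrates indexed under the predicted
#' (class, subclass) pair, applies the consensus rule, and, when the winning
#' coefficient clears `tcCutoff`, returns every EC tag of the winning
#' substrate that belongs to the predicted subclass (a substrate acted on by
#' several enzymes of the same subclass yields all of them). Below the
#' cutoff the outcome is `"no-confident-EC"`, with the best sub-threshold
#' hit retained for transparency.
#'
#' @param querySmiles single canonical SMILES.
#' @param db a [SubstrateDB-class].
#' @param classDigit,subclassDigit the predicted EC class and subclass.
#' @param tcCutoff minimum winning Tanimoto coefficient (default 0.5).
#' @param families passed to [consensusTopHit()].
#' @return list: `ecs` (character, possibly empty), `hit` (the consensus
#'   hit, or NULL), `outcome` (`"ok"`, `"no-confident-EC"` or
#'   `"empty-database"`).
#' @export
assignEC <- function(querySmiles, db, classDigit, subclassDigit,
                     tcCutoff = 0.5,
                     families = c("fp2like", "fp4like", "maccslike")) {
  stopifnot(is(db, "SubstrateDB"))
  cand <- subsetByEC(db, classDigit, subclassDigit)
  if (nrow(cand) == 0L)
    return(list(ecs = character(0), hit = NULL, outcome = "empty-database"))
  hit <- consensusTopHit(querySmiles, cand[, c("id", "smiles")], families)
  rec <- cand[cand$id == hit$substrate_id, , drop = FALSE]
  tags <- rec$ecTags[[1L]]
  m <- ecParse(tags)
  inSub <- m[, 1L] == classDigit & m[, 2L] == subclassDigit
  if (hit$winning_tc < tcCutoff)
    return(list(ecs = character(0), hit = hit, outcome = "no-confident-EC"))
  list(ecs = tags[inSub], hit = hit, outcome = "ok")
}
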