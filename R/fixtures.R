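#' Deterministic synthetic fixtures with known ground truth
#'
#' Generates substrate tables, enzyme/genome tables and alignment-hit files
#' that emulate the statistical structure the method assumes -- EC
#' class-separable substructure patterns, imbalanced class sizes, planted
#' near-duplicates, multi-class substrates and cofactor entries -- with a
#' ground-truth record for every planted feature, so each pipeline stage is
#' testable without downloads.
#'
#' Molecules are composed from a curated scaffold library: each EC class is
#' anchored by a distinct ring system (benzene, pyridine, furan, thiophene,
#' N-methylpyrrole, cyclohexane), each subclass by a distinct marker group
#' (carboxylic acid, sulfonamide, nitrile), and individual molecules by a
#' tail drawn without replacement from a library of 24 substituents chosen
#' so that any two distinct molecules stay at or below Tanimoto 0.92 under
#' the path-based family -- safely under the 0.95 redundancy threshold --
#' while molecules of one class share enough substructure to be separable.
#' Planted duplicates re-emit an existing structure with a different record
#' id and permuted atom ordering (Tanimoto exactly 1 to their parent).
#'
#' @name fixtures
NULL

.fxRings <- c("c1ccc(cc1)", "c1ncc(cc1)", "c1occ(c1)",
              "c1scc(c1)", "c1n(C)cc(c1)", "C1CCC(CC1)")
.fxMarkers <- c("OC(=O)", "NS(=O)(=O)", "N#C")
.fxTails <- c("C", "CN", "CF", "CCl", "CBr", "CI", "CCOC", "CCNC", "CON",
              "CSC", "C2CCOC2", "C2CCNC2", "C2CCSC2", "C=C", "C=CC", "C#C",
              "COC(=O)C", "CNC(=O)C", "COCO", "CNCN", "COC2CC2", "CP",
              "C[Si](C)C", "CN=C")

#' Fixture specification
#'
#' @param nClasses number of EC classes (<= 6).
#' @param subclassesPerClass subclasses per class (<= 3).
#' @param moleculesPerSubclass base molecules per subclass; together with
#'   planted extras this must not exceed the 24-tail library.
#' @param imbalanceProfile optional numeric vector of per-class relative
#'   sizes (scaled so the largest class keeps `moleculesPerSubclass`);
#'   `"gut_db_skew"` selects a preset mirroring a strongly imbalanced
#'   database (two dominant classes holding about two thirds of the
#'   records, two rare classes about 7 %).
#' @param duplicateRate,multiclassRate fractions of the base set planted as
#'   near-duplicate and multi-class rows.
#' @param cofactorCount cofactor rows drawn from the packaged list.
#' @param seed integer; fixes every random choice.
#' @return a `FixtureSpec` list.
#' @export
fixtureSpec <- function(nClasses = 6L, subclassesPerClass = 3L,
                        moleculesPerSubclass = 20L, imbalanceProfile = NULL,
                        duplicateRate = 0.05, multiclassRate = 0.03,
                        cofactorCount = 5L, seed = 1L) {
  stopifnot(nClasses >= 1L, nClasses <= 6L,
            subclassesPerClass >= 1L, subclassesPerClass <= 3L,
            moleculesPerSubclass >= 1L,
            duplicateRate >= 0, multiclassRate >= 0, cofactorCount >= 0L)
  if (identical(imbalanceProfile, "gut_db_skew"))
    imbalanceProfile <- c(1, 0.97, 0.45, 0.37, 0.11, 0.10)[seq_len(nClasses)]
  spec <- list(nClasses = as.integer(nClasses),
               subclassesPerClass = as.integer(subclassesPerClass),
               moleculesPerSubclass = as.integer(moleculesPerSubclass),
               imbalanceProfile = imbalanceProfile,
               duplicateRate = duplicateRate,
               multiclassRate = multiclassRate,
               cofactorCount = as.integer(cofactorCount),
               seed = as.integer(seed))
  class(spec) <- "FixtureSpec"
  spec
}

#' Named fixture presets
#'
#' `"separable6"`: 6 classes x 3 subclasses x 20 molecules (360 base
#' records) plus planted duplicates, multi-class rows and cofactors.
#' `"skewed6"`: same scaffolds under the strongly imbalanced class profile.
#' `"tiny"`: 3 classes x 2 subclasses x 6 molecules, for fast unit tests.
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return a `FixtureSpec`.
#' @export
fixturePreset <- function(preset = c("separable6", "skewed6", "tiny"),
                          seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    separable6 = fixtureSpec(6L, 3L, 20L, NULL, 0.05, 0.03, 5L, seed),
    skewed6 = fixtureSpec(6L, 3L, 20L, "gut_db_skew", 0.05, 0.03, 5L, seed),
    tiny = fixtureSpec(3L, 2L, 6L, NULL, 0.1, 0.05, 2L, seed))
}

# per-(class, subclass) base molecule counts under the imbalance profile
.cellCounts <- function(spec) {
  prof <- spec$imbalanceProfile %||% rep(1, spec$nClasses)
  stopifnot(length(prof) == spec$nClasses)
  counts <- matrix(0L, spec$nClasses, spec$subclassesPerClass)
  for (ci in seq_len(spec$nClasses)) {
    n <- max(2L, as.integer(roundHalfUp(spec$moleculesPerSubclass *
                                          prof[ci] / max(prof))))
    counts[ci, ] <- n
  }
  counts
}

#' Generate a raw substrate table with planted curation cases
#'
#' @param spec a `FixtureSpec`.
#' @return list: `raw` (data.frame `smiles`, `id`, `ec`, `name`) and
#'   `truth` (list: `survivorIds`, `duplicateMap`, `multiclassIds`,
#'   `cofactorIds`, `classOf`, `subclassOf`, `ecOf` keyed by id).
#' @export
generateSubstrates <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  counts <- .cellCounts(spec)
  nTails <- length(.fxTails)
  if (max(counts) > nTails)
    stop("infeasible spec: ", max(counts), " molecules per subclass exceeds ",
         nTails, " available tails")
  withSeed(spec$seed, {
    rows <- list(); truthClass <- c(); truthSub <- c(); ecOf <- list()
    usedTails <- list()
    serial <- 0L
    for (ci in seq_len(spec$nClasses)) for (si in seq_len(spec$subclassesPerClass)) {
      n <- counts[ci, si]
      tails <- sample(.fxTails, n)   # without replacement
      usedTails[[paste(ci, si)]] <- tails
      for (t in tails) {
        serial <- serial + 1L
        id <- sprintf("S%04d", serial)
        smi <- paste0(.fxMarkers[si], .fxRings[ci], t)
        # one or two four-digit ECs, same class+subclass
        nEC <- 1L + (stats::runif(1) < 0.25)
        ecs <- unique(sprintf("%d.%d.%d.%d", ci, si, sample(1:3, nEC, TRUE),
                              sample(1:40, nEC)))
        rows[[id]] <- data.frame(smiles = smi, id = id,
                                 ec = paste(ecs, collapse = ";"),
                                 name = sprintf("cmpd_%d_%d_%s", ci, si, t),
                                 stringsAsFactors = FALSE)
        truthClass[id] <- ci; truthSub[id] <- si; ecOf[[id]] <- ecs
      }
    }
    base <- do.call(rbind, rows)
    nBase <- nrow(base)
    survivorIds <- base$id

    # planted duplicates: same structure, new id, permuted atom order
    nDup <- as.integer(roundHalfUp(spec$duplicateRate * nBase))
    dupRows <- NULL; duplicateMap <- data.frame(id = character(),
                                                parent = character())
    if (nDup > 0L) {
      parents <- sample(base$id, nDup)
      can <- canonicalSmiles(base$smiles[match(parents, base$id)])
      dupRows <- data.frame(
        smiles = unname(can),
        id = sprintf("D%04d", seq_len(nDup)),
        ec = base$ec[match(parents, base$id)],
        name = paste0("dup_of_", parents), stringsAsFactors = FALSE)
      duplicateMap <- data.frame(id = dupRows$id, parent = parents,
                                 stringsAsFactors = FALSE)
    }

    # planted multi-class rows: fresh structures on unused tails, tagged
    # with ECs from two different classes
    nMc <- as.integer(roundHalfUp(spec$multiclassRate * nBase))
    mcRows <- NULL; multiclassIds <- character(0)
    if (nMc > 0L) {
      if (spec$nClasses < 2L) stop("infeasible spec: multi-class rows need >= 2 classes")
      mc <- list()
      for (i in seq_len(nMc)) {
        ci <- sample(seq_len(spec$nClasses), 1L)
        si <- sample(seq_len(spec$subclassesPerClass), 1L)
        free <- setdiff(.fxTails, usedTails[[paste(ci, si)]])
        if (!length(free))
          stop("infeasible spec: no free tails for multi-class rows")
        tail <- sample(free, 1L)
        usedTails[[paste(ci, si)]] <- c(usedTails[[paste(ci, si)]], tail)
        cj <- sample(setdiff(seq_len(spec$nClasses), ci), 1L)
        id <- sprintf("M%04d", i)
        mc[[i]] <- data.frame(
          smiles = paste0(.fxMarkers[si], .fxRings[ci], tail),
          id = id,
          ec = paste(sprintf("%d.%d.%d.%d", c(ci, cj),
                             sample(seq_len(spec$subclassesPerClass), 2L, TRUE),
                             sample(1:3, 2L, TRUE), sample(1:40, 2L)),
                     collapse = ";"),
          name = "planted_multiclass", stringsAsFactors = FALSE)
        multiclassIds <- c(multiclassIds, id)
      }
      mcRows <- do.call(rbind, mc)
    }

    # cofactor rows, tagged with an arbitrary same-class EC
    cofRows <- NULL; cofactorIds <- character(0)
    if (spec$cofactorCount > 0L) {
      cof <- defaultCofactors()
      pick <- cof[sample(nrow(cof), min(spec$cofactorCount, nrow(cof))), ]
      cofRows <- data.frame(
        smiles = pick$smiles,
        id = sprintf("C%04d", seq_len(nrow(pick))),
        ec = sprintf("%d.1.1.%d", sample(seq_len(spec$nClasses),
                                         nrow(pick), TRUE),
                     sample(50:60, nrow(pick))),
        name = pick$name, stringsAsFactors = FALSE)
      cofactorIds <- cofRows$id
    }

    planted <- rbind(dupRows, mcRows, cofRows)
    if (!is.null(planted) && nrow(planted))
      planted <- planted[sample(nrow(planted)), , drop = FALSE]
    raw <- rbind(base, planted)
    rownames(raw) <- NULL
    list(raw = raw,
         truth = list(survivorIds = survivorIds,
                      duplicateMap = duplicateMap,
                      multiclassIds = multiclassIds,
                      cofactorIds = cofactorIds,
                      classOf = truthClass, subclassOf = truthSub,
                      ecOf = ecOf))
  })
}

#' Generate a toy enzyme world consistent with a substrate fixture
#'
#' Builds toy genomes with taxonomy, proteins carrying the fixture's planted
#' ECs, and an alignment-hit table containing, per annotated protein, one
#' designated best hit, an inferior eligible hit, a sub-threshold hit, and
#' -- for a few boundary queries -- hits at exactly identity 40, coverage 80
#' or E-value 1e-15 (excluded by the strict inequalities).
#'
#' @param substrates output of [generateSubstrates()].
#' @param nGenomes number of toy genomes (default 8).
#' @param seed integer seed (default: the substrate fixture is already
#'   seeded; pass the same seed for a fully pinned world).
#' @return list: `hits`, `protein2genome`, `taxonomy` (data.frames) and
#'   `truth` (list: `expectedBest` keyed by query, `ec2genomes`,
#'   `boundaryQueries`).
#' @export
generateEnzymeWorld <- function(substrates, nGenomes = 8L, seed = 1L) {
  ecs <- sort(unique(unlist(substrates$truth$ecOf)))
  genera <- c("Bacteroides", "Prevotella", "Faecalibacterium", "Roseburia",
              "Escherichia", "Lactobacillus", "Bifidobacterium",
              "Akkermansia", "Clostridium", "Enterococcus", "Ruminococcus",
              "Eubacterium")
  phyla <- c("Bacteroidota", "Bacteroidota", "Bacillota", "Bacillota",
             "Pseudomonadota", "Bacillota", "Actinomycetota",
             "Verrucomicrobiota", "Bacillota", "Bacillota", "Bacillota",
             "Bacillota")
  withSeed(seed, {
    gidx <- seq_len(nGenomes)
    taxonomy <- data.frame(
      genome_id = sprintf("G%02d", gidx),
      lineage = sprintf("Bacteria; %s; %s; %s sp%02d",
                        phyla[((gidx - 1L) %% 12L) + 1L],
                        genera[((gidx - 1L) %% 12L) + 1L],
                        genera[((gidx - 1L) %% 12L) + 1L], gidx),
      stringsAsFactors = FALSE)
    hits <- list(); p2g <- list(); expectedBest <- list()
    ec2genomes <- stats::setNames(vector("list", length(ecs)), ecs)
    boundaryQueries <- character(0)
    serial <- 0L
    for (e in ecs) {
      nProt <- sample(1:3, 1L)
      homes <- sample(taxonomy$genome_id, nProt)
      for (g in homes) {
        serial <- serial + 1L
        q <- sprintf("P%05d", serial)
        p2g[[q]] <- data.frame(protein_id = q, genome_id = g,
                               stringsAsFactors = FALSE)
        bestSubj <- paste0("ref_", e, "_a")
        bs <- round(stats::runif(1, 200, 400), 1)
        mk <- function(subj, pid, qc, ev, score)
          data.frame(qseqid = q, sseqid = subj, pident = pid, length = 300L,
                     mismatch = 10L, gapopen = 1L, qstart = 1L, qend = 300L,
                     sstart = 1L, send = 300L, evalue = ev, bitscore = score,
                     sec = e, qcovs = qc, stringsAsFactors = FALSE)
        hits[[length(hits) + 1L]] <-
          mk(bestSubj, round(stats::runif(1, 55, 95), 1),
             round(stats::runif(1, 85, 100), 1),
             10^(-stats::runif(1, 30, 60)), bs)
        hits[[length(hits) + 1L]] <-                      # inferior eligible
          mk(paste0("ref_", e, "_b"), round(stats::runif(1, 45, 60), 1),
             round(stats::runif(1, 82, 95), 1),
             10^(-stats::runif(1, 20, 28)), bs - 50)
        hits[[length(hits) + 1L]] <-                      # clearly failing
          mk(paste0("ref_", e, "_c"), round(stats::runif(1, 10, 35), 1),
             round(stats::runif(1, 30, 70), 1),
             10^(-stats::runif(1, 2, 10)), bs - 150)
        expectedBest[[q]] <- bestSubj
        ec2genomes[[e]] <- sort(unique(c(ec2genomes[[e]], g)))
      }
    }
    # boundary queries: a single hit sitting exactly on each threshold
    bnd <- list(c(40, 95, 1e-30), c(70, 80, 1e-30), c(70, 95, 1e-15))
    for (b in bnd) {
      serial <- serial + 1L
      q <- sprintf("P%05d", serial)
      g <- sample(taxonomy$genome_id, 1L)
      p2g[[q]] <- data.frame(protein_id = q, genome_id = g,
                             stringsAsFactors = FALSE)
      hits[[length(hits) + 1L]] <-
        data.frame(qseqid = q, sseqid = "ref_boundary", pident = b[1],
                   length = 300L, mismatch = 10L, gapopen = 1L, qstart = 1L,
                   qend = 300L, sstart = 1L, send = 300L, evalue = b[3],
                   bitscore = 250, sec = ecs[1L], qcovs = b[2],
                   stringsAsFactors = FALSE)
      boundaryQueries <- c(boundaryQueries, q)
    }
    hits <- do.call(rbind, hits)
    hits <- hits[sample(nrow(hits)), , drop = FALSE]
    rownames(hits) <- NULL
    hits$query_coverage <- hits$qcovs
    list(hits = hits, protein2genome = do.call(rbind, p2g),
         taxonomy = taxonomy,
         truth = list(expectedBest = expectedBest, ec2genomes = ec2genomes,
                      boundaryQueries = boundaryQueries))
  })
}
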