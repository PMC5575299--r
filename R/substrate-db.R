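#' Substrate database construction and curation
#'
#' Builds the EC-tagged substrate database that trains the random-forest
#' cascade and backs the similarity search. Raw substrate tables (one row
#' per molecule with one or more EC numbers) pass through three curation
#' filters, in this fixed order:
#'
#' 1. *Cofactor removal* -- cofactors and supporting molecules of enzyme
#'    function (water, metal ions, ATP, NAD(P)(H), ...) are removed by
#'    canonical-key match against a packaged, editable exclusion list;
#' 2. *Multi-class exclusion* -- substrates metabolizable by enzymes of more
#'    than one EC class are removed (their class label would be ambiguous);
#' 3. *Redundancy removal* -- near-duplicate structures (pairwise Tanimoto
#'    coefficient strictly greater than the threshold, default 0.95) are
#'    collapsed to one representative by greedy leader clustering in stable
#'    input order.
#'
#' The first two filters are per-record predicates and commute; redundancy
#' removal must run last because the representative choice depends on the
#' surviving set. The curated records are indexed by EC class and by
#' (class, subclass) pairs.
#'
#' @name substrate-db
NULL

#' Packaged cofactor exclusion list
#'
#' @param path optional path to an alternative `name<TAB>smiles` list.
#' @return data.frame with columns `name`, `smiles` (as listed) and
#'   `canonical_key`.
#' @export
defaultCofactors <- function(path = system.file("extdata", "cofactors.tsv",
                                                package = "xenozyme")) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(name = vcapply(parts, `[`, 1L),
                   smiles = vcapply(parts, `[`, 2L),
                   stringsAsFactors = FALSE)
  key <- canonicalSmiles(df$smiles)
  bad <- is.na(key)
  if (any(bad))
    warning("cofactor entries failed canonicalization: ",
            paste(df$name[bad], collapse = ", "))
  df$canonical_key <- unname(key)
  df[!bad, , drop = FALSE]
}

# raw table (smiles, id, ec[, name]) -> curation-ready records
normalizeSubstrateTable <- function(raw) {
  stopifnot(is.data.frame(raw), all(c("smiles", "id", "ec") %in% names(raw)))
  key <- canonicalSmiles(raw$smiles)
  reduced <- attr(key, "fragmentReduced")
  failures <- data.frame(id = raw$id[is.na(key)],
                         reason = rep("canonicalization failed", sum(is.na(key))),
                         stringsAsFactors = FALSE)
  keep <- !is.na(key)
  ecTags <- lapply(strsplit(raw$ec[keep], ";", fixed = TRUE), trimws)
  badEC <- vlapply(ecTags, function(t) length(t) == 0L || !all(ecIsValid(t)))
  if (any(badEC)) {
    failures <- rbind(failures,
                      data.frame(id = raw$id[keep][badEC],
                                 reason = "invalid EC tag"))
  }
  rec <- data.frame(
    id = raw$id[keep][!badEC],
    smiles = unname(key[keep][!badEC]),
    name = if ("name" %in% names(raw)) raw$name[keep][!badEC] else NA_character_,
    provenance = ifelse(reduced[keep][!badEC],
                        "kept largest covalent fragment", "parsed"),
    stringsAsFactors = FALSE
  )
  rec$ecTags <- ecTags[!badEC]
  list(records = rec, failures = failures)
}

#' Cofactor filter
#'
#' Removes records whose canonical key appears in the cofactor list.
#'
#' @param records curation-ready records (see [buildSubstrateDB()]).
#' @param cofactorKeys character vector of canonical keys (empty = no-op).
#' @return list with `kept` and `removed` record data.frames.
#' @export
filterCofactors <- function(records, cofactorKeys = defaultCofactors()$canonical_key) {
  hit <- records$smiles %in% cofactorKeys
  if (all(hit) && nrow(records) > 0L)
    warning("all records are cofactors; curated set is empty")
  list(kept = records[!hit, , drop = FALSE],
       removed = records[hit, , drop = FALSE])
}

#' Multi-class filter
#'
#' Removes records whose EC tags span more than one EC class; a retained
#' record's tags all share a single class digit.
#'
#' @param records curation-ready records.
#' @return list with `kept`, `removed`, and `conflicts` (named list:
#'   removed id -> its conflicting class digits).
#' @export
filterMulticlass <- function(records) {
  classes <- lapply(records$ecTags, function(t) sort(unique(ecClass(t))))
  multi <- lengths(classes) > 1L
  list(kept = records[!multi, , drop = FALSE],
       removed = records[multi, , drop = FALSE],
       conflicts = stats::setNames(classes[multi], records$id[multi]))
}

#' Tanimoto redundancy removal (greedy leader clustering)
#'
#' Scans records in stable input order; a record joins the first existing
#' cluster whose leader it exceeds the Tanimoto threshold against,
#' otherwise it founds a new cluster. Cluster leaders are the
#' representatives. Strictly-greater-than semantics: a pair at exactly the
#' threshold is kept separate. Records with an all-zero fingerprint
#' (Tanimoto undefined) are excluded with a warning.
#'
#' @param records curation-ready records.
#' @param tcThreshold merge threshold (default 0.95).
#' @param fpFamily fingerprint family used for the all-against-all search
#'   (default the path-based 1024-bit family).
#' @return list: `representatives` (record data.frame), `clusterMap`
#'   (data.frame `id`, `representative`, `tc`), `excluded` (ids with
#'   all-zero fingerprints).
#' @export
removeRedundancy <- function(records, tcThreshold = 0.95, fpFamily = "fp2like") {
  stopifnot(tcThreshold > 0, tcThreshold <= 1)
  if (nrow(records) == 0L)
    return(list(representatives = records,
                clusterMap = data.frame(id = character(),
                                        representative = character(),
                                        tc = numeric()),
                excluded = character()))
  M <- fingerprintMatrix(stats::setNames(records$smiles, records$id),
                         families = fpFamily)
  lost <- setdiff(records$id, rownames(M))
  zero <- rownames(M)[rowSums(M) == 0L]
  if (length(zero) || length(lost))
    warning("excluded from redundancy clustering (all-zero or failed fingerprint): ",
            paste(c(zero, lost), collapse = ", "))
  usable <- setdiff(records$id, c(zero, lost))
  M <- M[usable, , drop = FALSE]
  ord <- records$id[records$id %in% usable]
  leaders <- character(0)
  map <- data.frame(id = character(), representative = character(),
                    tc = numeric(), stringsAsFactors = FALSE)
  for (id in ord) {
    placed <- FALSE
    if (length(leaders)) {
      x <- M[id, ]
      L <- M[leaders, , drop = FALSE]
      z <- as.vector(L %*% x)
      tc <- z / (rowSums(L) + sum(x) - z)
      hit <- which(tc > tcThreshold)
      if (length(hit)) {
        lead <- leaders[hit[1L]]
        map <- rbind(map, data.frame(id = id, representative = lead,
                                     tc = tc[hit[1L]]))
        placed <- TRUE
      }
    }
    if (!placed) {
      leaders <- c(leaders, id)
      map <- rbind(map, data.frame(id = id, representative = id, tc = 1))
    }
  }
  list(representatives = records[records$id %in% leaders, , drop = FALSE],
       clusterMap = map, excluded = c(zero, lost))
}

#' Build the curated, indexed substrate database
#'
#' Runs the full curation pipeline (cofactor filter, multi-class filter,
#' redundancy removal) on a raw substrate table and constructs the EC class
#' and (class, subclass) indexes. Counts at every stage are recorded in the
#' curation log.
#'
#' @param raw data.frame with columns `smiles`, `id`, `ec`
#'   (semicolon-separated EC labels) and optionally `name`.
#' @param cofactorKeys canonical keys to exclude (default: packaged list).
#' @param tcThreshold,fpFamily passed to [removeRedundancy()].
#' @return a [SubstrateDB-class].
#' @export
buildSubstrateDB <- function(raw, cofactorKeys = defaultCofactors()$canonical_key,
                             tcThreshold = 0.95, fpFamily = "fp2like") {
  norm <- normalizeSubstrateTable(raw)
  log <- sprintf("input: %d rows; parsed: %d; parse failures: %d",
                 nrow(raw), nrow(norm$records), nrow(norm$failures))
  cof <- filterCofactors(norm$records, cofactorKeys)
  log <- c(log, sprintf("cofactor filter: removed %d, kept %d",
                        nrow(cof$removed), nrow(cof$kept)))
  mc <- filterMulticlass(cof$kept)
  log <- c(log, sprintf("multi-class filter: removed %d, kept %d",
                        nrow(mc$removed), nrow(mc$kept)))
  red <- removeRedundancy(mc$kept, tcThreshold, fpFamily)
  log <- c(log, sprintf("redundancy removal (TC > %g, %s): %d representatives of %d",
                        tcThreshold, fpFamily,
                        nrow(red$representatives), nrow(mc$kept)))
  rec <- red$representatives
  if (nrow(rec) == 0L)
    stop("curation removed every record; stage counts:\n",
         paste(log, collapse = "\n"))
  classes <- viapply(rec$ecTags, function(t) unique(ecClass(t))[1L])
  classIndex <- split(rec$id, as.character(classes))
  pairs <- lapply(seq_len(nrow(rec)), function(i) {
    m <- ecParse(rec$ecTags[[i]])
    unique(paste0(m[, 1L], ".", m[, 2L]))
  })
  subKeys <- sort(unique(unlist(pairs)))
  subclassIndex <- lapply(subKeys, function(k)
    rec$id[vlapply(pairs, function(p) k %in% p)])
  names(subclassIndex) <- subKeys
  new("SubstrateDB", records = rec,
      classIndex = classIndex[order(as.integer(names(classIndex)))],
      subclassIndex = subclassIndex, log = log)
}

#' Training labels of a curated substrate database
#'
#' One row per record: the EC class digit, the (primary tag's) subclass
#' digit, and the combined `"class.subclass"` group label. The group label
#' is the recommended discrimination target for hybrid-bit selection, since
#' one hybrid fingerprint serves both levels of the cascade.
#'
#' @param db a [SubstrateDB-class].
#' @return data.frame with columns `id`, `class` (factor 1..6), `subclass`
#'   (integer) and `group` (factor `"class.subclass"`).
#' @export
substrateLabels <- function(db) {
  stopifnot(is(db, "SubstrateDB"))
  rec <- db@records
  m <- lapply(rec$ecTags, ecParse)
  cls <- viapply(m, function(x) x[1L, 1L])
  sub <- viapply(m, function(x) x[1L, 2L])
  data.frame(id = rec$id,
             class = factor(cls, levels = sort(unique(cls))),
             subclass = sub,
             group = factor(paste0(cls, ".", sub)),
             stringsAsFactors = FALSE)
}

#' Substrate records of one EC class or subclass
#'
#' @param db a [SubstrateDB-class].
#' @param classDigit EC class digit.
#' @param subclassDigit optional subclass digit; when given, records indexed
#'   under `class.subclass` are returned.
#' @return the matching subset of `substrateRecords(db)`.
#' @export
subsetByEC <- function(db, classDigit, subclassDigit = NULL) {
  stopifnot(is(db, "SubstrateDB"))
  ids <- if (is.null(subclassDigit)) {
    db@classIndex[[as.character(classDigit)]]
  } else {
    db@subclassIndex[[paste0(classDigit, ".", subclassDigit)]]
  }
  db@records[db@records$id %in% (ids %||% character(0)), , drop = FALSE]
}

#' Serialize / restore a substrate database as a plain-text directory
#'
#' Writes `molecules.smi` (SMILES table), `records.tsv` (id, ec_tags,
#' provenance) and `indexes.json`.
#'
#' @param db a [SubstrateDB-class].
#' @param dir directory path (created if needed).
#' @export
writeSubstrateDB <- function(db, dir) {
  stopifnot(is(db, "SubstrateDB"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMolecules(db@records, file.path(dir, "molecules.smi"), "smiles")
  rec <- db@records
  utils::write.table(
    data.frame(id = rec$id,
               ec_tags = vcapply(rec$ecTags, paste, collapse = ";"),
               name = rec$name, provenance = rec$provenance),
    file.path(dir, "records.tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(classIndex = db@classIndex,
                            subclassIndex = db@subclassIndex,
                            log = db@log),
                       file.path(dir, "indexes.json"))
  invisible(dir)
}

#' @rdname writeSubstrateDB
#' @export
readSubstrateDB <- function(dir) {
  mols <- readMolecules(file.path(dir, "molecules.smi"), "smiles")$molecules
  rec <- utils::read.delim(file.path(dir, "records.tsv"),
                           colClasses = "character")
  stopifnot(identical(mols$id, rec$id))
  records <- data.frame(id = rec$id, smiles = mols$smiles, name = rec$name,
                        provenance = rec$provenance, stringsAsFactors = FALSE)
  records$ecTags <- strsplit(rec$ec_tags, ";", fixed = TRUE)
  idx <- jsonlite::read_json(file.path(dir, "indexes.json"),
                             simplifyVector = TRUE)
  new("SubstrateDB", records = records,
      classIndex = lapply(idx$classIndex, as.character),
      subclassIndex = lapply(idx$subclassIndex, as.character),
      log = as.character(idx$log))
}
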