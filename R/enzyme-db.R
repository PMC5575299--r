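#' Gut bacterial enzyme database construction
#'
#' Annotates bacterial proteins with four-digit EC numbers by best-hit
#' filtering of a standard tabular protein-alignment file (the aligner
#' itself is external and pluggable), then joins proteins to genomes and
#' taxonomic lineages and indexes EC -> proteins -> genomes.
#'
#' A hit is eligible when identity > 40 %, query coverage > 80 % and
#' E-value < 1e-15 (all strict inequalities); among a query's eligible hits
#' the best one is taken by highest bitscore, ties broken by lowest E-value,
#' then lexicographic subject id.
#'
#' @name enzyme-db
NULL

#' Read a tabular alignment-hit file
#'
#' Expects the standard 12-column tabular alignment format (`qseqid sseqid
#' pident length mismatch gapopen qstart qend sstart send evalue bitscore`)
#' extended with a 13th column `sec` carrying the subject's EC label, and
#' optionally a 14th column `qcovs` with precomputed query coverage. When
#' `qcovs` is absent a `qlen` column is required so coverage can be derived
#' as `100 * (qend - qstart + 1) / qlen`.
#'
#' @param path path to the tab-separated hit file (a `#` header line is
#'   allowed).
#' @return data.frame of hits with a `query_coverage` column populated.
#' @export
readAlignmentHits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore", "sec")
  first <- readLines(path, n = 1L, warn = FALSE)
  hasHeader <- grepl("^#?\\s*qseqid", first)
  df <- utils::read.delim(path, header = hasHeader, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!hasHeader) {
    extra <- ncol(df) - length(cols)
    names(df) <- c(cols, if (extra > 0) c("qcovs", "qlen")[seq_len(extra)])
  }
  names(df) <- sub("^X\\.?", "", names(df))
  if (!"qcovs" %in% names(df)) {
    if (!"qlen" %in% names(df))
      stop("hit file has neither 'qcovs' nor 'qlen'; query coverage undefined")
    df$qcovs <- 100 * (df$qend - df$qstart + 1) / df$qlen
  }
  df$query_coverage <- df$qcovs
  df
}

#' Best-hit filtering of alignment hits
#'
#' @param hits data.frame with at least `qseqid`, `sseqid`, `pident`,
#'   `query_coverage` (or `qcovs`), `evalue`, `bitscore`, `sec`.
#' @param idMin,qcovMin,evalueMax eligibility thresholds; a hit must satisfy
#'   `pident > idMin`, `query_coverage > qcovMin` and `evalue < evalueMax`
#'   (strict inequalities, so boundary hits at exactly 40/80/1e-15 are
#'   rejected).
#' @return data.frame with one row per query that has at least one eligible
#'   hit: its single best hit. Queries with no eligible hit are absent.
#' @export
filterBestHits <- function(hits, idMin = 40, qcovMin = 80, evalueMax = 1e-15) {
  if (!"query_coverage" %in% names(hits)) hits$query_coverage <- hits$qcovs
  elig <- hits[hits$pident > idMin &
               hits$query_coverage > qcovMin &
               hits$evalue < evalueMax, , drop = FALSE]
  if (nrow(elig) == 0L) return(elig)
  # best per query: max bitscore, then min evalue, then lexicographic sseqid
  ord <- order(elig$qseqid, -elig$bitscore, elig$evalue, elig$sseqid)
  elig <- elig[ord, , drop = FALSE]
  best <- elig[!duplicated(elig$qseqid), , drop = FALSE]
  rownames(best) <- NULL
  best
}

#' Build the EC-indexed enzyme database
#'
#' Joins best hits to their genomes and taxonomy. Proteins without a genome
#' mapping are skipped and collected in the `"errors"` attribute; a genome
#' without taxonomy is an error.
#'
#' @param bestHits output of [filterBestHits()].
#' @param protein2genome data.frame with columns `protein_id`, `genome_id`.
#' @param taxonomy data.frame with columns `genome_id`, `lineage`
#'   (`"; "`-separated lineage string).
#' @return an [EnzymeDB-class]; attribute `"errors"` lists skipped proteins.
#' @export
buildEnzymeDB <- function(bestHits, protein2genome, taxonomy) {
  stopifnot(all(c("protein_id", "genome_id") %in% names(protein2genome)),
            all(c("genome_id", "lineage") %in% names(taxonomy)))
  gid <- protein2genome$genome_id[match(bestHits$qseqid, protein2genome$protein_id)]
  skipped <- bestHits$qseqid[is.na(gid)]
  keep <- !is.na(gid)
  records <- data.frame(
    protein_id = bestHits$qseqid[keep],
    genome_id = gid[keep],
    ec = bestHits$sec[keep],
    subject_id = bestHits$sseqid[keep],
    identity = bestHits$pident[keep],
    query_coverage = bestHits$query_coverage[keep],
    evalue = bestHits$evalue[keep],
    bitscore = bestHits$bitscore[keep],
    stringsAsFactors = FALSE
  )
  missingTax <- setdiff(records$genome_id, taxonomy$genome_id)
  if (length(missingTax))
    stop("genomes without taxonomy: ", paste(missingTax, collapse = ", "))
  ecIndex <- split(seq_len(nrow(records)), records$ec)
  db <- new("EnzymeDB", records = records, ecIndex = ecIndex,
            genomeIndex = taxonomy[, c("genome_id", "lineage"), drop = FALSE])
  attr(db, "errors") <- skipped
  db
}

#' Look up enzymes by (possibly partial) EC number
#'
#' With `allowPartial = TRUE` the query may contain wildcard levels
#' (`1.14.-.-`) and matches every record agreeing on all non-wildcard
#' digits; otherwise only exact labels match.
#'
#' @param db an [EnzymeDB-class].
#' @param ec a single EC label.
#' @param allowPartial hierarchical prefix matching (default FALSE).
#' @return data.frame of matching enzyme records with a `lineage` column
#'   appended (zero rows when nothing matches; never an error).
#' @export
lookupEC <- function(db, ec, allowPartial = FALSE) {
  stopifnot(is(db, "EnzymeDB"))
  ecParse(ec)   # validity check
  keys <- names(db@ecIndex)
  hit <- if (allowPartial) keys[ecMatches(ec, keys)] else intersect(ec, keys)
  rows <- sort(unlist(db@ecIndex[hit], use.names = FALSE))
  out <- db@records[rows, , drop = FALSE]
  out$lineage <- db@genomeIndex$lineage[match(out$genome_id,
                                              db@genomeIndex$genome_id)]
  rownames(out) <- NULL
  out
}

#' Serialize / restore an enzyme database
#'
#' Writes `enzymes.tsv`, `taxonomy.tsv` and `ec_index.json` into `dir`.
#'
#' @param db an [EnzymeDB-class].
#' @param dir directory path.
#' @export
writeEnzymeDB <- function(db, dir) {
  stopifnot(is(db, "EnzymeDB"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(db@records, file.path(dir, "enzymes.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(db@genomeIndex, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(db@ecIndex, file.path(dir, "ec_index.json"))
  invisible(dir)
}

#' @rdname writeEnzymeDB
#' @export
readEnzymeDB <- function(dir) {
  records <- utils::read.delim(file.path(dir, "enzymes.tsv"),
                               stringsAsFactors = FALSE)
  genomeIndex <- utils::read.delim(file.path(dir, "taxonomy.tsv"),
                                   stringsAsFactors = FALSE)
  ecIndex <- lapply(jsonlite::read_json(file.path(dir, "ec_index.json"),
                                        simplifyVector = TRUE), as.integer)
  new("EnzymeDB", records = records, ecIndex = ecIndex,
      genomeIndex = genomeIndex)
}
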