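#' The three-step prediction workflow
#'
#' For each query molecule: (1) the class-level random forest predicts the
#' EC class; (2) the class-specific forest predicts the EC subclass; (3) a
#' consensus Tanimoto search against the predicted subclass's substrates
#' assigns four-digit EC number(s), which are resolved against the enzyme
#' database into bacterial enzymes, genomes and taxonomic lineages. Any
#' stage may halt the chain explicitly ("unclassified",
#' "no-subclass-model", "no-confident-EC", "empty-database"); downstream
#' fields then stay empty and the stage log records the reason.
#'
#' @name pipeline
NULL

#' Predict the biotransforming enzymes of one query molecule
#'
#' @param query list or one-row data.frame with `id` and `smiles` (raw
#'   SMILES accepted; canonicalized internally).
#' @param model a [CascadeModel-class].
#' @param sdb the [SubstrateDB-class] backing the similarity search.
#' @param edb the [EnzymeDB-class] resolving ECs to bacteria.
#' @param config list of options: `classThreshold`, `subclassThreshold`
#'   (minimum winning probability, default 0), `tcCutoff` (default 0.5),
#'   `families` (similarity families).
#' @return a [PredictionResult-class].
#' @export
predictBiotransformation <- function(query, model, sdb, edb,
                                     config = list()) {
  stopifnot(is(model, "CascadeModel"), is(sdb, "SubstrateDB"),
            is(edb, "EnzymeDB"))
  if (!identical(model@specKey, contentKey(model@hybridSpec@selected)))
    stop("model bundle corrupt: hybrid spec hash mismatch")
  cfg <- utils::modifyList(
    list(classThreshold = 0, subclassThreshold = 0, tcCutoff = 0.5,
         families = c("fp2like", "fp4like", "maccslike")),
    config)
  qid <- as.character(query$id %||% query[["id"]])
  stages <- character(0)
  emptyResult <- function(stages) {
    new("PredictionResult", queryId = qid, classDigit = NA_integer_,
        classProbs = numeric(0), subclassDigit = NA_integer_,
        subclassProbs = numeric(0), similarity = list(),
        assignedECs = character(0),
        enzymes = data.frame(), stages = stages)
  }
  can <- canonicalSmiles(query$smiles)
  if (is.na(can))
    return(emptyResult(c(stages, "parse: failed")))
  stages <- c(stages, "parse: ok")
  fp <- tryCatch(
    fingerprintMatrix(stats::setNames(can, qid),
                      families = model@hybridSpec@families),
    error = function(e) NULL)
  if (is.null(fp) || nrow(fp) != 1L)
    return(emptyResult(c(stages, "fingerprint: failed")))
  stages <- c(stages, "fingerprint: ok")

  cls <- predictClass(model, fp[1L, ], threshold = cfg$classThreshold)
  if (is.na(cls$classDigit)) {
    res <- emptyResult(c(stages, "class: unclassified"))
    res@classProbs <- cls$probs
    return(res)
  }
  stages <- c(stages, sprintf("class: %d (p=%.3f)", cls$classDigit,
                              max(cls$probs)))

  sub <- predictSubclass(model, cls$classDigit, fp[1L, ],
                         threshold = cfg$subclassThreshold)
  if (is.na(sub$subclassDigit)) {
    res <- emptyResult(c(stages, paste0("subclass: ", sub$outcome)))
    res@classDigit <- cls$classDigit
    res@classProbs <- cls$probs
    res@subclassProbs <- sub$probs
    return(res)
  }
  stages <- c(stages, sprintf("subclass: %d.%d (p=%.3f)", cls$classDigit,
                              sub$subclassDigit, max(sub$probs)))

  asg <- assignEC(can, sdb, cls$classDigit, sub$subclassDigit,
                  tcCutoff = cfg$tcCutoff, families = cfg$families)
  if (asg$outcome != "ok") {
    res <- emptyResult(c(stages, paste0("similarity: ", asg$outcome)))
    res@classDigit <- cls$classDigit
    res@classProbs <- cls$probs
    res@subclassDigit <- sub$subclassDigit
    res@subclassProbs <- sub$probs
    res@similarity <- if (is.null(asg$hit)) list() else asg$hit
    return(res)
  }
  stages <- c(stages, sprintf("similarity: %s (TC=%.3f, consensus %d/3)",
                              asg$hit$substrate_id, asg$hit$winning_tc,
                              asg$hit$consensus_family_count))

  enz <- do.call(rbind, lapply(asg$ecs, function(e) {
    r <- lookupEC(edb, e, allowPartial = anyNA(ecParse(e)))
    if (nrow(r)) r$assigned_ec <- e
    r
  }))
  enz <- enz %||% data.frame()
  stages <- c(stages, sprintf("enzymes: %d records for EC(s) %s",
                              nrow(enz), paste(asg$ecs, collapse = ",")))
  new("PredictionResult", queryId = qid, classDigit = cls$classDigit,
      classProbs = cls$probs, subclassDigit = sub$subclassDigit,
      subclassProbs = sub$probs, similarity = asg$hit,
      assignedECs = asg$ecs, enzymes = enz, stages = stages)
}

#' Batch prediction
#'
#' @param queries data.frame with columns `id` and `smiles`.
#' @param model,sdb,edb,config as in [predictBiotransformation()].
#' @return list of [PredictionResult-class], one per query, in input order.
#' @export
predictBatch <- function(queries, model, sdb, edb, config = list()) {
  lapply(seq_len(nrow(queries)), function(i)
    predictBiotransformation(queries[i, , drop = FALSE], model, sdb, edb,
                             config))
}

#' Tabulate prediction results
#'
#' One row per (query, EC, enzyme); queries that halted early yield a
#' single row with empty downstream fields.
#'
#' @param results list of [PredictionResult-class].
#' @return data.frame.
#' @export
predictionTable <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    base <- data.frame(
      query_id = r@queryId,
      ec_class = ifelse(is.na(r@classDigit), "", as.character(r@classDigit)),
      class_prob = if (length(r@classProbs)) max(r@classProbs) else NA_real_,
      ec_subclass = ifelse(is.na(r@subclassDigit), "",
                           paste0(r@classDigit, ".", r@subclassDigit)),
      similar_substrate = if (length(r@similarity)) r@similarity$substrate_id else "",
      tanimoto = if (length(r@similarity)) r@similarity$winning_tc else NA_real_,
      stringsAsFactors = FALSE)
    if (nrow(r@enzymes) == 0L) {
      base$assigned_ec <- if (length(r@assignedECs))
        paste(r@assignedECs, collapse = ";") else ""
      base$protein_id <- ""; base$genome_id <- ""; base$lineage <- ""
      return(base)
    }
    cbind(base[rep(1L, nrow(r@enzymes)), , drop = FALSE],
          r@enzymes[, c("assigned_ec", "protein_id", "genome_id", "lineage")],
          row.names = NULL)
  }))
}

#' Save / load a cascade model bundle
#'
#' The bundle directory holds the serialized forests plus a plain-text
#' `manifest.json` (hybrid spec, sampling mode, seed, tuning traces,
#' training counts) so any bundle is auditable without loading it.
#'
#' @param model a [CascadeModel-class].
#' @param dir bundle directory.
#' @export
saveCascade <- function(model, dir) {
  stopifnot(is(model, "CascadeModel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "cascade.rds"))
  jsonlite::write_json(
    list(hybrid_spec = model@hybridSpec@selected,
         hybrid_spec_key = model@specKey,
         families = model@hybridSpec@families,
         sampling = model@sampling, seed = model@seed,
         tuning = lapply(model@tuning, function(t)
           t[c("mtry", "ntree", "oob_error_percent")]),
         training_counts = model@trainingCounts),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveCascade
#' @export
loadCascade <- function(dir) {
  model <- readRDS(file.path(dir, "cascade.rds"))
  stopifnot(is(model, "CascadeModel"))
  if (!identical(model@specKey, contentKey(model@hybridSpec@selected)))
    stop("model bundle corrupt: hybrid spec hash mismatch")
  model
}
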