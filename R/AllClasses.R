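#' @import methods
NULL

#' HybridSpec: a selected hybrid-fingerprint bit set
#'
#' Records which `(family, bit)` columns compose the hybrid fingerprint, in
#' their selection order (families in registration order, bits ascending
#' within a family), together with the selection parameters that produced
#' them. Column identifiers follow the stable `"family:bitindex"` scheme
#' (0-based bit indices).
#'
#' @slot selected ordered character vector of column ids `"family:bit"`.
#' @slot families character vector of the families the spec was built from.
#' @slot params list of selection parameters (dominance threshold, best-first
#'   staleness limit, per-family bit counts).
#' @export
setClass("HybridSpec", representation(
  selected = "character",
  families = "character",
  params = "list"
))

setValidity("HybridSpec", function(object) {
  msgs <- character()
  if (anyDuplicated(object@selected))
    msgs <- c(msgs, "duplicate column ids in 'selected'")
  fams <- sub(":.*$", "", object@selected)
  if (length(object@selected) && !all(fams %in% object@families))
    msgs <- c(msgs, "selected columns reference unknown families")
  if (!all(grepl("^[a-z0-9]+:[0-9]+$", object@selected)))
    msgs <- c(msgs, "column ids must have the form 'family:bitindex'")
  if (length(msgs)) msgs else TRUE
})

#' SubstrateDB: curated, EC-tagged substrate database
#'
#' The training database of the method: one row per retained substrate
#' molecule, each tagged with one or more four-digit EC numbers that all share
#' a single EC class (enforced by curation), indexed by EC class and by
#' (class, subclass) pairs.
#'
#' @slot records data.frame with columns `id`, `smiles` (canonical),
#'   `name`, `provenance` and list-column `ecTags` (character vectors of
#'   four-digit EC labels).
#' @slot classIndex named list: class digit (as character) -> record ids.
#' @slot subclassIndex named list: `"class.subclass"` -> record ids.
#' @slot log character vector of per-stage curation counts and actions.
#' @export
setClass("SubstrateDB", representation(
  records = "data.frame",
  classIndex = "list",
  subclassIndex = "list",
  log = "character"
))

setValidity("SubstrateDB", function(object) {
  r <- object@records
  msgs <- character()
  need <- c("id", "smiles", "ecTags")
  if (!all(need %in% names(r)))
    return(paste("records must contain columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(r$id)) msgs <- c(msgs, "duplicate record ids")
  if (anyDuplicated(r$smiles)) msgs <- c(msgs, "duplicate canonical keys")
  if (nrow(r)) {
    classes <- lapply(r$ecTags, function(tags) unique(ecClass(tags)))
    if (any(lengths(r$ecTags) == 0L)) msgs <- c(msgs, "record with empty ecTags")
    if (any(lengths(classes) != 1L))
      msgs <- c(msgs, "record whose ecTags span multiple EC classes")
    idx <- unlist(object@classIndex, use.names = FALSE)
    if (length(idx) != nrow(r) || !setequal(idx, r$id))
      msgs <- c(msgs, "classIndex is not a partition of records")
    sub <- unlist(object@subclassIndex, use.names = FALSE)
    if (!all(sub %in% r$id))
      msgs <- c(msgs, "subclassIndex references unknown ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' EnzymeDB: EC-annotated gut bacterial enzyme database
#'
#' Proteins annotated with a four-digit EC number by best-hit filtering of a
#' tabular protein-alignment file, joined to their genomes and taxonomic
#' lineages.
#'
#' @slot records data.frame with columns `protein_id`, `genome_id`, `ec`,
#'   `subject_id`, `identity`, `query_coverage`, `evalue`, `bitscore`.
#' @slot ecIndex named list: EC label -> row indices into `records`.
#' @slot genomeIndex data.frame with columns `genome_id`, `lineage`.
#' @export
setClass("EnzymeDB", representation(
  records = "data.frame",
  ecIndex = "list",
  genomeIndex = "data.frame"
))

setValidity("EnzymeDB", function(object) {
  msgs <- character()
  idx <- unlist(object@ecIndex, use.names = FALSE)
  if (length(idx) != nrow(object@records) ||
      (length(idx) && !setequal(idx, seq_len(nrow(object@records)))))
    msgs <- c(msgs, "ecIndex must cover each record exactly once")
  if (!all(object@records$genome_id %in% object@genomeIndex$genome_id))
    msgs <- c(msgs, "record genome without taxonomy entry")
  if (length(msgs)) msgs else TRUE
})

#' CascadeModel: the two-level random-forest cascade
#'
#' One random forest discriminating the six EC classes, plus one forest per
#' EC class discriminating that class's subclasses, all trained on features
#' projected through a shared [HybridSpec-class]. Tuning metadata (mtry/ntree
#' search traces and out-of-bag errors) is retained so any model bundle is
#' auditable and reproducible.
#'
#' @slot classModel the class-level `randomForest` fit.
#' @slot subclassModels named list, class digit -> `randomForest` fit (a class
#'   may legitimately lack a model when too few subclasses are trainable).
#' @slot hybridSpec the [HybridSpec-class] all models were trained through.
#' @slot sampling `"with_upsampling"` or `"without_upsampling"`.
#' @slot tuning named list of tuning results (`mtry`, `ntree`,
#'   `oob_error_percent`, `trace`) per model.
#' @slot seed integer seed that reproduces the whole cascade.
#' @slot specKey content key of the hybrid spec, checked at prediction time.
#' @slot trainingCounts named list of per-model training class counts.
#' @export
setClass("CascadeModel", representation(
  classModel = "ANY",
  subclassModels = "list",
  hybridSpec = "HybridSpec",
  sampling = "character",
  tuning = "list",
  seed = "integer",
  specKey = "character",
  trainingCounts = "list"
))

setValidity("CascadeModel", function(object) {
  msgs <- character()
  if (!object@sampling %in% c("with_upsampling", "without_upsampling"))
    msgs <- c(msgs, "sampling must be with_upsampling or without_upsampling")
  keys <- names(object@subclassModels)
  if (length(keys) && !all(keys %in% as.character(1:6)))
    msgs <- c(msgs, "subclassModels keys must be class digits 1..6")
  if (length(msgs)) msgs else TRUE
})

#' PredictionResult: one query molecule's full prediction chain
#'
#' The staged outcome of the three-step prediction: EC class (random forest),
#' EC subclass (class-specific random forest), most-similar substrate
#' (three-fingerprint consensus Tanimoto search), assigned four-digit EC(s),
#' and the bacterial enzymes/genomes/taxonomies carrying them. Early halts
#' ("unclassified", "no-confident-EC", "empty-database") leave downstream
#' slots empty and are recorded in the stage log.
#'
#' @slot queryId query molecule identifier.
#' @slot classDigit predicted EC class (NA when unclassified).
#' @slot classProbs named numeric vector of class probabilities.
#' @slot subclassDigit predicted subclass digit (NA when unavailable).
#' @slot subclassProbs named numeric vector of subclass probabilities.
#' @slot similarity list: consensus similarity hit (substrate id, per-family
#'   Tanimoto coefficients, consensus count, winning coefficient).
#' @slot assignedECs character vector of assigned EC labels.
#' @slot enzymes data.frame of matching enzyme records with taxonomy.
#' @slot stages character vector: ordered stage log.
#' @export
setClass("PredictionResult", representation(
  queryId = "character",
  classDigit = "integer",
  classProbs = "numeric",
  subclassDigit = "integer",
  subclassProbs = "numeric",
  similarity = "list",
  assignedECs = "character",
  enzymes = "data.frame",
  stages = "character"
))

# ---- show methods -----------------------------------------------------------

setMethod("show", "HybridSpec", function(object) {
  cat("HybridSpec:", length(object@selected), "bits from",
      length(object@families), "families\n")
  tab <- table(sub(":.*$", "", object@selected))
  for (f in object@families)
    cat("  ", f, ": ", if (f %in% names(tab)) tab[[f]] else 0L, " bits\n", sep = "")
})

setMethod("show", "SubstrateDB", function(object) {
  cat("SubstrateDB:", nrow(object@records), "curated substrate records\n")
  cat("  EC classes:", paste(names(object@classIndex), collapse = ", "), "\n")
  cat("  subclass subsets:", length(object@subclassIndex), "\n")
})

setMethod("show", "EnzymeDB", function(object) {
  cat("EnzymeDB:", nrow(object@records), "enzyme records,",
      length(object@ecIndex), "distinct ECs,",
      nrow(object@genomeIndex), "genomes\n")
})

setMethod("show", "CascadeModel", function(object) {
  cat("CascadeModel (", object@sampling, ", seed ", object@seed, ")\n", sep = "")
  cat("  hybrid bits:", length(object@hybridSpec@selected), "\n")
  cat("  subclass models for classes:",
      paste(names(object@subclassModels), collapse = ", "), "\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult for", object@queryId, "\n")
  cat("  class:", ifelse(is.na(object@classDigit), "unclassified", object@classDigit),
      if (!is.na(object@classDigit))
        sprintf("(p=%.3f)", object@classProbs[as.character(object@classDigit)]), "\n")
  if (!is.na(object@subclassDigit))
    cat("  subclass:", paste0(object@classDigit, ".", object@subclassDigit), "\n")
  if (length(object@assignedECs))
    cat("  assigned EC(s):", paste(object@assignedECs, collapse = ", "), "\n")
  cat("  enzymes:", nrow(object@enzymes), "records\n")
  cat("  stages:", paste(object@stages, collapse = " | "), "\n")
})

# ---- accessors --------------------------------------------------------------

#' Accessors for xenozyme S4 containers
#'
#' Small read-only accessors, preferred over direct slot access.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
hybridBits <- function(x) { stopifnot(is(x, "HybridSpec")); x@selected }

#' @rdname accessors
#' @export
substrateRecords <- function(x) { stopifnot(is(x, "SubstrateDB")); x@records }

#' @rdname accessors
#' @export
classIndex <- function(x) { stopifnot(is(x, "SubstrateDB")); x@classIndex }

#' @rdname accessors
#' @export
subclassIndex <- function(x) { stopifnot(is(x, "SubstrateDB")); x@subclassIndex }

#' @rdname accessors
#' @export
curationLog <- function(x) { stopifnot(is(x, "SubstrateDB")); x@log }

#' @rdname accessors
#' @export
enzymeRecords <- function(x) { stopifnot(is(x, "EnzymeDB")); x@records }

#' @rdname accessors
#' @export
ecIndex <- function(x) { stopifnot(is(x, "EnzymeDB")); x@ecIndex }

#' @rdname accessors
#' @export
genomeIndex <- function(x) { stopifnot(is(x, "EnzymeDB")); x@genomeIndex }

#' @rdname accessors
#' @export
hybridSpec <- function(x) { stopifnot(is(x, "CascadeModel")); x@hybridSpec }

#' @rdname accessors
#' @export
modelTuning <- function(x) { stopifnot(is(x, "CascadeModel")); x@tuning }

#' @rdname accessors
#' @export
assignedECs <- function(x) { stopifnot(is(x, "PredictionResult")); x@assignedECs }

#' @rdname accessors
#' @export
predictedEnzymes <- function(x) { stopifnot(is(x, "PredictionResult")); x@enzymes }

#' @rdname accessors
#' @export
stageLog <- function(x) { stopifnot(is(x, "PredictionResult")); x@stages }
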