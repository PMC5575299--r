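#' Molecule input/output and canonicalization
#'
#' Molecules are carried through the package as plain data.frames with one
#' row per molecule and, at minimum, columns `id` and `smiles`, where
#' `smiles` holds the canonical SMILES used as the deduplication key: it is
#' identical for any two structurally identical inputs regardless of atom
#' ordering or input format. Canonicalization is delegated to Open Babel
#' (via ChemmineOB); stereochemistry is retained when present and hydrogens
#' are implicit (all fingerprint families in use are defined on heavy-atom
#' graphs).
#'
#' Multi-fragment inputs (salts, counter-ions) are reduced to their largest
#' covalent fragment, and the action is recorded in the molecule's
#' provenance column.
#'
#' @name chem-io
NULL

# heavy-atom count of a SMILES string: bracket atoms (except [H]) plus
# organic-subset symbols outside brackets
heavyAtomCount <- function(smiles) {
  vnapply(smiles, function(s) {
    if (is.na(s)) return(NA_real_)
    brackets <- regmatches(s, gregexpr("\\[[^]]*\\]", s))[[1]]
    nb <- sum(!grepl("^\\[[0-9]*H[0-9+\\-]*\\]$", brackets))
    rest <- gsub("\\[[^]]*\\]", "", s)
    m <- gregexpr("Cl|Br|B|C|N|O|P|S|F|I|b|c|n|o|p|s", rest)[[1]]
    nb + sum(m > 0)
  })
}

# batch Open Babel SMILES -> canonical SMILES; returns named character
# vector aligned with input, NA where Open Babel could not parse the entry
obCanonical <- function(smiles) {
  if (!length(smiles)) return(character(0))
  tags <- sprintf("x%06d", seq_along(smiles))
  input <- paste0(paste(smiles, tags), "\n", collapse = "")
  outTxt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", input)),
    error = function(e) ""
  )
  out <- rep(NA_character_, length(smiles))
  lines <- strsplit(outTxt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "[ \t]+")[[1]]
    if (length(tok) >= 2L) {
      i <- match(tok[2L], tags)
      if (!is.na(i)) out[i] <- tok[1L]
    }
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  # a malformed record can derail Open Babel's batch reader; retry missing
  # entries one at a time so one bad record never costs its neighbours
  retry <- which(is.na(out) & !is.na(smiles))
  if (length(retry) && length(smiles) > 1L) {
    for (i in retry) out[i] <- obCanonical(smiles[i])
  }
  names(out) <- names(smiles)
  out
}

#' Canonical SMILES keys
#'
#' Computes the canonical SMILES key for each input SMILES. With
#' `keepLargestFragment = TRUE` (the default) multi-fragment records are
#' reduced to the fragment with the most heavy atoms (ties broken toward the
#' first) before canonicalization.
#'
#' @param smiles character vector of SMILES strings.
#' @param keepLargestFragment reduce salts/mixtures to the dominant fragment.
#' @return character vector of canonical SMILES, `NA` for unparseable input,
#'   with attribute `"fragmentReduced"` (logical) marking entries where a
#'   fragment was stripped.
#' @export
canonicalSmiles <- function(smiles, keepLargestFragment = TRUE) {
  can <- obCanonical(smiles)
  reduced <- logical(length(can))
  if (keepLargestFragment) {
    multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
    if (length(multi)) {
      picks <- vcapply(can[multi], function(s) {
        frags <- strsplit(s, ".", fixed = TRUE)[[1]]
        frags[which.max(heavyAtomCount(frags))]
      })
      can[multi] <- obCanonical(picks)
      reduced[multi] <- TRUE
    }
  }
  attr(can, "fragmentReduced") <- reduced
  can
}

#' Read molecules from SDF, MOL or SMILES-table files
#'
#' Parses a molecule file, canonicalizes every record, and returns both the
#' successfully parsed molecules and a structured list of per-record
#' failures. Individual bad records are collected, never silently dropped
#' and never fatal; an unreadable file is fatal.
#'
#' @param path path to the input file.
#' @param format one of `"sdf"` (V2000 multi-record), `"mol"` (single
#'   record), `"smiles"` (2-column tab-separated `smiles<TAB>id`; lines
#'   starting with `#` ignored).
#' @return list with elements `molecules` (data.frame: `id`, `smiles`
#'   (canonical key), `input_smiles`, `name`, `provenance`) and `failures`
#'   (data.frame: `index`, `id`, `reason`).
#' @export
readMolecules <- function(path, format = c("sdf", "mol", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  failures <- data.frame(index = integer(), id = character(),
                         reason = character(), stringsAsFactors = FALSE)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    raw <- vcapply(parts, `[`, 1L)
    ids <- vcapply(parts, function(p) if (length(p) >= 2L) p[2L] else NA_character_)
    ids[is.na(ids)] <- sprintf("mol%04d", which(is.na(ids)))
    names <- rep(NA_character_, length(raw))
  } else {
    txt <- readLines(path, warn = FALSE)
    if (format == "mol" && !any(grepl("^\\$\\$\\$\\$", txt)))
      txt <- c(txt, "$$$$")
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(txt, tmp)
    sdf <- tryCatch(ChemmineR::read.SDFset(tmp),
                    error = function(e) stop("unreadable ", format, " file: ",
                                             path, " (", conditionMessage(e), ")"))
    ok <- ChemmineR::validSDF(sdf)
    ids <- ChemmineR::sdfid(sdf)
    ids[is.na(ids) | !nzchar(ids)] <- sprintf("mol%04d", which(is.na(ids) | !nzchar(ids)))
    raw <- rep(NA_character_, length(sdf))
    if (any(ok)) {
      smi <- tryCatch(ChemmineR::sdf2smiles(sdf[ok]), error = function(e) NULL)
      if (!is.null(smi)) raw[ok] <- unname(as.character(smi))
    }
    for (i in which(!ok))
      failures <- rbind(failures, data.frame(index = i, id = ids[i],
                                             reason = "invalid SDF record"))
    names <- ids
  }
  can <- canonicalSmiles(raw)
  reduced <- attr(can, "fragmentReduced")
  bad <- is.na(can) & !(seq_along(can) %in% failures$index)
  for (i in which(bad))
    failures <- rbind(failures, data.frame(index = i, id = ids[i],
                                           reason = "SMILES canonicalization failed"))
  keep <- !is.na(can)
  mols <- data.frame(
    id = ids[keep],
    smiles = unname(can[keep]),
    input_smiles = raw[keep],
    name = names[keep],
    provenance = ifelse(reduced[keep],
                        "kept largest covalent fragment", "parsed"),
    stringsAsFactors = FALSE
  )
  if (nrow(mols) == 0L && nrow(failures) == 0L && format == "smiles")
    mols <- mols   # empty file is a valid empty table
  list(molecules = mols, failures = failures)
}

#' Write molecules to SDF or SMILES-table files
#'
#' Serializes molecules so that `readMolecules(writeMolecules(x))`
#' reproduces the same canonical keys in the same order.
#'
#' @param mols data.frame with columns `id` and `smiles`.
#' @param path output path.
#' @param format `"sdf"` or `"smiles"`.
#' @export
writeMolecules <- function(mols, path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(mols), all(c("id", "smiles") %in% names(mols)))
  if (format == "smiles") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# smiles\tid", con)
    if (nrow(mols))
      writeLines(paste(mols$smiles, mols$id, sep = "\t"), con)
  } else {
    if (nrow(mols) == 0L) { file.create(path); return(invisible(NULL)) }
    smi <- stats::setNames(mols$smiles, mols$id)
    sdf <- ChemmineR::smiles2sdf(smi)
    ChemmineR::write.SDF(sdf, file = path, cid = TRUE)
  }
  invisible(NULL)
}
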