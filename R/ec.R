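#' Enzyme Commission (EC) label utilities
#'
#' EC numbers are four-level hierarchical identifiers of enzyme-catalysed
#' reactions, written `class.subclass.subsubclass.serial` (e.g. `3.2.1.21`).
#' Partial labels use `-` for unknown levels (e.g. `1.14.-.-`); a wildcard at
#' one level forces wildcards at all deeper levels. The top-level class digit
#' is always 1--6 (oxidoreductases, transferases, hydrolases, lyases,
#' isomerases, ligases).
#'
#' `ecParse()` converts labels to a 4-column integer matrix with `NA` for
#' wildcards; `ecFormat()` is its inverse; `ecIsValid()` vectorises the
#' syntactic check; `ecClass()`/`ecSubclass()` extract single digits;
#' `ecMatches()` implements hierarchical (prefix) matching used for partial
#' EC lookups.
#'
#' @param ec,query,target character vector(s) of EC labels.
#' @param mat integer matrix with 4 columns as returned by `ecParse()`.
#' @return `ecParse()` an integer matrix (rows = labels, columns =
#'   class/subclass/subsubclass/serial, `NA` = wildcard); `ecFormat()` a
#'   character vector; `ecIsValid()` a logical vector; `ecMatches()` a logical
#'   vector saying, for each `target`, whether it agrees with `query` on every
#'   non-wildcard level of `query`.
#' @examples
#' ecParse("1.14.-.-")
#' ecMatches("1.14.-.-", c("1.14.13.7", "1.1.1.1"))
#' @name ec-utils
NULL

#' @rdname ec-utils
#' @export
ecParse <- function(ec) {
  stopifnot(is.character(ec))
  parts <- strsplit(ec, ".", fixed = TRUE)
  bad <- vlapply(parts, function(p) length(p) != 4L)
  mat <- matrix(NA_integer_, nrow = length(ec), ncol = 4L,
                dimnames = list(ec, c("class", "subclass", "subsubclass", "serial")))
  for (i in seq_along(parts)) {
    if (bad[i]) next
    p <- parts[[i]]
    v <- suppressWarnings(as.integer(p))
    v[p == "-"] <- NA_integer_
    malformed <- any(p != "-" & (is.na(v) | v < 1L))
    # wildcard cascade: once wild, all deeper levels must be wild
    wild <- is.na(v)
    cascadeOK <- !is.unsorted(wild)   # FALSE..TRUE pattern only
    if (malformed || !cascadeOK || is.na(v[1L]) || v[1L] < 1L || v[1L] > 6L) {
      bad[i] <- TRUE
    } else {
      mat[i, ] <- v
    }
  }
  if (any(bad)) stop("malformed EC label(s): ", paste(ec[bad], collapse = ", "))
  mat
}

#' @rdname ec-utils
#' @export
ecFormat <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) == 4L)
  apply(mat, 1L, function(r) paste(ifelse(is.na(r), "-", r), collapse = "."))
}

#' @rdname ec-utils
#' @export
ecIsValid <- function(ec) {
  vlapply(ec, function(e) !inherits(try(ecParse(e), silent = TRUE), "try-error"))
}

#' @rdname ec-utils
#' @export
ecClass <- function(ec) unname(ecParse(ec)[, 1L])

#' @rdname ec-utils
#' @export
ecSubclass <- function(ec) unname(ecParse(ec)[, 2L])

#' @rdname ec-utils
#' @export
ecMatches <- function(query, target) {
  q <- ecParse(query)
  if (nrow(q) != 1L) stop("ecMatches() takes a single query label")
  t <- ecParse(target)
  lvl <- which(!is.na(q[1L, ]))
  unname(apply(t, 1L, function(r)
    all(r[lvl] == q[1L, lvl], na.rm = FALSE) %in% TRUE))
}
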