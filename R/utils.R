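# internal helpers shared across modules

# round-half-up; base round() is banker's rounding
roundHalfUp <- function(x) floor(x + 0.5)

# run expr with a locally-seeded RNG, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# stable content key for a character vector (model/spec compatibility checks)
contentKey <- function(x) {
  x <- paste(x, collapse = "\x1f")
  # 31-polynomial rolling hash mod (2^31 - 1), dependency-free
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

vlapply <- function(x, f, ...) vapply(x, f, logical(1L), ...)
vcapply <- function(x, f, ...) vapply(x, f, character(1L), ...)
vnapply <- function(x, f, ...) vapply(x, f, numeric(1L), ...)
viapply <- function(x, f, ...) vapply(x, f, integer(1L), ...)

`%||%` <- function(a, b) if (is.null(a)) b else a
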