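## Internal helpers: residue encoding, coordinate conversion, rounding,
## seed splitting and logging.

#' Encode an amino-acid string as integer codes
#'
#' Maps the 20 standard residues to 1..20 in [AA_ALPHABET20] order; any
#' other letter (X, B, Z, U, O, J, ...) maps to the unknown code, which is
#' scored at background (log-odds 0) by the search engine.
#'
#' @param x A character scalar (protein sequence).
#' @return Integer vector of codes.
#' @keywords internal
encodeResidues <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "")[[1]]
  idx <- match(chars, AA_ALPHABET20)
  idx[is.na(idx)] <- AA_UNKNOWN_CODE
  idx
}

decodeResidues <- function(codes) {
  out <- rep("X", length(codes))
  ok <- codes >= 1L & codes <= 20L
  out[ok] <- AA_ALPHABET20[codes[ok]]
  paste0(out, collapse = "")
}

#' Round half away from zero
#'
#' Integer rounding used for all reported percentages (base `round()`
#' rounds half to even, which is not the convention of printed tables).
#'
#' @param x numeric.
#' @return numeric of the same length, integral-valued.
#' @keywords internal
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

## 1-based inclusive (file convention) <-> 0-based half-open (internal)
toFileCoords <- function(start0, end0) {
  list(start = start0 + 1L, end = end0)
}
toInternalCoords <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

## Derive a per-stream 32-bit seed from a global seed and an index, so
## appending proteins to a config never changes earlier proteins' draws.
splitSeed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271 + as.double(index) * 16807) %% 2147483647
  x <- (x * 69621) %% 2147483647
  as.integer(x)
}

## Run expr with a local RNG state seeded from `seed` (restores the caller's
## RNG afterwards).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Leveled logging to standard error; machine-readable outputs stay on
## stdout / in files.
screenLog <- function(level = c("info", "debug", "warn", "error"), ...) {
  level <- match.arg(level)
  opt <- getOption("CRRscreen.verbose", TRUE)
  if (!isTRUE(opt) && level %in% c("debug", "info")) return(invisible(NULL))
  message(sprintf("[%s] %s", toupper(level), paste0(..., collapse = "")))
  invisible(NULL)
}

## log2-sum-exp of a numeric vector (base-2 log domain)
log2SumExp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
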