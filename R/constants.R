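## Shared constants: amino-acid alphabet, background composition, and the
## default cysteine-rich module consensus used by the synthetic generator.

#' The 20-letter amino-acid alphabet
#'
#' Residue order used for all emission vectors and matrices in the package
#' (alphabetical one-letter codes).
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

## Integer codes appended after the 20 residues:
##  21 = unknown residue (X/B/Z/U/O/J...), scored at background (log-odds 0)
##  22 = masked residue, match emission forbidden (-Inf)
AA_UNKNOWN_CODE <- 21L
AA_MASK_CODE <- 22L

#' Background amino-acid frequencies
#'
#' Fixed background composition of globular proteins (Robinson--Robinson
#' style frequencies, normalised to sum exactly to 1). All log-odds scores,
#' pseudocounts, decoy sampling and synthetic background proteins use this
#' single table so that E-value calibration is reproducible.
#'
#' @format Named numeric vector of length 20 summing to 1, names in
#'   [AA_ALPHABET20] order.
#' @export
BACKGROUND_FREQS <- local({
  f <- c(
    A = 0.0787945, C = 0.0151600, D = 0.0535222, E = 0.0668298,
    F = 0.0397062, G = 0.0695071, H = 0.0229198, I = 0.0590092,
    K = 0.0646520, L = 0.0966459, M = 0.0237793, N = 0.0414128,
    P = 0.0457031, Q = 0.0349061, R = 0.0551046, S = 0.0756591,
    T = 0.0536518, V = 0.0667357, W = 0.0118490, Y = 0.0305961
  )
  f / sum(f)
})

#' Default cysteine-rich module consensus
#'
#' A 33-residue stand-in consensus for one cysteine-rich module: six
#' invariant cysteines (positions 3, 8, 14, 19, 24, 32), glycines at
#' positions 10, 21, 26 and 30 and prolines at positions 29 and 31
#' (1-based). Only the cysteines are treated as unconditionally invariant
#' by the synthetic generator; all other positions are subject to the
#' configured substitution rate.
#'
#' @format A character scalar of 33 residues.
#' @export
DEFAULT_MODULE_CONSENSUS <- "ASCQETLCNGKVYCDRFSCAGIECKGNLPGPCV"

#' Invariant positions of the default module consensus
#'
#' 1-based positions of the six invariant cysteines in
#' [DEFAULT_MODULE_CONSENSUS].
#'
#' @format Integer vector.
#' @export
DEFAULT_INVARIANT_POSITIONS <- c(3L, 8L, 14L, 19L, 24L, 32L)

## Euler-Mascheroni constant, used by the method-of-moments Gumbel fit.
EULER_GAMMA <- 0.5772156649015329

## Controlled vocabulary of function tags understood by classifyFunction().
FUNCTION_TAG_VOCABULARY <- c(
  "cell_wall_hydrolase", "lysozyme", "amidase", "peptidase",
  "glycoside_hydrolase", "unknown"
)

## Function tags that imply cell-wall hydrolase activity (lysozymes,
## peptidoglycan amidases, M15-type peptidases, glycoside hydrolases of the
## lysozyme superfamily).
CELL_WALL_TAGS <- c(
  "cell_wall_hydrolase", "lysozyme", "amidase", "glycoside_hydrolase"
)
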