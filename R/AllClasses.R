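## S4 classes: the profile HMM, domain-family library, and search result.

setClassUnion("characterOrNULL", c("character", "NULL"))

#' Local-alignment profile hidden Markov model
#'
#' A profile HMM over match, insert and delete states with free local
#' entry/exit: the begin state enters any match state with uniform
#' probability, every match state carries an exit transition to the end
#' state, and flanking residues are emitted by the background (null) model
#' so they contribute zero log-odds. Insert state \eqn{I_j} sits between
#' match states \eqn{M_j} and \eqn{M_{j+1}} (so there are \eqn{L-1} usable
#' insert states) and delete states \eqn{D_2..D_L} allow interior match
#' states to be skipped; \eqn{D_L} exits to the end state with
#' probability 1.
#'
#' @slot matchEmis numeric matrix, `nMatch x 20`: match emission
#'   probabilities in [AA_ALPHABET20] order; each row sums to 1.
#' @slot insEmis numeric matrix, `nMatch x 20`: insert emission
#'   probabilities (row `L` is unused by the topology and kept at
#'   background).
#' @slot entry numeric, length `nMatch`: begin-to-match entry
#'   distribution (sums to 1).
#' @slot transM numeric matrix `nMatch x 4`, columns `mm`, `mi`, `md`,
#'   `me`: outgoing probabilities of each match state (row `L` has
#'   `me = 1`).
#' @slot transI numeric matrix `nMatch x 2`, columns `im`, `ii` (rows
#'   `1..L-1` meaningful).
#' @slot transD numeric matrix `nMatch x 2`, columns `dm`, `dd` (rows
#'   `2..L-1` meaningful; `D_L` exits with probability 1).
#' @slot background numeric, length 20: null-model residue frequencies.
#' @slot consensus character: most probable residue per match state.
#'
#' @seealso [buildProfile()], [viterbiScore()], [forwardScore()]
#' @export
setClass("ProfileHMM",
  representation(
    matchEmis = "matrix",
    insEmis = "matrix",
    entry = "numeric",
    transM = "matrix",
    transI = "matrix",
    transD = "matrix",
    background = "numeric",
    consensus = "character"
  )
)

.checkStochasticRows <- function(m, rows, what, tol = 1e-9) {
  msgs <- character(0)
  if (any(m < -tol)) msgs <- c(msgs, sprintf("%s has negative entries", what))
  if (length(rows)) {
    s <- rowSums(m[rows, , drop = FALSE])
    if (any(abs(s - 1) > tol)) {
      msgs <- c(msgs, sprintf("%s rows do not sum to 1 (max dev %.3g)",
                              what, max(abs(s - 1))))
    }
  }
  msgs
}

setValidity("ProfileHMM", function(object) {
  L <- nrow(object@matchEmis)
  msgs <- character(0)
  if (L < 1L) msgs <- c(msgs, "profile needs at least one match state")
  if (ncol(object@matchEmis) != 20L || ncol(object@insEmis) != 20L) {
    msgs <- c(msgs, "emission matrices must have 20 columns")
  }
  if (length(object@background) != 20L ||
      abs(sum(object@background) - 1) > 1e-9 || any(object@background <= 0)) {
    msgs <- c(msgs, "background must be 20 positive values summing to 1")
  }
  msgs <- c(msgs,
    .checkStochasticRows(object@matchEmis, seq_len(L), "match emissions"),
    .checkStochasticRows(object@insEmis, seq_len(L), "insert emissions"))
  if (abs(sum(object@entry) - 1) > 1e-9 || any(object@entry < 0)) {
    msgs <- c(msgs, "entry distribution must sum to 1")
  }
  msgs <- c(msgs, .checkStochasticRows(object@transM, seq_len(L),
                                       "match transitions"))
  if (L >= 1L && abs(object@transM[L, "me"] - 1) > 1e-9) {
    msgs <- c(msgs, "last match state must exit with probability 1")
  }
  if (L > 1L) {
    msgs <- c(msgs,
      .checkStochasticRows(object@transI, seq_len(L - 1L),
                           "insert transitions"))
    if (L > 2L) {
      msgs <- c(msgs,
        .checkStochasticRows(object@transD, 2:(L - 1L), "delete transitions"))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname ProfileHMM-class
#' Number of match states.
#' @param x,object A `ProfileHMM`.
#' @export
setGeneric("nMatch", function(x) standardGeneric("nMatch"))

#' @rdname ProfileHMM-class
#' @export
setMethod("nMatch", "ProfileHMM", function(x) nrow(x@matchEmis))

#' @rdname ProfileHMM-class
#' Match emission probability matrix.
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))

#' @rdname ProfileHMM-class
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmis)

#' @rdname ProfileHMM-class
#' Insert emission probability matrix.
#' @export
setGeneric("insertEmissions", function(x) standardGeneric("insertEmissions"))

#' @rdname ProfileHMM-class
#' @export
setMethod("insertEmissions", "ProfileHMM", function(x) x@insEmis)

#' @rdname ProfileHMM-class
#' Background (null model) residue frequencies.
#' @export
setGeneric("backgroundFreqs", function(x) standardGeneric("backgroundFreqs"))

#' @rdname ProfileHMM-class
#' @export
setMethod("backgroundFreqs", "ProfileHMM", function(x) x@background)

#' @rdname ProfileHMM-class
#' Consensus (argmax) residue string.
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @rdname ProfileHMM-class
#' @export
setMethod("consensusSeq", "ProfileHMM", function(x) x@consensus)

setMethod("show", "ProfileHMM", function(object) {
  cat(sprintf("ProfileHMM with %d match states\n", nMatch(object)))
  cat(sprintf("  consensus: %s\n", object@consensus))
  cat(sprintf("  mean match self-information: %.2f bits\n",
              mean(-log2(apply(object@matchEmis, 1, max)))))
  invisible(object)
})

#' A domain family: model, carrier species, function tags
#'
#' One entry of a domain-family library: an accession-style identifier, a
#' scoring model (a [ProfileHMM] built from the family's ungapped
#' consensus), the taxonomic lineages of the species known to carry the
#' family, and controlled-vocabulary function tags (e.g.
#' `"cell_wall_hydrolase"`).
#'
#' @slot familyId character: unique accession-style label.
#' @slot name character: human-readable name.
#' @slot consensus character: ungapped consensus sequence of the family.
#' @slot model A [ProfileHMM] used by [scanDomains()].
#' @slot carrierLineages data.frame with columns `species`,
#'   `superkingdom`, `kingdom`, `phylum` (one row per carrier species).
#' @slot functionTags character: tags from the controlled vocabulary.
#' @slot donorPhylum character or NULL: phylum of the synthetic donor used
#'   by the proteome generator (bookkeeping; empty for user libraries).
#' @export
setClass("DomainFamily",
  representation(
    familyId = "character",
    name = "character",
    consensus = "character",
    model = "ProfileHMM",
    carrierLineages = "data.frame",
    functionTags = "character",
    donorPhylum = "characterOrNULL"
  )
)

setValidity("DomainFamily", function(object) {
  msgs <- character(0)
  if (length(object@familyId) != 1L || !nzchar(object@familyId)) {
    msgs <- c(msgs, "familyId must be a non-empty scalar")
  }
  need <- c("species", "superkingdom", "kingdom", "phylum")
  if (!all(need %in% names(object@carrierLineages))) {
    msgs <- c(msgs, "carrierLineages must have species/superkingdom/kingdom/phylum columns")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DomainFamily", function(object) {
  cat(sprintf("DomainFamily %s (%s): %d-residue consensus, %d carrier species, tags: %s\n",
              object@familyId, object@name, nchar(object@consensus),
              nrow(object@carrierLineages),
              paste(object@functionTags, collapse = ", ")))
  invisible(object)
})

#' A library of domain families
#'
#' Ordered collection of [DomainFamily] objects with unique identifiers;
#' the unit consumed by [scanDomains()] and [classifyDomainTaxonomy()].
#'
#' @slot families list of [DomainFamily].
#' @export
setClass("DomainLibrary", representation(families = "list"))

setValidity("DomainLibrary", function(object) {
  if (!all(vapply(object@families, is, logical(1), class2 = "DomainFamily"))) {
    return("all elements must be DomainFamily objects")
  }
  ids <- vapply(object@families, function(f) f@familyId, character(1))
  if (anyDuplicated(ids)) return("family ids must be unique within a library")
  TRUE
})

#' @rdname DomainLibrary-class
#' Family identifiers, in library order.
#' @param x,object A `DomainLibrary`.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname DomainLibrary-class
#' @export
setMethod("familyIds", "DomainLibrary", function(x) {
  vapply(x@families, function(f) f@familyId, character(1))
})

#' @rdname DomainLibrary-class
#' Retrieve one family by id.
#' @param id character scalar family identifier.
#' @export
setGeneric("getFamily", function(x, id) standardGeneric("getFamily"))

#' @rdname DomainLibrary-class
#' @export
setMethod("getFamily", "DomainLibrary", function(x, id) {
  i <- match(id, familyIds(x))
  if (is.na(i)) stop("no family with id '", id, "' in library", call. = FALSE)
  x@families[[i]]
})

setMethod("show", "DomainLibrary", function(object) {
  cat(sprintf("DomainLibrary with %d families: %s\n",
              length(object@families),
              paste(familyIds(object), collapse = ", ")))
  invisible(object)
})

setMethod("length", "DomainLibrary", function(x) length(x@families))

#' Result of an iterative profile search
#'
#' @slot hits data.frame with one row per target hit: `target_id`,
#'   `env_start`, `env_end` (0-based half-open), `bit_score`, `e_value`,
#'   `iteration_found`, `repeat_count`; sorted by ascending E-value.
#' @slot profiles list of [ProfileHMM], the profile used at each
#'   iteration (element 1 is the seed).
#' @slot repeatCounts named integer: non-overlapping module matches per
#'   hit protein (envelope-masking count).
#' @slot calibration list of Gumbel parameter lists, one per iteration.
#' @export
setClass("SearchResult",
  representation(
    hits = "data.frame",
    profiles = "list",
    repeatCounts = "integer",
    calibration = "list"
  )
)

setValidity("SearchResult", function(object) {
  h <- object@hits
  msgs <- character(0)
  need <- c("target_id", "env_start", "env_end", "bit_score", "e_value",
            "iteration_found", "repeat_count")
  if (!all(need %in% names(h))) {
    msgs <- c(msgs, "hits is missing required columns")
  } else {
    if (is.unsorted(h$e_value)) msgs <- c(msgs, "hits must be sorted by ascending e_value")
    if (any(h$e_value < 0)) msgs <- c(msgs, "e_value must be non-negative")
  }
  if (length(object@repeatCounts) && any(object@repeatCounts < 1L)) {
    msgs <- c(msgs, "repeat counts must be >= 1 for every hit protein")
  }
  if (length(msgs)) msgs else TRUE
})

#' @rdname SearchResult-class
#' Hit table (data.frame).
#' @param x,object A `SearchResult`.
#' @export
setGeneric("searchHits", function(x) standardGeneric("searchHits"))

#' @rdname SearchResult-class
#' @export
setMethod("searchHits", "SearchResult", function(x) x@hits)

#' @rdname SearchResult-class
#' Per-iteration profiles (list of [ProfileHMM]).
#' @export
setGeneric("iterationProfiles", function(x) standardGeneric("iterationProfiles"))

#' @rdname SearchResult-class
#' @export
setMethod("iterationProfiles", "SearchResult", function(x) x@profiles)

#' @rdname SearchResult-class
#' Per-protein repeat counts (named integer).
#' @export
setGeneric("repeatCounts", function(x) standardGeneric("repeatCounts"))

#' @rdname SearchResult-class
#' @export
setMethod("repeatCounts", "SearchResult", function(x) x@repeatCounts)

setMethod("show", "SearchResult", function(object) {
  cat(sprintf("SearchResult: %d hits over %d iteration(s)\n",
              nrow(object@hits), length(object@profiles)))
  if (nrow(object@hits)) {
    cat(sprintf("  E-value range: %.3g .. %.3g\n",
                min(object@hits$e_value), max(object@hits$e_value)))
  }
  invisible(object)
})
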