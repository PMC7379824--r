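## repeat_profile: split repeat regions into modules, build a profile HMM
## from a module alignment, and compute per-column logo statistics.

## ---- alignment handling ----------------------------------------------

## Coerce an alignment (AAStringSet / AAMultipleAlignment / character
## vector of gapped strings) to an upper-case character matrix, one row
## per sequence. Gap symbols '-' and '.' are normalised to '-'.
alignmentMatrix <- function(alignment) {
  if (is(alignment, "AAMultipleAlignment")) {
    alignment <- as.character(alignment)
  } else if (is(alignment, "XStringSet")) {
    alignment <- as.character(alignment)
  }
  stopIfNot(is.character(alignment) && length(alignment) >= 1L,
            "alignment must be a character vector, AAStringSet or AAMultipleAlignment")
  alignment <- toupper(alignment)
  widths <- nchar(alignment)
  stopIfNot(length(unique(widths)) == 1L,
            "all aligned rows must have identical length")
  m <- do.call(rbind, strsplit(alignment, ""))
  m[m == "."] <- "-"
  rownames(m) <- if (is.null(names(alignment))) {
    paste0("row", seq_len(nrow(m)))
  } else names(alignment)
  m
}

#' Read a module alignment from aligned FASTA
#'
#' @param path Path to an aligned FASTA file (gap symbol `-` or `.`).
#' @return Named character vector of aligned rows.
#' @export
readModuleAlignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

## ---- module splitting -------------------------------------------------

#' Split a repeat region into individual modules at given borders
#'
#' Cuts `sequence` at each border position (0-based, half-open
#' convention: a border at position `b` ends one module at `b` and starts
#' the next at `b`). With no borders the sequence is returned unchanged;
#' concatenating the returned modules reconstructs the input.
#'
#' @param sequence Character scalar, the repeat region.
#' @param borders Integer vector of cut positions, sorted strictly
#'   increasing, each strictly inside the sequence (`0 < b < nchar`).
#' @return Character vector of module strings.
#' @examples
#' splitRepeatPair("ABCDEF", 3) # "ABC" "DEF"
#' @export
splitRepeatPair <- function(sequence, borders = integer(0)) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L &&
              nchar(sequence) > 0L, "sequence must be a non-empty string")
  n <- nchar(sequence)
  borders <- as.integer(borders)
  if (length(borders)) {
    stopIfNot(!is.unsorted(borders, strictly = TRUE),
              "borders must be sorted strictly increasing")
    stopIfNot(all(borders > 0L & borders < n),
              "borders must lie strictly inside the sequence")
  }
  starts <- c(0L, borders)
  ends <- c(borders, n)
  substring(sequence, starts + 1L, ends)
}

#' Propose repeat-module intervals by iterative local self-alignment
#'
#' Detects internal repeats by Smith--Waterman alignment of the sequence
#' against itself with the main diagonal forbidden, extracting the best
#' off-diagonal local alignment, masking its footprint, and repeating
#' (Waterman--Eggert style) until no alignment reaches `min_score`.
#' Overlapping self-alignments (tandem arrays) are decomposed into
#' period-length modules; disjoint ones contribute both aligned copies.
#'
#' @param sequence Character scalar.
#' @param min_module_len Minimum module length to report (residues).
#' @param min_score Minimum Smith--Waterman score (BLOSUM62, gap open 11,
#'   extend 1) for a self-alignment to seed modules.
#' @param max_rounds Safety cap on extraction rounds.
#' @return data.frame with columns `start`, `end` (0-based half-open),
#'   sorted by `start`; zero rows when no repeat is found.
#' @export
proposeRepeatModules <- function(sequence, min_module_len = 15L,
                                 min_score = 40, max_rounds = 25L) {
  stopIfNot(is.character(sequence) && length(sequence) == 1L,
            "sequence must be a string")
  n <- nchar(sequence)
  empty <- data.frame(start = integer(0), end = integer(0))
  if (n < 2L * min_module_len) return(empty)
  codes <- encodeResidues(sequence)
  sub <- blosumScoreMatrix()
  mask <- rep(FALSE, n)
  cand <- list()
  for (round in seq_len(max_rounds)) {
    al <- cpp_sw_self(codes, sub, 11, 1, mask)
    if (al$score < min_score) break
    qs <- al$q_start; qe <- al$q_end; ss <- al$s_start; se <- al$s_end
    d <- ss - qs
    if (qe > ss && d >= min_module_len) {
      # tandem: cut the union region into period-d modules
      pos <- qs
      while (pos + d <= se) {
        cand[[length(cand) + 1L]] <- c(pos, pos + d)
        pos <- pos + d
      }
    } else {
      cand[[length(cand) + 1L]] <- c(qs, qe)
      cand[[length(cand) + 1L]] <- c(ss, se)
    }
    mask[(qs + 1L):qe] <- TRUE
    mask[(ss + 1L):se] <- TRUE
  }
  if (!length(cand)) return(empty)
  ivs <- do.call(rbind, cand)
  ivs <- ivs[(ivs[, 2] - ivs[, 1]) >= min_module_len, , drop = FALSE]
  if (!nrow(ivs)) return(empty)
  ivs <- ivs[order(ivs[, 1], ivs[, 2]), , drop = FALSE]
  keep <- rep(TRUE, nrow(ivs))
  last_end <- -1L
  for (k in seq_len(nrow(ivs))) {
    if (ivs[k, 1] < last_end) keep[k] <- FALSE else last_end <- ivs[k, 2]
  }
  ivs <- ivs[keep, , drop = FALSE]
  data.frame(start = as.integer(ivs[, 1]), end = as.integer(ivs[, 2]))
}

## BLOSUM62 extended to the internal 22-code alphabet (unknown scores 0
## against everything; the masked code is handled by the mask argument).
blosumScoreMatrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  m <- matrix(0, 22L, 22L)
  m[1:20, 1:20] <- b62[AA_ALPHABET20, AA_ALPHABET20]
  m
}

## ---- profile construction --------------------------------------------

## Shared estimator used by buildProfile() and by iterative-search profile
## re-estimation (which forces every column to be a match state to keep
## model length fixed). Returns a validated ProfileHMM.
estimateProfile <- function(alnmat, match_cols, pseudocount_weight,
                            background, exit_prob = 0.1) {
  L <- length(match_cols)
  ncolaln <- ncol(alnmat)
  nrows <- nrow(alnmat)
  w <- pseudocount_weight

  residCount <- function(chars) {
    idx <- match(chars, AA_ALPHABET20)
    tabulate(idx[!is.na(idx)], nbins = 20L)
  }

  matchEmis <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET20))
  insEmis <- matrix(rep(background, each = L), L, 20L,
                    dimnames = list(NULL, AA_ALPHABET20))
  for (j in seq_len(L)) {
    cnt <- residCount(alnmat[, match_cols[j]])
    matchEmis[j, ] <- (cnt + w * background) / (sum(cnt) + w)
  }
  # insert emissions from residues in non-match columns after match col j
  bounds <- c(match_cols, ncolaln + 1L)
  for (j in seq_len(L - 1L)) {
    cols <- setdiff(seq.int(match_cols[j] + 1L, bounds[j + 1L] - 1L),
                    match_cols)
    cols <- cols[cols >= 1 & cols <= ncolaln]
    cnt <- if (length(cols)) residCount(as.vector(alnmat[, cols])) else
      integer(20L)
    insEmis[j, ] <- (cnt + w * background) / (sum(cnt) + w)
  }

  # transition counts from per-row gap patterns over match columns
  cMM <- cMI <- cMD <- numeric(L); cIM <- cII <- numeric(L)
  cDM <- cDD <- numeric(L)
  for (r in seq_len(nrows)) {
    isres <- alnmat[r, ] != "-"
    state <- ifelse(isres[match_cols], "M", "D")
    for (j in seq_len(L - 1L)) {
      between <- setdiff(seq.int(match_cols[j] + 1L, match_cols[j + 1L] - 1L),
                         match_cols)
      k <- if (length(between)) sum(isres[between]) else 0L
      p <- state[j]; nx <- state[j + 1L]
      if (k > 0L && p == "M" && nx == "M") {
        cMI[j] <- cMI[j] + 1
        cII[j] <- cII[j] + (k - 1L)
        cIM[j] <- cIM[j] + 1
      } else {
        # inserts flanked by deletions have no legal path; count direct
        if (p == "M" && nx == "M") cMM[j] <- cMM[j] + 1
        if (p == "M" && nx == "D") cMD[j] <- cMD[j] + 1
        if (p == "D" && nx == "M") cDM[j] <- cDM[j] + 1
        if (p == "D" && nx == "D") cDD[j] <- cDD[j] + 1
      }
    }
  }

  transM <- matrix(0, L, 4L, dimnames = list(NULL, c("mm", "mi", "md", "me")))
  transI <- matrix(0, L, 2L, dimnames = list(NULL, c("im", "ii")))
  transD <- matrix(0, L, 2L, dimnames = list(NULL, c("dm", "dd")))
  for (j in seq_len(L)) {
    if (j < L) {
      core <- c(cMM[j], cMI[j], cMD[j]) + w / 3
      core <- core / sum(core)
      transM[j, ] <- c(core * (1 - exit_prob), exit_prob)
      ins <- c(cIM[j], cII[j]) + w / 2
      transI[j, ] <- ins / sum(ins)
      del <- c(cDM[j], cDD[j]) + w / 2
      transD[j, ] <- del / sum(del)
    } else {
      transM[j, ] <- c(0, 0, 0, 1)
      transI[j, ] <- c(1, 0)
      transD[j, ] <- c(1, 0)
    }
  }
  if (L >= 2L) transD[L, ] <- c(1, 0)  # D_L exits; row unused by topology

  consensus <- paste0(AA_ALPHABET20[apply(matchEmis, 1, which.max)],
                      collapse = "")
  obj <- new("ProfileHMM",
             matchEmis = matchEmis, insEmis = insEmis,
             entry = rep(1 / L, L), transM = transM, transI = transI,
             transD = transD, background = background,
             consensus = consensus)
  validObject(obj)
  obj
}

#' Build a local profile HMM from a module alignment
#'
#' Columns whose occupancy (fraction of rows with a residue) reaches
#' `match_occ` become match states; the remaining columns feed the insert
#' states between them. Emission probabilities are background-weighted
#' pseudocount mixtures, `(count + w * background) / (n + w)`, and
#' transitions are estimated from the per-row gap patterns with the same
#' pseudocount rule (uniform prior over each state's legal transitions).
#' Local entry is uniform over match states; every match state carries an
#' exit probability `exit_prob` (the last one exits with probability 1).
#'
#' @param alignment Aligned rows: character vector, `AAStringSet` or
#'   `AAMultipleAlignment`; at least 2 rows of identical length.
#' @param match_occ Occupancy threshold in (0, 1] for match columns.
#' @param pseudocount Background-mixing pseudocount weight (>= 0).
#' @param background Length-20 background frequencies.
#' @param exit_prob Per-match-state local exit probability.
#' @return A [ProfileHMM].
#' @examples
#' buildProfile(c("CAC", "C-C", "CTC"))
#' @export
buildProfile <- function(alignment, match_occ = 0.5, pseudocount = 1.0,
                         background = BACKGROUND_FREQS, exit_prob = 0.1) {
  m <- alignmentMatrix(alignment)
  stopIfNot(nrow(m) >= 2L, "profile construction needs at least 2 rows")
  stopIfNot(match_occ > 0 && match_occ <= 1,
            "match_occ must be in (0, 1]")
  stopIfNot(pseudocount >= 0, "pseudocount must be non-negative")
  background <- background / sum(background)
  occ <- colMeans(m != "-")
  match_cols <- which(occ >= match_occ)
  if (!length(match_cols)) {
    stop("no column reaches the match occupancy threshold; ",
         "the alignment is too gappy to build a profile", call. = FALSE)
  }
  prof <- estimateProfile(m, match_cols, pseudocount, background, exit_prob)
  attr(prof, "match_cols") <- match_cols
  prof
}

## ---- column statistics ------------------------------------------------

#' Per-column logo statistics of a profile and its alignment
#'
#' For every match column: the information content in bits (relative
#' entropy of the match emission against the background), the column
#' occupancy, the probability of entering the following insert state, and
#' the expected insert length `1 / (1 - p_II)` of that insert state's
#' geometric length distribution.
#'
#' @param alignment The alignment the profile was built from.
#' @param profile The [ProfileHMM] built from it (via [buildProfile()]).
#' @return data.frame with one row per match state: `column` (1-based
#'   alignment column), `information_content`, `occupancy`,
#'   `insert_probability`, `expected_insert_length`.
#' @export
columnStats <- function(alignment, profile) {
  m <- alignmentMatrix(alignment)
  match_cols <- attr(profile, "match_cols")
  if (is.null(match_cols)) {
    stopIfNot(ncol(m) == nMatch(profile),
              "profile was not built from this alignment")
    match_cols <- seq_len(ncol(m))
  }
  L <- nMatch(profile)
  bg <- backgroundFreqs(profile)
  me <- matchEmissions(profile)
  info <- vapply(seq_len(L), function(j) {
    p <- me[j, ]
    sum(ifelse(p > 0, p * log2(p / bg), 0))
  }, numeric(1))
  occ <- colMeans(m[, match_cols, drop = FALSE] != "-")
  ip <- profile@transM[, "mi"]
  ii <- profile@transI[, "ii"]
  eil <- ifelse(seq_len(L) < L, 1 / (1 - ii), 0)
  data.frame(
    column = as.integer(match_cols),
    information_content = pmax(info, 0),
    occupancy = occ,
    insert_probability = ip,
    expected_insert_length = eil
  )
}

#' Write column statistics to TSV
#'
#' @param stats data.frame from [columnStats()].
#' @param path Output path.
#' @export
writeColumnStats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ---- profile serialisation -------------------------------------------

#' Write a profile HMM to a versioned JSON file
#'
#' All probabilities are written explicitly at full precision; a
#' read-back reproduces the model to better than 1e-12.
#'
#' @param profile A [ProfileHMM].
#' @param path Output path.
#' @export
writeProfile <- function(profile, path) {
  stopIfNot(is(profile, "ProfileHMM"), "profile must be a ProfileHMM")
  obj <- list(
    format = "crrscreen-profile",
    version = 1L,
    alphabet = paste0(AA_ALPHABET20, collapse = ""),
    n_match = nMatch(profile),
    consensus = profile@consensus,
    background = unname(profile@background),
    match_emissions = unname(apply(profile@matchEmis, 1, identity,
                                   simplify = FALSE)),
    insert_emissions = unname(apply(profile@insEmis, 1, identity,
                                    simplify = FALSE)),
    entry = unname(profile@entry),
    trans_m = unname(apply(profile@transM, 1, identity, simplify = FALSE)),
    trans_i = unname(apply(profile@transI, 1, identity, simplify = FALSE)),
    trans_d = unname(apply(profile@transD, 1, identity, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a profile HMM from JSON
#'
#' @param path Path written by [writeProfile()].
#' @return A [ProfileHMM].
#' @export
readProfile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopIfNot(identical(obj$format, "crrscreen-profile"),
            "not a profile JSON file")
  L <- as.integer(obj$n_match)
  asMat <- function(x, nc, cn) {
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    stopIfNot(nrow(m) == L && ncol(m) == nc, "malformed profile matrix")
    dimnames(m) <- list(NULL, cn)
    m
  }
  prof <- new("ProfileHMM",
              matchEmis = asMat(obj$match_emissions, 20L, AA_ALPHABET20),
              insEmis = asMat(obj$insert_emissions, 20L, AA_ALPHABET20),
              entry = as.numeric(obj$entry),
              transM = asMat(obj$trans_m, 4L, c("mm", "mi", "md", "me")),
              transI = asMat(obj$trans_i, 2L, c("im", "ii")),
              transD = asMat(obj$trans_d, 2L, c("dm", "dd")),
              background = as.numeric(obj$background),
              consensus = obj$consensus)
  validObject(prof)
  prof
}
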