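## hmm_search: Viterbi/forward scoring of a profile HMM against protein
## databases, Gumbel E-value calibration on shuffled decoys, and the
## iterative (jackhmmer-style) search with profile re-estimation.

## Precompute log2 scoring tables for the DP core. Emission log-odds get
## two extra columns: code 21 (unknown residue) scores 0 bits, code 22
## (masked) scores -Inf for both match and insert states.
profileScoringTables <- function(profile) {
  L <- nMatch(profile)
  bg <- profile@background
  lo <- function(emis) {
    m <- log2(sweep(emis, 2, bg, "/"))
    cbind(m, rep(0, L), rep(-Inf, L))
  }
  pad <- function(x, fill = -Inf) {
    out <- rep(fill, L); out[seq_along(x)] <- x; out
  }
  tm <- profile@transM; ti <- profile@transI; td <- profile@transD
  last <- function(v) { v[L] <- -Inf; v }
  ldm <- ldd <- rep(-Inf, L)
  if (L > 2L) {
    idx <- 2:(L - 1L)
    ldm[idx] <- log2(td[idx, "dm"])
    ldd[idx] <- log2(td[idx, "dd"])
  }
  list(
    mlo = lo(profile@matchEmis),
    ilo = lo(profile@insEmis),
    entry = log2(profile@entry),
    lmm = last(log2(tm[, "mm"])),
    lmi = last(log2(tm[, "mi"])),
    lmd = last(log2(tm[, "md"])),
    lme = log2(tm[, "me"]),
    lim = last(log2(ti[, "im"])),
    lii = last(log2(ti[, "ii"])),
    ldm = ldm,
    ldd = ldd
  )
}

.asCodes <- function(sequence) {
  if (is.character(sequence)) {
    stopIfNot(length(sequence) == 1L, "one sequence at a time")
    stopIfNot(nzchar(sequence), "sequence must be non-empty")
    encodeResidues(sequence)
  } else {
    codes <- as.integer(sequence)
    stopIfNot(length(codes) > 0L, "sequence must be non-empty")
    codes
  }
}

#' Viterbi score of a profile against one sequence
#'
#' Computes the best local alignment of the profile to the sequence: the
#' bit score is the base-2 log-odds of the highest-probability state path
#' against the background (null) model, with flanking residues emitted by
#' the null model at zero cost. Ties are broken deterministically
#' (match > delete > insert).
#'
#' @param profile A [ProfileHMM].
#' @param sequence Character scalar, or an integer code vector as
#'   produced internally (codes 1-20 residues, 21 unknown, 22 masked).
#' @param tables Optional precomputed scoring tables (internal reuse).
#' @return list with `bit_score` (bits), `path` (matrix of state type
#'   1=M/2=I/3=D, profile index, 1-based sequence position), and
#'   `envelope` (0-based half-open interval on the target).
#' @export
viterbiScore <- function(profile, sequence, tables = NULL) {
  codes <- .asCodes(sequence)
  t <- if (is.null(tables)) profileScoringTables(profile) else tables
  r <- cpp_viterbi(t$mlo, t$ilo, t$entry, t$lmm, t$lmi, t$lmd, t$lme,
                   t$lim, t$lii, t$ldm, t$ldd, codes)
  list(bit_score = r$bit_score, path = r$path,
       envelope = c(start = r$env_start, end = r$env_end))
}

#' Forward score of a profile against one sequence
#'
#' As [viterbiScore()] but summing probability over all local alignments
#' (all entry points, paths and start positions) in log space; the
#' forward bit score is therefore always >= the Viterbi bit score.
#'
#' @inheritParams viterbiScore
#' @return Bit score (numeric scalar).
#' @export
forwardScore <- function(profile, sequence, tables = NULL) {
  codes <- .asCodes(sequence)
  t <- if (is.null(tables)) profileScoringTables(profile) else tables
  cpp_forward(t$mlo, t$ilo, t$entry, t$lmm, t$lmi, t$lmd, t$lme,
              t$lim, t$lii, t$ldm, t$ldd, codes)
}

## Extract the match-state-aligned row of a Viterbi path: one character
## per match state (the emitted residue, or '-' if deleted or outside the
## local alignment). Insertions are dropped, keeping model length fixed
## across search iterations.
matchAlignedRow <- function(path, codes, n_match) {
  row <- rep("-", n_match)
  if (nrow(path)) {
    m <- path[path[, 1] == 1L, , drop = FALSE]
    row[m[, 2]] <- AA_ALPHABET20[pmin(codes[m[, 3]], 20L)]
    unk <- codes[m[, 3]] > 20L
    if (any(unk)) row[m[unk, 2]] <- "-"
  }
  paste0(row, collapse = "")
}

## ---- E-value calibration ---------------------------------------------

#' Fit a Gumbel distribution by the method of moments
#'
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with
#' `gamma` the Euler--Mascheroni constant.
#'
#' @param scores Numeric vector of (decoy) bit scores.
#' @return list with `mu`, `lambda`, `n_decoys`.
#' @export
fitGumbelMoments <- function(scores) {
  scores <- scores[is.finite(scores)]
  stopIfNot(length(scores) >= 2L, "need at least two finite scores")
  s <- stats::sd(scores)
  if (s == 0) stop("zero score variance; cannot calibrate", call. = FALSE)
  lambda <- pi / (s * sqrt(6))
  mu <- mean(scores) - EULER_GAMMA / lambda
  list(mu = mu, lambda = lambda, n_decoys = length(scores))
}

#' Calibrate E-value parameters on background decoys
#'
#' Samples `n_decoys` i.i.d. background sequences (lengths drawn with
#' replacement from `decoy_lengths`, typically the real database's length
#' distribution), scores them, and fits a Gumbel null distribution by the
#' method of moments. The default statistic is the Viterbi bit score:
#' null maximum scores follow a Gumbel law by extreme-value theory, so
#' the moment fit extrapolates faithfully into the significance tail
#' (forward scores are also supported but their null bulk is narrower
#' than their tail, making the fitted tail anticonservative).
#' Deterministic for a given seed.
#'
#' @param profile A [ProfileHMM].
#' @param n_decoys Number of decoy sequences (>= 100).
#' @param decoy_lengths Integer vector of lengths to resample from.
#' @param seed Integer seed.
#' @param statistic Score used for fitting: `"viterbi"` (default) or
#'   `"forward"`.
#' @return list with `mu`, `lambda`, `n_decoys`.
#' @export
calibrateEvalues <- function(profile, n_decoys = 200L, decoy_lengths = 300L,
                             seed = 1L,
                             statistic = c("viterbi", "forward")) {
  stopIfNot(n_decoys >= 100L, "n_decoys must be >= 100")
  statistic <- match.arg(statistic)
  tables <- profileScoringTables(profile)
  bg <- profile@background
  scoreOne <- if (statistic == "viterbi") {
    function(codes) viterbiScore(profile, codes, tables = tables)$bit_score
  } else {
    function(codes) forwardScore(profile, codes, tables = tables)
  }
  scores <- withSeed(seed, {
    lens <- sample(rep_len(as.integer(decoy_lengths), n_decoys),
                   n_decoys, replace = TRUE)
    vapply(lens, function(n) {
      scoreOne(sample.int(20L, n, replace = TRUE, prob = bg))
    }, numeric(1))
  })
  fitGumbelMoments(scores)
}

#' Convert a bit score to an E-value
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (score - mu))))`: the expected
#' number of database sequences reaching the score under the calibrated
#' Gumbel null. Strictly decreasing in the bit score.
#'
#' @param bit_score Numeric (vectorised).
#' @param params Gumbel parameters from [calibrateEvalues()] or
#'   [fitGumbelMoments()].
#' @param db_size Number of sequences searched (>= 1).
#' @return E-values (numeric).
#' @export
scoreToEvalue <- function(bit_score, params, db_size = 1) {
  stopIfNot(db_size >= 1, "db_size must be >= 1")
  stopIfNot(params$lambda > 0, "lambda must be positive")
  p <- -expm1(-exp(-params$lambda * (bit_score - params$mu)))
  pmax(db_size * p, 0)
}

## ---- iterative search -------------------------------------------------

.asStringDb <- function(database) {
  if (is(database, "XStringSet")) {
    out <- as.character(database)
    names(out) <- sub("\\s.*$", "", names(database))
    out
  } else {
    stopIfNot(is.character(database), "database must be sequences")
    if (length(database) && is.null(names(database))) {
      names(database) <- paste0("seq", seq_along(database))
    }
    database
  }
}

#' Iterative profile search of a protein database
#'
#' Jackhmmer-style search: the seed profile is scored (Viterbi bit
#' score) against every target; targets with E-value <= `inclusion_e`
#' are included; the
#' match-state-aligned residues of the included hits' Viterbi alignments
#' form a new alignment from which the profile is re-estimated (model
#' length fixed, insertions dropped) and the search repeats, stopping
#' after `iterations` rounds or when the included set stops changing.
#' E-values are calibrated per iteration on background decoys whose
#' lengths resample the database's length distribution. Per-protein
#' repeat counts are obtained with the final profile by envelope masking:
#' the best hit's envelope is masked and the target rescanned until the
#' score drops below the inclusion threshold.
#'
#' @param profile Seed [ProfileHMM].
#' @param database Named character vector or `AAStringSet`.
#' @param iterations Maximum refinement rounds (>= 1; default 3).
#' @param inclusion_e Inclusion E-value threshold (default 0.01).
#' @param n_decoys Decoys per calibration.
#' @param pseudocount Pseudocount weight for profile re-estimation.
#' @param seed Integer seed (governs decoy sampling).
#' @return A [SearchResult].
#' @export
iterativeSearch <- function(profile, database, iterations = 3L,
                            inclusion_e = 0.01, n_decoys = 200L,
                            pseudocount = 1.0, seed = 1L) {
  stopIfNot(iterations >= 1L, "iterations must be >= 1")
  stopIfNot(inclusion_e > 0, "inclusion_e must be positive")
  db <- .asStringDb(database)
  if (!length(db)) stop("empty database", call. = FALSE)
  ids <- names(db)
  codes <- lapply(db, encodeResidues)
  lens <- lengths(codes)
  dbsize <- length(db)
  L <- nMatch(profile)

  profiles <- list(profile)
  calib <- list()
  iter_found <- setNames(rep(NA_integer_, dbsize), ids)
  prev_included <- NULL
  vits <- NULL; evals <- NULL; included <- NULL
  cur <- profile

  for (it in seq_len(iterations)) {
    tables <- profileScoringTables(cur)
    params <- calibrateEvalues(cur, n_decoys = n_decoys,
                               decoy_lengths = lens,
                               seed = splitSeed(seed, it))
    calib[[it]] <- params
    vits <- lapply(codes, function(x) viterbiScore(cur, x, tables = tables))
    scores <- vapply(vits, `[[`, numeric(1), "bit_score")
    evals <- scoreToEvalue(scores, params, dbsize)
    included <- which(evals <= inclusion_e)
    newly <- included[is.na(iter_found[included])]
    iter_found[newly] <- it
    if (!length(included)) {
      if (it == 1L) {
        warning("no target passed the inclusion threshold at iteration 1")
        empty <- data.frame(target_id = character(0), env_start = integer(0),
                            env_end = integer(0), bit_score = numeric(0),
                            e_value = numeric(0), iteration_found = integer(0),
                            repeat_count = integer(0))
        return(new("SearchResult", hits = empty, profiles = profiles,
                   repeatCounts = integer(0), calibration = calib))
      }
      break
    }
    if (!is.null(prev_included) && identical(included, prev_included)) break
    prev_included <- included
    if (it < iterations) {
      rows <- vapply(included, function(i) {
        matchAlignedRow(vits[[i]]$path, codes[[i]], L)
      }, character(1))
      alnmat <- do.call(rbind, strsplit(rows, ""))
      cur <- estimateProfile(alnmat, seq_len(L), pseudocount,
                             profile@background)
      profiles[[it + 1L]] <- cur
    }
  }

  final <- profiles[[length(profiles)]]
  ftab <- profileScoringTables(final)
  fparams <- calib[[length(calib)]]

  env <- matrix(NA_integer_, length(included), 2L)
  rc <- integer(length(included))
  for (k in seq_along(included)) {
    i <- included[k]
    env[k, ] <- vits[[i]]$envelope
    rc[k] <- countRepeatModules(final, codes[[i]], fparams, dbsize,
                                inclusion_e, tables = ftab)
  }

  hits <- data.frame(
    target_id = ids[included],
    env_start = env[, 1], env_end = env[, 2],
    bit_score = vapply(vits[included], `[[`, numeric(1), "bit_score"),
    e_value = evals[included],
    iteration_found = iter_found[included],
    repeat_count = rc,
    row.names = NULL
  )
  hits <- hits[order(hits$e_value, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  res <- new("SearchResult", hits = hits, profiles = profiles,
             repeatCounts = setNames(as.integer(rc), ids[included]),
             calibration = calib)
  validObject(res)
  res
}

## Count non-overlapping module matches on one target by envelope
## masking: score, mask the best envelope, rescan, until the E-value
## exceeds the inclusion threshold.
countRepeatModules <- function(profile, codes, params, db_size,
                               inclusion_e, tables = NULL, max_hits = 100L) {
  if (is.null(tables)) tables <- profileScoringTables(profile)
  count <- 0L
  cur <- codes
  for (k in seq_len(max_hits)) {
    v <- cpp_viterbi(tables$mlo, tables$ilo, tables$entry, tables$lmm,
                     tables$lmi, tables$lmd, tables$lme, tables$lim,
                     tables$lii, tables$ldm, tables$ldd, cur)
    if (!is.finite(v$bit_score)) break
    if (scoreToEvalue(v$bit_score, params, db_size) > inclusion_e) break
    count <- count + 1L
    cur[(v$env_start + 1L):v$env_end] <- AA_MASK_CODE
  }
  count
}

## ---- hits I/O ---------------------------------------------------------

#' Write a search hit table to TSV
#'
#' Coordinates are converted to the 1-based inclusive file convention.
#'
#' @param result A [SearchResult] or its hits data.frame.
#' @param path Output path.
#' @export
writeHits <- function(result, path) {
  h <- if (is(result, "SearchResult")) searchHits(result) else result
  out <- data.frame(
    target_id = h$target_id,
    env_start = h$env_start + 1L,
    env_end = h$env_end,
    bit_score = h$bit_score,
    e_value = h$e_value,
    iteration = h$iteration_found,
    repeat_count = h$repeat_count
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a search hit table written by [writeHits()]
#'
#' @param path TSV path.
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
readHits <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("target_id", "env_start", "env_end", "bit_score", "e_value",
            "iteration", "repeat_count")
  stopIfNot(all(need %in% names(h)), "hit table is missing columns")
  data.frame(
    target_id = as.character(h$target_id),
    env_start = as.integer(h$env_start) - 1L,
    env_end = as.integer(h$env_end),
    bit_score = h$bit_score,
    e_value = h$e_value,
    iteration_found = as.integer(h$iteration),
    repeat_count = as.integer(h$repeat_count)
  )
}
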