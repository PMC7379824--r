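# Independent oracles and fixture builders shared across the suite.
# The oracles deliberately re-derive quantities by enumeration or closed
# form, never by calling the code paths they check.

# ---- profile fixtures --------------------------------------------------

# Single-match-state profile emitting one residue with probability ~1.
toyProfile <- function(residue = "C", background = rep(1 / 20, 20)) {
  me <- matrix(0, 1, 20, dimnames = list(NULL, AA_ALPHABET20))
  me[1, residue] <- 1
  new("ProfileHMM",
      matchEmis = me,
      insEmis = matrix(background, 1, 20, byrow = TRUE,
                       dimnames = list(NULL, AA_ALPHABET20)),
      entry = 1,
      transM = matrix(c(0, 0, 0, 1), 1, 4,
                      dimnames = list(NULL, c("mm", "mi", "md", "me"))),
      transI = matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("im", "ii"))),
      transD = matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("dm", "dd"))),
      background = background, consensus = residue)
}

# Random valid profile with L match states (arbitrary entry distribution,
# random emissions and transitions) for property-based comparisons.
randomProfile <- function(L) {
  norm <- function(m) m / rowSums(m)
  me <- norm(matrix(rexp(L * 20), L, 20,
                    dimnames = list(NULL, AA_ALPHABET20)))
  ie <- norm(matrix(rexp(L * 20), L, 20,
                    dimnames = list(NULL, AA_ALPHABET20)))
  tm <- matrix(0, L, 4, dimnames = list(NULL, c("mm", "mi", "md", "me")))
  ti <- matrix(0, L, 2, dimnames = list(NULL, c("im", "ii")))
  td <- matrix(0, L, 2, dimnames = list(NULL, c("dm", "dd")))
  for (j in seq_len(L)) {
    if (j < L) {
      core <- runif(3, 0.05, 1)
      exitp <- runif(1, 0.05, 0.4)
      tm[j, ] <- c(core / sum(core) * (1 - exitp), exitp)
      p <- runif(1, 0.1, 0.9); ti[j, ] <- c(p, 1 - p)
      q <- runif(1, 0.1, 0.9); td[j, ] <- c(q, 1 - q)
    } else {
      tm[j, ] <- c(0, 0, 0, 1); ti[j, ] <- c(1, 0); td[j, ] <- c(1, 0)
    }
  }
  if (L >= 2) td[L, ] <- c(1, 0)
  entry <- runif(L, 0.1, 1); entry <- entry / sum(entry)
  bg <- rexp(20); bg <- bg / sum(bg)
  new("ProfileHMM", matchEmis = me, insEmis = ie, entry = entry,
      transM = tm, transI = ti, transD = td, background = bg,
      consensus = paste0(AA_ALPHABET20[apply(me, 1, which.max)],
                         collapse = ""))
}

randomSeq <- function(n) {
  paste0(sample(AA_ALPHABET20, n, replace = TRUE), collapse = "")
}

# ---- path-enumeration oracle ------------------------------------------
# Enumerates every legal local path (entry position x entry state x state
# sequence) and returns the log2-odds score of each complete path. The
# Viterbi oracle is the max, the forward oracle the log2-sum-exp.

enumPathScores <- function(prof, seq_str) {
  codes <- match(strsplit(seq_str, "")[[1]], AA_ALPHABET20)
  n <- length(codes)
  L <- nMatch(prof)
  bg <- prof@background
  mlo <- log2(sweep(prof@matchEmis, 2, bg, "/"))
  ilo <- log2(sweep(prof@insEmis, 2, bg, "/"))
  tm <- prof@transM; ti <- prof@transI; td <- prof@transD
  scores <- new.env()
  scores$v <- numeric(0)
  emit <- function(x) scores$v <- c(scores$v, x)

  visitM <- function(j, i, acc) {
    acc <- acc + mlo[j, codes[i]]
    if (!is.finite(acc)) return(invisible(NULL))
    if (tm[j, "me"] > 0) emit(acc + log2(tm[j, "me"]))
    if (j < L) {
      if (i < n && tm[j, "mm"] > 0) visitM(j + 1, i + 1,
                                           acc + log2(tm[j, "mm"]))
      if (i < n && tm[j, "mi"] > 0) visitI(j, i + 1, acc + log2(tm[j, "mi"]))
      if (tm[j, "md"] > 0) visitD(j + 1, i, acc + log2(tm[j, "md"]))
    }
  }
  visitI <- function(j, i, acc) {
    acc <- acc + ilo[j, codes[i]]
    if (!is.finite(acc)) return(invisible(NULL))
    if (i < n) {
      if (ti[j, "im"] > 0) visitM(j + 1, i + 1, acc + log2(ti[j, "im"]))
      if (ti[j, "ii"] > 0) visitI(j, i + 1, acc + log2(ti[j, "ii"]))
    }
  }
  visitD <- function(j, i, acc) {
    if (j == L) { emit(acc); return(invisible(NULL)) }
    if (i < n && td[j, "dm"] > 0) visitM(j + 1, i + 1,
                                         acc + log2(td[j, "dm"]))
    if (td[j, "dd"] > 0) visitD(j + 1, i, acc + log2(td[j, "dd"]))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(L)) {
      if (prof@entry[j] > 0) visitM(j, i, log2(prof@entry[j]))
    }
  }
  scores$v
}

log2sumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

# ---- exhaustive local-alignment oracle --------------------------------
# Best local alignment score over all alignments: memoised recursion over
# (position, position, last-column type), affine gaps costing
# open + k * extend for a length-k gap. Independent of the Biostrings
# aligner used by the implementation.

swOracle <- function(a, b, open = 11, ext = 1) {
  b62 <- local({
    data("BLOSUM62", package = "Biostrings", envir = environment())
    get("BLOSUM62", envir = environment())
  })
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  M <- matrix(-Inf, na + 1, nb + 1)
  E <- matrix(-Inf, na + 1, nb + 1)  # gap consuming b
  F <- matrix(-Inf, na + 1, nb + 1)  # gap consuming a
  best <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      s <- b62[ca[i], cb[j]]
      M[i + 1, j + 1] <- s + max(0, M[i, j], E[i, j], F[i, j])
      E[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, E[i + 1, j] - ext)
      F[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, F[i, j + 1] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# ---- overlap-resolution oracle ----------------------------------------
# Greedy-equivalent solution found by exhaustive subset search: among all
# pairwise non-overlapping subsets, the one whose membership indicator in
# priority order (ascending e-value, descending bit score, ascending
# start) is lexicographically largest.

resolveOracle <- function(ann) {
  n <- nrow(ann)
  ord <- order(ann$e_value, -ann$bit_score, ann$start, ann$family_id)
  a <- ann[ord, , drop = FALSE]
  compatible <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    for (x in seq_along(idx)) for (y in seq_len(x - 1)) {
      i <- idx[x]; j <- idx[y]
      if (a$protein_id[i] == a$protein_id[j] &&
          a$start[i] < a$end[j] && a$end[i] > a$start[j]) return(FALSE)
    }
    TRUE
  }
  best <- NULL; bestkey <- NULL
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!compatible(idx)) next
    key <- as.integer(seq_len(n) %in% idx)
    if (is.null(bestkey) ||
        (function(k1, k2) {
          d <- which(k1 != k2)
          length(d) > 0 && k1[d[1]] > k2[d[1]]
        })(key, bestkey)) {
      best <- idx; bestkey <- key
    }
  }
  a[best, , drop = FALSE]
}

# ---- misc --------------------------------------------------------------

rGumbel <- function(n, mu, lambda) mu - log(-log(runif(n))) / lambda

smallConfig <- function(...) {
  args <- list(n_background = 20L, n_repeat_proteins = 6L, n_chimeric = 2L)
  override <- list(...)
  args[names(override)] <- override
  do.call(syntheticConfig, args)
}

makeCarriers <- function(n_prok, n_euk) {
  rbind(
    if (n_prok > 0) data.frame(
      species = paste0("bact", seq_len(n_prok)), superkingdom = "Bacteria",
      kingdom = "", phylum = "Firmicutes") else NULL,
    if (n_euk > 0) data.frame(
      species = paste0("euk", seq_len(n_euk)), superkingdom = "Eukaryota",
      kingdom = "Fungi", phylum = "Ascomycota") else NULL)
}

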