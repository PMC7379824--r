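## hgt_screen: taxonomic-bias and function classification of domain
## families, per-domain ancestry via nearest cross-superkingdom homologs,
## HGT candidate / chimera calling, and aggregate statistics.

#' Classify a domain family by taxonomic bias of its carriers
#'
#' Computes the fraction of unique carrier species belonging to Bacteria,
#' Archaea or Viruses; the family is labelled `prokaryote_phage_typical`
#' iff that fraction strictly exceeds 3/4 (so exactly three quarters is
#' `unbiased`), otherwise `unbiased`.
#'
#' @param family A [DomainFamily] (or a data.frame of carrier lineages).
#' @return list with `family_id`, `prokaryote_virus_fraction`, `label`.
#' @export
classifyDomainTaxonomy <- function(family) {
  if (is(family, "DomainFamily")) {
    carriers <- family@carrierLineages
    fid <- family@familyId
  } else {
    carriers <- family
    fid <- NA_character_
  }
  if (is.null(carriers) || !nrow(carriers)) {
    stop("family ", fid, " has no carrier species; cannot classify",
         call. = FALSE)
  }
  u <- carriers[!duplicated(carriers$species), , drop = FALSE]
  frac <- mean(u$superkingdom %in% c("Bacteria", "Archaea", "Viruses"))
  list(family_id = fid,
       prokaryote_virus_fraction = frac,
       label = if (frac > 0.75) "prokaryote_phage_typical" else "unbiased")
}

#' Classify every family of a library
#'
#' @param library A [DomainLibrary].
#' @return data.frame with one row per family: `family_id`,
#'   `prokaryote_virus_fraction`, `label`, `cell_wall_hydrolase`, `note`.
#' @export
classifyLibrary <- function(library) {
  rows <- lapply(library@families, function(f) {
    tx <- classifyDomainTaxonomy(f)
    fn <- classifyFunction(f)
    data.frame(family_id = tx$family_id,
               prokaryote_virus_fraction = tx$prokaryote_virus_fraction,
               label = tx$label,
               cell_wall_hydrolase = fn$cell_wall_hydrolase,
               note = fn$note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag cell-wall hydrolase function of a family
#'
#' A family is flagged as a cell-wall hydrolase when any of its function
#' tags (or an explicit vocabulary entry for its id) denotes a
#' peptidoglycan-degrading activity: lysozymes, peptidoglycan amidases,
#' lysozyme-superfamily glycoside hydrolases, or the explicit
#' `cell_wall_hydrolase` tag. Untagged families are flagged `FALSE` with
#' the note `"unknown"`.
#'
#' @param family A [DomainFamily].
#' @param vocabulary Optional named logical vector mapping family ids to
#'   the flag, overriding the tags.
#' @return list with `family_id`, `cell_wall_hydrolase`, `note`.
#' @export
classifyFunction <- function(family, vocabulary = NULL) {
  fid <- family@familyId
  if (!is.null(vocabulary) && fid %in% names(vocabulary)) {
    flag <- isTRUE(vocabulary[[fid]])
    return(list(family_id = fid, cell_wall_hydrolase = flag,
                note = if (flag) "vocabulary" else "unknown"))
  }
  tags <- family@functionTags
  if (!length(tags)) {
    return(list(family_id = fid, cell_wall_hydrolase = FALSE,
                note = "unknown"))
  }
  flag <- any(tags %in% CELL_WALL_TAGS)
  list(family_id = fid, cell_wall_hydrolase = flag,
       note = if (flag) "cell_wall_hydrolase" else
         paste(tags, collapse = ","))
}

#' Extract the residue string of an annotated domain
#'
#' @param protein Character scalar (whole protein sequence).
#' @param start,end 0-based half-open interval (or pass an annotation
#'   row's `start`/`end`).
#' @return Character scalar.
#' @export
extractDomainSequence <- function(protein, start, end) {
  stopIfNot(is.character(protein) && length(protein) == 1L,
            "protein must be a string")
  n <- nchar(protein)
  stopIfNot(start >= 0L && end <= n && end > start,
            "interval out of range")
  substr(protein, start + 1L, end)
}

#' Local alignment of two residue strings
#'
#' Smith--Waterman local alignment with affine gaps (BLOSUM62, gap open
#' 11, extend 1). Percent identity counts identical aligned residue
#' pairs over aligned residue pairs, excluding gap columns. When several
#' alignments are co-optimal, the traceback is made order-independent by
#' aligning the lexicographically smaller sequence as the pattern, so
#' identity is symmetric in the two arguments.
#'
#' @param a,b Non-empty residue strings.
#' @return list with `score`, `alignment` (two gapped strings) and
#'   `percent_identity`.
#' @export
localAlign <- function(a, b) {
  stopIfNot(is.character(a) && length(a) == 1L && nzchar(a),
            "a must be a non-empty string")
  stopIfNot(is.character(b) && length(b) == 1L && nzchar(b),
            "b must be a non-empty string")
  swapped <- a > b
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(al))
  pb <- as.character(Biostrings::alignedSubject(al))
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(pb, "")[[1]]
  resid <- ca != "-" & cb != "-"
  pid <- if (any(resid)) 100 * sum(ca[resid] == cb[resid]) / sum(resid) else 0
  list(score = Biostrings::score(al),
       alignment = if (swapped) c(pb, pa) else c(pa, pb),
       percent_identity = pid)
}

## Vectorised score-only Smith-Waterman of one query against many
## subjects (same scoring system as localAlign()).
.swScores <- function(query, subjects) {
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
}

#' Nearest cross-superkingdom homolog of a domain sequence
#'
#' Ranks the donor database by Smith--Waterman score against the domain
#' sequence and returns the best-scoring donor whose superkingdom
#' differs from the query protein's, provided its Gumbel-calibrated
#' E-value (fitted on residue-shuffled donor decoys) is at most `max_e`.
#'
#' @param domain_seq Character scalar.
#' @param donors Named character vector or `AAStringSet`.
#' @param donor_taxonomy data.frame with columns `sequence_id`,
#'   `species`, `superkingdom`, `kingdom`, `phylum` covering every donor.
#' @param self_superkingdom Superkingdom of the query protein.
#' @param max_e E-value ceiling for accepting a hit.
#' @param n_decoys Minimum number of shuffled decoys for calibration.
#' @param seed Integer seed for the decoy shuffle.
#' @return list with `donor_id`, `donor_species`, `donor_lineage`
#'   (list), `score`, `e_value`, `percent_identity`, `alignment`; or
#'   `NULL` when no qualifying hit exists.
#' @export
nearestForeignHit <- function(domain_seq, donors, donor_taxonomy,
                              self_superkingdom, max_e = 1e-5,
                              n_decoys = 200L, seed = 1L) {
  db <- .asStringDb(donors)
  miss <- setdiff(names(db), donor_taxonomy$sequence_id)
  if (length(miss)) {
    stop("donor sequence(s) missing taxonomy: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (max_e <= 0) return(NULL)
  scores <- .swScores(domain_seq, unname(db))
  decoys <- withSeed(splitSeed(seed, 8000001L), {
    idx <- rep_len(seq_along(db), max(n_decoys, 100L))
    vapply(idx, function(i) {
      paste0(sample(strsplit(db[[i]], "")[[1]]), collapse = "")
    }, character(1))
  })
  params <- fitGumbelMoments(.swScores(domain_seq, decoys))
  evals <- scoreToEvalue(scores, params, length(db))
  tax <- donor_taxonomy[match(names(db), donor_taxonomy$sequence_id), ]
  ord <- order(-scores, names(db))
  for (i in ord) {
    if (tax$superkingdom[i] == self_superkingdom) next
    if (evals[i] > max_e) next
    al <- localAlign(domain_seq, db[[i]])
    return(list(donor_id = names(db)[i],
                donor_species = tax$species[i],
                donor_lineage = list(superkingdom = tax$superkingdom[i],
                                     kingdom = tax$kingdom[i],
                                     phylum = tax$phylum[i]),
                score = scores[[i]], e_value = evals[[i]],
                percent_identity = al$percent_identity,
                alignment = al$alignment))
  }
  NULL
}

#' Call HGT status of one protein
#'
#' Rules: `candidate` iff the protein carries at least one domain whose
#' family is `prokaryote_phage_typical`; `chimeric` iff it carries two or
#' more such domains from distinct families; `independent_events` iff it
#' is chimeric and the best foreign hits of at least two such domains
#' fall in distinct donor phyla. The rationale records each rule that
#' fired.
#'
#' @param protein_id Protein identifier.
#' @param annotations data.frame of (resolved) annotations for this
#'   protein.
#' @param classifications data.frame from [classifyLibrary()] (or with
#'   columns `family_id`, `label`).
#' @param foreign_hits list parallel to the annotation rows: each element
#'   the [nearestForeignHit()] result for that domain, or `NULL`.
#' @return list with `protein_id`, `candidate`, `chimeric`,
#'   `independent_events`, `per_domain` (data.frame) and `rationale`.
#' @export
callHGT <- function(protein_id, annotations, classifications,
                    foreign_hits = NULL) {
  if (nrow(annotations)) {
    stopIfNot(all(annotations$protein_id == protein_id),
              "annotations must all belong to the called protein")
  }
  n <- nrow(annotations)
  if (is.null(foreign_hits)) foreign_hits <- vector("list", n)
  stopIfNot(length(foreign_hits) == n,
            "foreign_hits must be parallel to annotations")
  lab <- classifications$label[match(annotations$family_id,
                                     classifications$family_id)]
  lab[is.na(lab)] <- "unbiased"
  donor_phylum <- vapply(foreign_hits, function(h) {
    if (is.null(h)) NA_character_ else h$donor_lineage$phylum
  }, character(1))
  per_domain <- data.frame(
    family_id = annotations$family_id %||% character(0),
    label = lab,
    donor_species = vapply(foreign_hits, function(h) {
      if (is.null(h)) NA_character_ else h$donor_species
    }, character(1)),
    donor_phylum = donor_phylum,
    stringsAsFactors = FALSE)

  typical <- which(lab == "prokaryote_phage_typical")
  candidate <- length(typical) >= 1L
  chimeric <- length(unique(annotations$family_id[typical])) >= 2L
  phyla <- unique(stats::na.omit(donor_phylum[typical]))
  independent <- chimeric && length(phyla) >= 2L

  rationale <- character(0)
  if (candidate) {
    rationale <- c(rationale, sprintf(
      "%d domain(s) from prokaryote/phage-typical families (%s): HGT candidate",
      length(typical),
      paste(unique(annotations$family_id[typical]), collapse = ", ")))
  } else {
    rationale <- c(rationale, "no prokaryote/phage-typical domain: not a candidate")
  }
  if (chimeric) {
    rationale <- c(rationale,
                   ">=2 distinct prokaryote/phage-typical families: chimeric")
  }
  if (independent) {
    rationale <- c(rationale, sprintf(
      "best foreign hits in distinct donor phyla (%s): independent transfer events",
      paste(phyla, collapse = " vs ")))
  }
  list(protein_id = protein_id, candidate = candidate, chimeric = chimeric,
       independent_events = independent, per_domain = per_domain,
       rationale = rationale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen every annotated protein for HGT
#'
#' Convenience driver over [callHGT()]: resolves overlaps, extracts each
#' prokaryote/phage-typical domain's sequence, finds its nearest foreign
#' hit in the donor database, and emits one call per protein that has a
#' repeat hit.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param hit_ids Protein ids with repeat hits (the screen's dataset).
#' @param annotations Annotation data.frame ([scanDomains()] output).
#' @param classifications data.frame from [classifyLibrary()].
#' @param taxonomy Per-sequence taxonomy data.frame.
#' @param donors,donor_taxonomy Donor database and its taxonomy.
#' @param max_e Foreign-hit E-value ceiling.
#' @param seed Integer seed.
#' @return list of [callHGT()] results, named by protein id.
#' @export
screenHGT <- function(proteins, hit_ids, annotations, classifications,
                      taxonomy, donors, donor_taxonomy, max_e = 1e-5,
                      seed = 1L) {
  db <- .asStringDb(proteins)
  ann <- resolveOverlaps(annotations)
  calls <- list()
  for (pid in hit_ids) {
    a <- ann[ann$protein_id == pid, , drop = FALSE]
    self_sk <- taxonomy$superkingdom[match(pid, taxonomy$sequence_id)]
    if (is.na(self_sk)) {
      stop("hit protein missing taxonomy: ", pid, call. = FALSE)
    }
    fh <- vector("list", nrow(a))
    if (nrow(a)) {
      lab <- classifications$label[match(a$family_id,
                                         classifications$family_id)]
      for (k in which(lab == "prokaryote_phage_typical")) {
        dseq <- extractDomainSequence(db[[pid]], a$start[k], a$end[k])
        fh[[k]] <- nearestForeignHit(dseq, donors, donor_taxonomy,
                                     self_superkingdom = self_sk,
                                     max_e = max_e,
                                     seed = splitSeed(seed, 9000000L + k))
      }
    }
    calls[[pid]] <- callHGT(pid, a, classifications, fh)
  }
  calls
}

#' Write HGT calls to JSON
#'
#' @param calls list from [screenHGT()].
#' @param path Output path.
#' @export
writeCalls <- function(calls, path) {
  jsonlite::write_json(unname(calls), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

## ---- aggregate statistics --------------------------------------------

#' Aggregate screen statistics
#'
#' Counts and integer percentages over the screen's dataset: proteins
#' with repeat hits, with annotated domains, with prokaryote/phage-
#' typical domains, with cell-wall hydrolase domains; per-family protein
#' counts; and per-taxon protein counts at superkingdom, kingdom and
#' phylum rank. Percentages are rounded to the nearest integer, half
#' away from zero.
#'
#' @param hit_ids Protein ids with repeat hits.
#' @param annotations Annotation data.frame (resolved or raw).
#' @param classifications data.frame from [classifyLibrary()] (columns
#'   `family_id`, `label`, `cell_wall_hydrolase`).
#' @param taxonomy Per-sequence taxonomy data.frame.
#' @return list of class `SummaryStats`.
#' @export
aggregateStats <- function(hit_ids, annotations, classifications,
                           taxonomy) {
  hit_ids <- unique(hit_ids)
  miss <- setdiff(hit_ids, taxonomy$sequence_id)
  if (length(miss)) {
    stop("hit protein(s) missing taxonomy: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  ann <- annotations[annotations$protein_id %in% hit_ids, , drop = FALSE]
  lab <- classifications$label[match(ann$family_id,
                                     classifications$family_id)]
  cw <- classifications$cell_wall_hydrolase[match(
    ann$family_id, classifications$family_id)]

  n_hits <- length(hit_ids)
  with_domains <- unique(ann$protein_id)
  n_with_domains <- length(with_domains)
  prok_prot <- unique(ann$protein_id[lab %in% "prokaryote_phage_typical"])
  cw_prot <- unique(ann$protein_id[cw %in% TRUE])
  n_prok <- length(prok_prot)
  n_cw <- length(cw_prot)

  per_family <- if (nrow(ann)) {
    counts <- tapply(ann$protein_id, ann$family_id,
                     function(x) length(unique(x)))
    data.frame(family_id = names(counts),
               n_proteins = as.integer(counts),
               percent_of_annotated = as.integer(roundHalfAway(
                 100 * as.integer(counts) / max(n_with_domains, 1L))),
               row.names = NULL)
  } else {
    data.frame(family_id = character(0), n_proteins = integer(0),
               percent_of_annotated = integer(0))
  }

  tx <- taxonomy[match(hit_ids, taxonomy$sequence_id), , drop = FALSE]
  countRank <- function(rank) {
    v <- tx[[rank]]
    v[is.na(v) | v == ""] <- "(none)"
    counts <- sort(table(v), decreasing = TRUE)
    data.frame(taxon = names(counts), n_proteins = as.integer(counts),
               row.names = NULL)
  }

  out <- list(
    n_hits = n_hits,
    n_with_domains = n_with_domains,
    n_prokaryote_typical_proteins = n_prok,
    n_cell_wall_proteins = n_cw,
    pct_prokaryote_typical = percentOf(n_prok, n_with_domains),
    pct_cell_wall = percentOf(n_cw, n_with_domains),
    pct_unbiased_only = percentOf(n_with_domains - n_prok, n_with_domains),
    per_family_counts = per_family,
    per_taxon_counts = list(superkingdom = countRank("superkingdom"),
                            kingdom = countRank("kingdom"),
                            phylum = countRank("phylum"))
  )
  class(out) <- c("SummaryStats", "list")
  stopIfNot(out$n_prokaryote_typical_proteins <= out$n_with_domains &&
              out$n_with_domains <= out$n_hits,
            "summary count invariant violated")
  out
}

#' Integer percentage, rounded half away from zero
#'
#' `percentOf(98, 124)` is 79; `percentOf(26, 124)` is 21.
#'
#' @param count,denominator Non-negative counts.
#' @return Integer percentage (0 when the denominator is 0).
#' @export
percentOf <- function(count, denominator) {
  if (denominator == 0) return(0L)
  as.integer(roundHalfAway(100 * count / denominator))
}

#' @export
print.SummaryStats <- function(x, ...) {
  cat(sprintf("Screen summary: %d hit proteins, %d with domains\n",
              x$n_hits, x$n_with_domains))
  cat(sprintf("  prokaryote/phage-typical: %d (%d%%)\n",
              x$n_prokaryote_typical_proteins, x$pct_prokaryote_typical))
  cat(sprintf("  cell-wall hydrolase:      %d (%d%%)\n",
              x$n_cell_wall_proteins, x$pct_cell_wall))
  invisible(x)
}

#' Write summary statistics to JSON
#'
#' @param stats A `SummaryStats`.
#' @param path Output path.
#' @export
writeSummary <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
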