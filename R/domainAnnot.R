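## domain_annot: domain-family libraries, profile scans of proteins,
## overlap resolution, and ingestion of external domain tables.

#' Build a scoring model from an ungapped family consensus
#'
#' Treats the consensus as a single-row alignment and applies the same
#' pseudocount estimator as [buildProfile()] with every column a match
#' state, yielding a sharp but smoothed profile for the family.
#'
#' @param consensus Character scalar (ungapped).
#' @param pseudocount Background-mixing weight.
#' @param background Length-20 background frequencies.
#' @return A [ProfileHMM].
#' @export
buildFamilyModel <- function(consensus, pseudocount = 1.0,
                             background = BACKGROUND_FREQS) {
  stopIfNot(is.character(consensus) && length(consensus) == 1L &&
              nchar(consensus) >= 1L, "consensus must be a non-empty string")
  m <- matrix(strsplit(toupper(consensus), "")[[1]], nrow = 1L)
  estimateProfile(m, seq_len(ncol(m)), pseudocount,
                  background / sum(background))
}

#' Construct a domain family
#'
#' @param family_id Unique accession-style identifier.
#' @param name Human-readable name.
#' @param consensus Ungapped consensus sequence.
#' @param carriers data.frame of carrier species lineages (`species`,
#'   `superkingdom`, `kingdom`, `phylum`).
#' @param function_tags Character vector of controlled-vocabulary tags.
#' @param donor_phylum,donor_species Optional synthetic-donor bookkeeping.
#' @return A [DomainFamily].
#' @export
domainFamily <- function(family_id, name, consensus, carriers,
                         function_tags = character(0),
                         donor_phylum = NULL, donor_species = NULL) {
  unknown <- setdiff(function_tags, FUNCTION_TAG_VOCABULARY)
  if (length(unknown)) {
    stop("unknown function tag(s) for family ", family_id, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obj <- new("DomainFamily",
             familyId = family_id, name = name,
             consensus = toupper(consensus),
             model = buildFamilyModel(consensus),
             carrierLineages = carriers,
             functionTags = function_tags,
             donorPhylum = donor_phylum)
  attr(obj, "donor_species") <- donor_species
  validObject(obj)
  obj
}

## Build the synthetic library described by a SyntheticConfig: family
## consensus sequences are deterministic draws from the background, and
## carrier species are spread over the configured phyla.
buildDomainLibrary <- function(config) {
  fams <- lapply(seq_along(config$domain_families), function(fi) {
    fs <- config$domain_families[[fi]]
    withSeed(splitSeed(config$seed, 6000000L + fi), {
      consensus <- .bgResidues(fs$length)
      carriers <- list()
      for (sk in names(fs$carrier_counts)) {
        n <- fs$carrier_counts[[sk]]
        ph <- rep_len(config$phyla[[sk]], n)
        for (i in seq_len(n)) {
          carriers[[length(carriers) + 1L]] <- data.frame(
            species = sprintf("%s carrier %s %02d (synthetic)",
                              fs$family_id, sk, i),
            superkingdom = sk,
            kingdom = if (sk == "Eukaryota") {
              if (ph[i] == "Ascomycota") "Fungi" else "Metazoa"
            } else "",
            phylum = ph[i])
        }
      }
      domainFamily(fs$family_id, fs$name, consensus,
                   do.call(rbind, carriers), fs$function_tags,
                   donor_phylum = if (is.na(fs$donor_phylum)) NULL else
                     fs$donor_phylum,
                   donor_species = if (is.na(fs$donor_species)) NULL else
                     fs$donor_species)
    })
  })
  lib <- new("DomainLibrary", families = fams)
  validObject(lib)
  lib
}

#' Write a domain library to JSON
#'
#' @param library A [DomainLibrary].
#' @param path Output path.
#' @export
writeDomainLibrary <- function(library, path) {
  obj <- list(
    format = "crrscreen-library", version = 1L,
    families = lapply(library@families, function(f) {
      list(family_id = f@familyId, name = f@name, consensus = f@consensus,
           function_tags = as.list(f@functionTags),
           donor_phylum = f@donorPhylum,
           donor_species = attr(f, "donor_species"),
           carriers = f@carrierLineages)
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a domain library from JSON
#'
#' Family models are rebuilt from the stored consensus sequences.
#'
#' @param path Path written by [writeDomainLibrary()].
#' @return A [DomainLibrary].
#' @export
readDomainLibrary <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopIfNot(identical(obj$format, "crrscreen-library"),
            "not a domain-library JSON file")
  fams <- lapply(obj$families, function(f) {
    carriers <- do.call(rbind, lapply(f$carriers, function(r) {
      data.frame(species = r$species, superkingdom = r$superkingdom,
                 kingdom = r$kingdom %||% "", phylum = r$phylum %||% "")
    }))
    tags <- as.character(unlist(f$function_tags))
    asScalar <- function(x) if (is.character(x) && length(x) == 1L) x else NULL
    domainFamily(f$family_id, f$name, f$consensus, carriers, tags,
                 donor_phylum = asScalar(f$donor_phylum),
                 donor_species = asScalar(f$donor_species))
  })
  lib <- new("DomainLibrary", families = fams)
  validObject(lib)
  lib
}

## ---- scanning ---------------------------------------------------------

#' Scan proteins for domain-family matches
#'
#' Scores each family's profile against each protein with the search
#' engine, finding multiple instances by envelope masking, and reports
#' annotations with E-value <= `report_e`. E-values are per protein and
#' family (database size 1), calibrated on background decoys whose
#' lengths resample the scanned proteins' lengths.
#'
#' @param proteins Named character vector or `AAStringSet`.
#' @param library A [DomainLibrary].
#' @param report_e Reporting threshold (> 0; default 1e-3).
#' @param n_decoys Decoys per family calibration.
#' @param seed Integer seed for decoy sampling.
#' @return data.frame of annotations: `protein_id`, `family_id`,
#'   `start`, `end` (0-based half-open), `e_value`, `bit_score`; sorted
#'   by protein then start.
#' @export
scanDomains <- function(proteins, library, report_e = 1e-3,
                        n_decoys = 200L, seed = 1L) {
  stopIfNot(is(library, "DomainLibrary") && length(library) > 0L,
            "library must be a non-empty DomainLibrary")
  stopIfNot(report_e > 0, "report_e must be positive")
  db <- .asStringDb(proteins)
  codes <- lapply(db, encodeResidues)
  lens <- lengths(codes)
  rows <- list()
  for (fi in seq_along(library@families)) {
    fam <- library@families[[fi]]
    ok <- tryCatch(validObject(fam@model), error = function(e) e)
    if (inherits(ok, "error")) {
      stop("malformed model in family ", fam@familyId, ": ",
           conditionMessage(ok), call. = FALSE)
    }
    tables <- profileScoringTables(fam@model)
    params <- calibrateEvalues(fam@model, n_decoys = n_decoys,
                               decoy_lengths = lens,
                               seed = splitSeed(seed, 7000000L + fi))
    for (pi in seq_along(codes)) {
      cur <- codes[[pi]]
      for (k in seq_len(25L)) {
        v <- cpp_viterbi(tables$mlo, tables$ilo, tables$entry, tables$lmm,
                         tables$lmi, tables$lmd, tables$lme, tables$lim,
                         tables$lii, tables$ldm, tables$ldd, cur)
        if (!is.finite(v$bit_score)) break
        e <- scoreToEvalue(v$bit_score, params, 1)
        if (e > report_e) break
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = names(db)[pi], family_id = fam@familyId,
          start = v$env_start, end = v$env_end,
          e_value = e, bit_score = v$bit_score)
        cur[(v$env_start + 1L):v$env_end] <- AA_MASK_CODE
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    protein_id = character(0), family_id = character(0),
    start = integer(0), end = integer(0),
    e_value = numeric(0), bit_score = numeric(0))
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve overlapping domain annotations greedily
#'
#' Annotations on one protein are admitted in order of ascending E-value
#' (ties: higher bit score, then smaller start); an annotation is kept
#' iff it shares no residue with any already-kept annotation of the same
#' protein. Order of the input rows does not affect the result.
#'
#' @param annotations data.frame as returned by [scanDomains()].
#' @return The non-overlapping subset, sorted by protein then start.
#' @export
resolveOverlaps <- function(annotations) {
  if (!nrow(annotations)) return(annotations)
  stopIfNot(all(annotations$end > annotations$start),
            "zero-length annotation intervals are forbidden")
  ord <- order(annotations$e_value, -annotations$bit_score,
               annotations$start, annotations$family_id)
  a <- annotations[ord, , drop = FALSE]
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    prior <- which(keep & a$protein_id == a$protein_id[i])
    clash <- any(a$start[prior] < a$end[i] & a$end[prior] > a$start[i])
    keep[i] <- !clash
  }
  out <- a[keep, , drop = FALSE]
  out <- out[order(out$protein_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## ---- annotation table I/O --------------------------------------------

#' Write a domain-annotation table to TSV
#'
#' Coordinates are written 1-based inclusive.
#'
#' @param annotations data.frame from [scanDomains()].
#' @param path Output path.
#' @export
writeDomainTable <- function(annotations, path) {
  out <- data.frame(
    protein_id = annotations$protein_id,
    family_id = annotations$family_id,
    start = annotations$start + 1L,
    end = annotations$end,
    e_value = annotations$e_value,
    bit_score = if ("bit_score" %in% names(annotations))
      annotations$bit_score else NA_real_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a domain-annotation table (possibly from an external scan)
#'
#' Expects a TSV with header columns `protein_id`, `family_id`, `start`,
#' `end`, `e_value` (1-based inclusive coordinates); an optional
#' `bit_score` column is carried through. Rows with non-numeric fields
#' or `end < start` are rejected with their line numbers.
#'
#' @param path TSV path.
#' @return data.frame with internal 0-based half-open coordinates.
#' @export
readDomainTable <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("protein_id", "family_id", "start", "end", "e_value")
  missing <- setdiff(need, names(t))
  if (length(missing)) {
    stop("domain table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!nrow(t)) {
    return(data.frame(protein_id = character(0), family_id = character(0),
                      start = integer(0), end = integer(0),
                      e_value = numeric(0), bit_score = numeric(0)))
  }
  numOrNA <- function(x) suppressWarnings(as.numeric(x))
  start <- numOrNA(t$start); end <- numOrNA(t$end); ev <- numOrNA(t$e_value)
  bad <- which(is.na(start) | is.na(end) | is.na(ev))
  if (length(bad)) {
    stop("non-numeric fields at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  rev <- which(end < start)
  if (length(rev)) {
    stop("end < start at line(s) ", paste(rev + 1L, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    protein_id = t$protein_id, family_id = t$family_id,
    start = as.integer(start) - 1L, end = as.integer(end),
    e_value = ev,
    bit_score = if ("bit_score" %in% names(t)) numOrNA(t$bit_score) else
      NA_real_)
  rownames(out) <- NULL
  out
}
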