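## synth_data: synthetic proteomes, taxonomy tables, domain libraries and
## ground-truth tables with the statistical structure the screen assumes.

#' Default domain-family specifications for the synthetic proteome
#'
#' Four families: two prokaryote-biased cell-wall hydrolase families whose
#' donors sit in distinct bacterial phyla (Firmicutes and Bacteroidetes,
#' the chimeric-protein scenario), one phage-typical lysozyme-like family,
#' and one eukaryote-dominated family with no functional annotation as the
#' unbiased negative control.
#'
#' @return list of family specification lists.
#' @export
defaultFamilySpecs <- function() {
  list(
    list(family_id = "SYNF001", name = "glycoside hydrolase (synthetic)",
         length = 60L,
         function_tags = c("glycoside_hydrolase", "cell_wall_hydrolase"),
         donor_superkingdom = "Bacteria", donor_phylum = "Firmicutes",
         donor_species = "Lachnoclostridium sp. (synthetic)",
         carrier_counts = c(Bacteria = 9L, Eukaryota = 1L)),
    list(family_id = "SYNF002", name = "peptidase M15 (synthetic)",
         length = 55L,
         function_tags = c("peptidase", "cell_wall_hydrolase"),
         donor_superkingdom = "Bacteria", donor_phylum = "Bacteroidetes",
         donor_species = "Bacteroides clarus (synthetic)",
         carrier_counts = c(Bacteria = 10L, Viruses = 2L, Eukaryota = 1L)),
    list(family_id = "SYNF003", name = "lysozyme-like (synthetic)",
         length = 50L,
         function_tags = c("lysozyme"),
         donor_superkingdom = "Viruses", donor_phylum = "Uroviricota",
         donor_species = "Siphophage sp. (synthetic)",
         carrier_counts = c(Bacteria = 4L, Viruses = 4L, Eukaryota = 1L)),
    list(family_id = "SYNF004", name = "eukaryotic scaffold (synthetic)",
         length = 58L,
         function_tags = character(0),
         donor_superkingdom = NA_character_, donor_phylum = NA_character_,
         donor_species = NA_character_,
         carrier_counts = c(Bacteria = 2L, Eukaryota = 10L))
  )
}

#' Build a synthetic-proteome configuration
#'
#' Defaults define the study conditions of the bundled benchmark: a
#' 500-protein proteome (445 background, 50 repeat-carrying, 5 chimeric),
#' repeat modules drawn from the 33-residue consensus at substitution
#' rate 0.1 with the six cysteines invariant, 2--6 module copies per
#' repeat protein arranged in pairs, every fifth repeat protein carrying
#' one library domain, and chimeric proteins carrying two domains whose
#' donors sit in Firmicutes and Bacteroidetes, each preceded by a pair of
#' modules.
#'
#' @param n_background,n_repeat_proteins,n_chimeric Protein counts.
#' @param repeat_copies_range Integer interval of module copies per
#'   repeat protein.
#' @param module_consensus Module consensus string.
#' @param invariant_positions 1-based positions held invariant.
#' @param substitution_rate Per-mutable-position substitution probability
#'   (a substitution draws uniformly among the 20 residues, so 1/20 of
#'   draws are silent).
#' @param indel_rate Optional per-position probability of a geometric
#'   insertion after the position (exercises insert states; 0 keeps truth
#'   intervals exact and is the default).
#' @param domain_substitution_rate Substitution rate for implanted domain
#'   instances and donor sequences.
#' @param domain_attach_period Every `period`-th repeat protein carries
#'   one library domain (0 disables).
#' @param background_length_range Length interval of background proteins.
#' @param max_protein_length Sizing cap; a protein whose implants exceed
#'   it raises an error.
#' @param n_species Named integer: species per superkingdom.
#' @param phyla Named list: phylum labels per superkingdom.
#' @param euk_kingdom_weights Sampling weights of eukaryotic host
#'   kingdoms for proteome proteins.
#' @param domain_families list of family specs ([defaultFamilySpecs()]).
#' @param n_decoy_donors Eukaryotic decoy sequences added to the donor
#'   database.
#' @param seed Integer master seed; every protein derives its own
#'   substream from it, so appending proteins leaves earlier ones
#'   unchanged.
#' @return A `SyntheticConfig` (list with class attribute).
#' @export
syntheticConfig <- function(n_background = 445L,
                            n_repeat_proteins = 50L,
                            n_chimeric = 5L,
                            repeat_copies_range = c(2L, 6L),
                            module_consensus = DEFAULT_MODULE_CONSENSUS,
                            invariant_positions = DEFAULT_INVARIANT_POSITIONS,
                            substitution_rate = 0.1,
                            indel_rate = 0,
                            domain_substitution_rate = 0.05,
                            domain_attach_period = 5L,
                            background_length_range = c(80L, 400L),
                            max_protein_length = 2000L,
                            n_species = c(Bacteria = 12L, Archaea = 2L,
                                          Eukaryota = 12L, Viruses = 3L),
                            phyla = list(
                              Bacteria = c("Firmicutes", "Bacteroidetes",
                                           "Proteobacteria"),
                              Archaea = "Euryarchaeota",
                              Eukaryota = c("Ascomycota", "Chordata",
                                            "Arthropoda"),
                              Viruses = "Uroviricota"),
                            euk_kingdom_weights = c(Fungi = 0.79,
                                                    Metazoa = 0.21),
                            domain_families = defaultFamilySpecs(),
                            n_decoy_donors = 5L,
                            seed = 42L) {
  cfg <- list(
    n_background = as.integer(n_background),
    n_repeat_proteins = as.integer(n_repeat_proteins),
    n_chimeric = as.integer(n_chimeric),
    repeat_copies_range = as.integer(repeat_copies_range),
    module_consensus = toupper(module_consensus),
    invariant_positions = as.integer(invariant_positions),
    substitution_rate = substitution_rate,
    indel_rate = indel_rate,
    domain_substitution_rate = domain_substitution_rate,
    domain_attach_period = as.integer(domain_attach_period),
    background_length_range = as.integer(background_length_range),
    max_protein_length = as.integer(max_protein_length),
    n_species = n_species,
    phyla = phyla,
    euk_kingdom_weights = euk_kingdom_weights,
    domain_families = domain_families,
    n_decoy_donors = as.integer(n_decoy_donors),
    seed = as.integer(seed)
  )
  class(cfg) <- c("SyntheticConfig", "list")
  validateSyntheticConfig(cfg)
  cfg
}

#' Validate a synthetic configuration
#'
#' @param config A `SyntheticConfig`.
#' @return Invisibly `TRUE`; stops on the first violation.
#' @export
validateSyntheticConfig <- function(config) {
  with(config, {
    stopIfNot(n_background >= 0L && n_repeat_proteins >= 0L &&
                n_chimeric >= 0L, "all protein counts must be >= 0")
    stopIfNot(substitution_rate >= 0 && substitution_rate <= 1,
              "substitution_rate must be in [0, 1]")
    stopIfNot(indel_rate >= 0 && indel_rate < 1,
              "indel_rate must be in [0, 1)")
    stopIfNot(length(repeat_copies_range) == 2L &&
                repeat_copies_range[1] >= 1L &&
                repeat_copies_range[1] <= repeat_copies_range[2],
              "repeat_copies_range must be a valid integer interval")
    cons <- strsplit(module_consensus, "")[[1]]
    stopIfNot(all(invariant_positions >= 1L &
                    invariant_positions <= length(cons)),
              "invariant positions out of range")
    stopIfNot(all(cons[invariant_positions] %in% c("C", "G", "P")),
              "invariant positions must be cysteines or flagged conserved residues")
    stopIfNot(all(names(n_species) %in%
                    c("Bacteria", "Archaea", "Eukaryota", "Viruses")),
              "n_species names must be superkingdoms")
  })
  invisible(TRUE)
}

## ---- taxonomy ---------------------------------------------------------

#' Sample a species pool (taxonomy table)
#'
#' Generates the species pool the proteome draws from: `n_species[k]`
#' species per superkingdom `k`, spread round-robin over the configured
#' phyla, plus the named donor species of the domain-family specs.
#' Deterministic for a given config seed; species labels unique.
#'
#' @param config A `SyntheticConfig`.
#' @return data.frame with columns `species`, `superkingdom`, `kingdom`,
#'   `phylum`.
#' @export
sampleTaxonomy <- function(config) {
  validateSyntheticConfig(config)
  # a family spec referencing a superkingdom with zero species is a
  # configuration error naming the family
  for (fs in config$domain_families) {
    sks <- names(fs$carrier_counts)[fs$carrier_counts > 0L]
    if (!is.na(fs$donor_superkingdom)) sks <- c(sks, fs$donor_superkingdom)
    missing <- setdiff(sks, names(config$n_species)[config$n_species > 0L])
    if (length(missing)) {
      stop(sprintf(
        "family %s references superkingdom(s) %s with zero species requested",
        fs$family_id, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  kingdomFor <- function(sk, phylum) {
    if (sk != "Eukaryota") return("")
    if (phylum == "Ascomycota") "Fungi" else "Metazoa"
  }
  rows <- withSeed(splitSeed(config$seed, 1L), {
    out <- list()
    for (sk in names(config$n_species)) {
      n <- config$n_species[[sk]]
      if (n == 0L) next
      ph <- rep_len(config$phyla[[sk]], n)
      for (i in seq_len(n)) {
        out[[length(out) + 1L]] <- data.frame(
          species = sprintf("%s %s sp. %02d (synthetic)", sk, ph[i], i),
          superkingdom = sk,
          kingdom = kingdomFor(sk, ph[i]),
          phylum = ph[i]
        )
      }
    }
    out
  })
  tab <- do.call(rbind, rows)
  for (fs in config$domain_families) {
    if (!is.na(fs$donor_species) && !(fs$donor_species %in% tab$species)) {
      tab <- rbind(tab, data.frame(
        species = fs$donor_species,
        superkingdom = fs$donor_superkingdom,
        kingdom = "",
        phylum = fs$donor_phylum
      ))
    }
  }
  stopIfNot(!anyDuplicated(tab$species), "species labels must be unique")
  rownames(tab) <- NULL
  tab
}

## ---- module generation ------------------------------------------------

#' Generate one cysteine-rich repeat module
#'
#' Returns a mutated copy of the module consensus: invariant positions
#' always carry the consensus residue; every other position is replaced,
#' with probability `substitution_rate`, by a residue drawn uniformly
#' from the 20-letter alphabet (so 1 in 20 substitutions is silent).
#' Consumes the caller's RNG stream.
#'
#' @param config A `SyntheticConfig`.
#' @return Character scalar of the consensus length.
#' @export
generateRepeatModule <- function(config) {
  cons <- strsplit(config$module_consensus, "")[[1]]
  mutable <- setdiff(seq_along(cons), config$invariant_positions)
  hit <- mutable[stats::runif(length(mutable)) < config$substitution_rate]
  if (length(hit)) {
    cons[hit] <- AA_ALPHABET20[sample.int(20L, length(hit), replace = TRUE)]
  }
  paste0(cons, collapse = "")
}

.bgResidues <- function(n) {
  if (n <= 0L) return("")
  paste0(AA_ALPHABET20[sample.int(20L, n, replace = TRUE,
                                  prob = BACKGROUND_FREQS)], collapse = "")
}

.mutateSeq <- function(sequence, rate) {
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- AA_ALPHABET20[sample.int(20L, length(hit), replace = TRUE)]
  }
  paste0(chars, collapse = "")
}

## Optional geometric-length insertions after each position (exercises
## insert states; shifts are reflected in the returned offset map).
.withIndels <- function(sequence, indel_rate) {
  if (indel_rate <= 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  out <- character(0)
  for (ch in chars) {
    out <- c(out, ch)
    if (stats::runif(1) < indel_rate) {
      k <- stats::rgeom(1, 0.5) + 1L
      out <- c(out, AA_ALPHABET20[sample.int(20L, k, replace = TRUE,
                                             prob = BACKGROUND_FREQS)])
    }
  }
  paste0(out, collapse = "")
}

## ---- proteome assembly ------------------------------------------------

.familyProkFraction <- function(fs) {
  tot <- sum(fs$carrier_counts)
  prok <- sum(fs$carrier_counts[names(fs$carrier_counts) %in%
                                  c("Bacteria", "Archaea", "Viruses")])
  prok / tot
}

## Assemble one protein from labelled segments; returns the sequence and
## the implant records (0-based half-open intervals).
.assembleProtein <- function(protein_id, segments, max_len) {
  seqs <- vapply(segments, `[[`, character(1), "seq")
  total <- sum(nchar(seqs))
  if (total > max_len) {
    stop(sprintf("protein %s: implants require %d residues, exceeding max_protein_length = %d",
                 protein_id, total, max_len), call. = FALSE)
  }
  starts <- cumsum(c(0L, nchar(seqs)[-length(seqs)]))
  implants <- list()
  for (k in seq_along(segments)) {
    sg <- segments[[k]]
    if (sg$type %in% c("repeat_module", "domain")) {
      implants[[length(implants) + 1L]] <- data.frame(
        protein_id = protein_id,
        implant_type = sg$type,
        family_id = if (is.null(sg$family_id)) NA_character_ else sg$family_id,
        start = starts[k],
        end = starts[k] + nchar(sg$seq),
        donor_species = if (is.null(sg$donor_species)) NA_character_ else
          sg$donor_species,
        donor_phylum = if (is.null(sg$donor_phylum)) NA_character_ else
          sg$donor_phylum,
        sequence = sg$seq
      )
    }
  }
  list(sequence = paste0(seqs, collapse = ""), implants = implants)
}

.seg <- function(seq, type = "flank", family_id = NULL,
                 donor_species = NULL, donor_phylum = NULL) {
  list(seq = seq, type = type, family_id = family_id,
       donor_species = donor_species, donor_phylum = donor_phylum)
}

#' Generate a synthetic proteome with ground truth
#'
#' Emits (a) background proteins drawn i.i.d. from the background residue
#' distribution, (b) repeat proteins carrying 2--k cysteine-rich modules
#' in pairs at recorded intervals (every `domain_attach_period`-th one
#' also carries a library domain), (c) chimeric proteins carrying two
#' domains from families whose donor phyla differ, each preceded by a
#' pair of modules, and (d) a donor database (the named prokaryotic donor
#' of each family plus eukaryotic decoys). Every protein derives its own
#' RNG substream from the master seed. The truth table records every
#' implant with its exact sequence and interval.
#'
#' @param config A `SyntheticConfig`.
#' @return A `SyntheticProteome`: list with `proteins`
#'   (`AAStringSet`), `taxonomy` (per-sequence data.frame:
#'   `sequence_id`, `species`, `superkingdom`, `kingdom`, `phylum`,
#'   covering proteome and donors), `library` ([DomainLibrary]),
#'   `truth` (list of `proteins` and `implants` data.frames), `donors`
#'   (`AAStringSet`), `species_pool`, `seed_msa` (aligned seed modules)
#'   and `config`.
#' @export
generateProteome <- function(config) {
  validateSyntheticConfig(config)
  pool <- sampleTaxonomy(config)
  library <- buildDomainLibrary(config)
  fams <- config$domain_families
  seed <- config$seed

  euk <- pool[pool$superkingdom == "Eukaryota", , drop = FALSE]
  eukWeights <- config$euk_kingdom_weights[euk$kingdom]
  eukWeights[is.na(eukWeights)] <- min(config$euk_kingdom_weights) / 2
  pickHost <- function() euk[sample.int(nrow(euk), 1L, prob = eukWeights), ]

  prokFrac <- vapply(fams, .familyProkFraction, numeric(1))
  donorFams <- which(!vapply(fams, function(f) is.na(f$donor_phylum),
                             logical(1)))
  if (config$n_chimeric > 0L) {
    phyla <- vapply(fams[donorFams], `[[`, character(1), "donor_phylum")
    stopIfNot(length(unique(phyla)) >= 2L,
              "chimeric proteins need >= 2 families with distinct donor phyla")
    chimPair <- donorFams[match(unique(phyla)[1:2], phyla)]
  }

  sequences <- character(0); ids <- character(0)
  prot_rows <- list(); implant_rows <- list()

  addProtein <- function(id, seqres, category, species_row, status) {
    sequences[[length(sequences) + 1L]] <<- seqres$sequence
    ids[[length(ids) + 1L]] <<- id
    prot_rows[[length(prot_rows) + 1L]] <<- data.frame(
      protein_id = id, category = category,
      species = species_row$species,
      superkingdom = species_row$superkingdom,
      kingdom = species_row$kingdom, phylum = species_row$phylum,
      hgt_status = status)
    for (im in seqres$implants) {
      implant_rows[[length(implant_rows) + 1L]] <<- im
    }
  }

  # repeat proteins -----------------------------------------------------
  for (i in seq_len(config$n_repeat_proteins)) {
    id <- sprintf("RPT%04d", i)
    withSeed(splitSeed(seed, 1000000L + i), {
      host <- pickHost()
      k <- sample(seq.int(config$repeat_copies_range[1],
                          config$repeat_copies_range[2]), 1L)
      segs <- list(.seg(.bgResidues(sample(10:40, 1L))))
      placed <- 0L
      while (placed < k) {
        in_pair <- min(2L, k - placed)
        for (p in seq_len(in_pair)) {
          segs[[length(segs) + 1L]] <-
            .seg(generateRepeatModule(config), "repeat_module")
        }
        placed <- placed + in_pair
        if (placed < k) {
          segs[[length(segs) + 1L]] <- .seg(.bgResidues(sample(5:15, 1L)))
        }
      }
      status <- "none"
      if (config$domain_attach_period > 0L &&
          i %% config$domain_attach_period == 0L) {
        fi <- 1L + (i %/% config$domain_attach_period - 1L) %% length(fams)
        fs <- fams[[fi]]
        segs[[length(segs) + 1L]] <- .seg(.bgResidues(sample(3:8, 1L)))
        segs[[length(segs) + 1L]] <- .seg(
          .mutateSeq(library@families[[fi]]@consensus,
                     config$domain_substitution_rate),
          "domain", family_id = fs$family_id,
          donor_species = fs$donor_species,
          donor_phylum = fs$donor_phylum)
        if (prokFrac[fi] > 0.75) status <- "candidate"
      }
      segs[[length(segs) + 1L]] <- .seg(.bgResidues(sample(10:40, 1L)))
      addProtein(id, .assembleProtein(id, segs, config$max_protein_length),
                 "repeat", host, status)
    })
  }

  # chimeric proteins ----------------------------------------------------
  for (i in seq_len(config$n_chimeric)) {
    id <- sprintf("CHM%04d", i)
    withSeed(splitSeed(seed, 2000000L + i), {
      host <- pickHost()
      segs <- list(.seg(.bgResidues(25L)))
      for (fi in chimPair) {
        fs <- fams[[fi]]
        segs[[length(segs) + 1L]] <-
          .seg(generateRepeatModule(config), "repeat_module")
        segs[[length(segs) + 1L]] <-
          .seg(generateRepeatModule(config), "repeat_module")
        segs[[length(segs) + 1L]] <- .seg(.bgResidues(sample(3:8, 1L)))
        segs[[length(segs) + 1L]] <- .seg(
          .mutateSeq(library@families[[fi]]@consensus,
                     config$domain_substitution_rate),
          "domain", family_id = fs$family_id,
          donor_species = fs$donor_species,
          donor_phylum = fs$donor_phylum)
        segs[[length(segs) + 1L]] <- .seg(.bgResidues(sample(5:12, 1L)))
      }
      addProtein(id, .assembleProtein(id, segs, config$max_protein_length),
                 "chimeric", host, "chimeric")
    })
  }

  # background proteins --------------------------------------------------
  for (i in seq_len(config$n_background)) {
    id <- sprintf("BKG%04d", i)
    withSeed(splitSeed(seed, 3000000L + i), {
      host <- pickHost()
      n <- sample(seq.int(config$background_length_range[1],
                          config$background_length_range[2]), 1L)
      addProtein(id, list(sequence = .bgResidues(n), implants = list()),
                 "background", host, "none")
    })
  }

  # donor database --------------------------------------------------------
  donor_seqs <- character(0); donor_ids <- character(0)
  donor_tax <- list()
  for (fi in donorFams) {
    fs <- fams[[fi]]
    withSeed(splitSeed(seed, 4000000L + fi), {
      donor_seqs[[length(donor_seqs) + 1L]] <- paste0(
        .bgResidues(10L),
        .mutateSeq(library@families[[fi]]@consensus,
                   config$domain_substitution_rate / 2),
        .bgResidues(10L))
      donor_ids[[length(donor_ids) + 1L]] <- sprintf("DON_%s", fs$family_id)
      donor_tax[[length(donor_tax) + 1L]] <- data.frame(
        sequence_id = sprintf("DON_%s", fs$family_id),
        species = fs$donor_species, superkingdom = fs$donor_superkingdom,
        kingdom = "", phylum = fs$donor_phylum)
    })
  }
  for (i in seq_len(config$n_decoy_donors)) {
    withSeed(splitSeed(seed, 5000000L + i), {
      host <- pickHost()
      donor_seqs[[length(donor_seqs) + 1L]] <- .bgResidues(sample(60:120, 1L))
      donor_ids[[length(donor_ids) + 1L]] <- sprintf("DONBG%02d", i)
      donor_tax[[length(donor_tax) + 1L]] <- data.frame(
        sequence_id = sprintf("DONBG%02d", i),
        species = host$species, superkingdom = host$superkingdom,
        kingdom = host$kingdom, phylum = host$phylum)
    })
  }

  # seed module alignment (emulates the known repeat-module MSA) ---------
  seed_msa <- withSeed(splitSeed(seed, 999983L), {
    out <- vapply(seq_len(40L), function(i) generateRepeatModule(config),
                  character(1))
    names(out) <- sprintf("seedmod%02d", seq_along(out))
    out
  })

  truth_proteins <- do.call(rbind, prot_rows)
  truth_implants <- if (length(implant_rows)) {
    do.call(rbind, implant_rows)
  } else {
    data.frame(protein_id = character(0), implant_type = character(0),
               family_id = character(0), start = integer(0),
               end = integer(0), donor_species = character(0),
               donor_phylum = character(0), sequence = character(0))
  }
  rownames(truth_proteins) <- rownames(truth_implants) <- NULL

  proteome_tax <- data.frame(
    sequence_id = truth_proteins$protein_id,
    species = truth_proteins$species,
    superkingdom = truth_proteins$superkingdom,
    kingdom = truth_proteins$kingdom,
    phylum = truth_proteins$phylum)
  taxonomy <- rbind(proteome_tax, do.call(rbind, donor_tax))
  rownames(taxonomy) <- NULL

  proteins <- Biostrings::AAStringSet(setNames(unlist(sequences), ids))
  donors <- Biostrings::AAStringSet(setNames(unlist(donor_seqs),
                                             unlist(donor_ids)))
  out <- list(proteins = proteins, taxonomy = taxonomy, library = library,
              truth = list(proteins = truth_proteins,
                           implants = truth_implants),
              donors = donors, species_pool = pool, seed_msa = seed_msa,
              config = config)
  class(out) <- c("SyntheticProteome", "list")
  out
}

#' @export
print.SyntheticProteome <- function(x, ...) {
  cat(sprintf(
    "SyntheticProteome: %d proteins (%d background, %d repeat, %d chimeric), %d donors, %d families\n",
    length(x$proteins), sum(x$truth$proteins$category == "background"),
    sum(x$truth$proteins$category == "repeat"),
    sum(x$truth$proteins$category == "chimeric"),
    length(x$donors), length(x$library)))
  invisible(x)
}

#' Write a synthetic proteome to an output directory
#'
#' Writes `proteins.fasta`, `donors.fasta`, `taxonomy.tsv` (header
#' `sequence_id  species  superkingdom  kingdom  phylum`),
#' `library.json`, `truth_proteins.tsv`, `truth_implants.tsv` (1-based
#' inclusive coordinates) and `seed_modules.afa`.
#'
#' @param sim A `SyntheticProteome` from [generateProteome()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
writeProteome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$proteins, p("proteins.fasta"))
  Biostrings::writeXStringSet(sim$donors, p("donors.fasta"))
  utils::write.table(sim$taxonomy, p("taxonomy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeDomainLibrary(sim$library, p("library.json"))
  utils::write.table(sim$truth$proteins, p("truth_proteins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ti <- sim$truth$implants
  ti$start <- ti$start + 1L  # 1-based inclusive in files
  utils::write.table(ti, p("truth_implants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sim$seed_msa), p("seed_modules.afa"))
  paths <- c(proteins = p("proteins.fasta"), donors = p("donors.fasta"),
             taxonomy = p("taxonomy.tsv"), library = p("library.json"),
             truth_proteins = p("truth_proteins.tsv"),
             truth_implants = p("truth_implants.tsv"),
             seed_msa = p("seed_modules.afa"))
  invisible(paths)
}

#' Read a per-sequence taxonomy table
#'
#' @param path TSV with header
#'   `sequence_id  species  superkingdom  kingdom  phylum`.
#' @return data.frame.
#' @export
readTaxonomy <- function(path) {
  t <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  need <- c("sequence_id", "species", "superkingdom", "kingdom", "phylum")
  stopIfNot(all(need %in% names(t)), "taxonomy table is missing columns")
  bad <- !t$superkingdom %in% c("Bacteria", "Archaea", "Eukaryota", "Viruses")
  if (any(bad)) {
    stop("invalid superkingdom label(s): ",
         paste(unique(t$superkingdom[bad]), collapse = ", "), call. = FALSE)
  }
  t
}
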