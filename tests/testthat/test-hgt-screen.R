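test_that("the taxonomic-bias rule is strict at three quarters", {
  at_boundary <- classifyDomainTaxonomy(makeCarriers(3, 1))
  expect_equal(at_boundary$prokaryote_virus_fraction, 0.75)
  expect_identical(at_boundary$label, "unbiased")

  above <- classifyDomainTaxonomy(makeCarriers(4, 1))
  expect_equal(above$prokaryote_virus_fraction, 0.8)
  expect_identical(above$label, "prokaryote_phage_typical")

  expect_identical(classifyDomainTaxonomy(makeCarriers(4, 0))$label,
                   "prokaryote_phage_typical")
  expect_identical(classifyDomainTaxonomy(makeCarriers(0, 10))$label,
                   "unbiased")
})

test_that("carriers are counted as unique species, not rows", {
  c4 <- makeCarriers(3, 1)
  dup <- rbind(c4, c4[c4$superkingdom == "Bacteria", ][1, ])
  expect_equal(classifyDomainTaxonomy(dup)$prokaryote_virus_fraction, 0.75)
  expect_error(classifyDomainTaxonomy(makeCarriers(0, 0)), "carrier")
})

test_that("function classification reads tags, vocabulary and unknowns", {
  lib <- generateProteome(smallConfig())$library
  lyso <- getFamily(lib, "SYNF003")      # lysozyme-like
  expect_true(classifyFunction(lyso)$cell_wall_hydrolase)
  plain <- getFamily(lib, "SYNF004")     # untagged eukaryotic family
  fn <- classifyFunction(plain)
  expect_false(fn$cell_wall_hydrolase)
  expect_identical(fn$note, "unknown")
  # explicit vocabulary overrides the tags
  expect_false(classifyFunction(lyso,
                                vocabulary = c(SYNF003 = FALSE))$cell_wall_hydrolase)
})

test_that("domain sequences are extracted exactly at their intervals", {
  expect_identical(extractDomainSequence("MKLVAN", 1, 4), "KLV")
  expect_identical(extractDomainSequence("MKLVAN", 0, 6), "MKLVAN")
  expect_error(extractDomainSequence("MKLVAN", 3, 9), "range")
  sim <- generateProteome(smallConfig())
  ti <- sim$truth$implants
  dom <- ti[ti$implant_type == "domain", ][1, ]
  expect_identical(
    extractDomainSequence(as.character(sim$proteins)[[dom$protein_id]],
                          dom$start, dom$end),
    dom$sequence)
})

test_that("local alignment identity matches hand counts and is symmetric", {
  expect_equal(localAlign("ACDEFG", "ACDEFG")$percent_identity, 100)
  expect_equal(localAlign("ACDE", "ACKE")$percent_identity, 75)
  set.seed(31)
  for (k in 1:10) {
    a <- randomSeq(sample(6:20, 1)); b <- randomSeq(sample(6:20, 1))
    expect_equal(localAlign(a, b)$percent_identity,
                 localAlign(b, a)$percent_identity)
  }
  expect_error(localAlign("", "ACDE"), "non-empty")
})

test_that("local alignment scores match the exhaustive-alignment oracle", {
  set.seed(32)
  for (k in 1:30) {
    a <- randomSeq(sample(2:8, 1)); b <- randomSeq(sample(2:8, 1))
    expect_equal(localAlign(a, b)$score, swOracle(a, b), tolerance = 1e-9)
  }
})

test_that("the nearest foreign hit is the cross-superkingdom donor, honouring the threshold", {
  sim <- generateProteome(smallConfig())
  ti <- sim$truth$implants
  dom <- ti[ti$implant_type == "domain" & ti$family_id == "SYNF001", ][1, ]
  dseq <- extractDomainSequence(
    as.character(sim$proteins)[[dom$protein_id]], dom$start, dom$end)
  donor_tax <- sim$taxonomy[sim$taxonomy$sequence_id %in%
                              names(sim$donors), ]
  hit <- nearestForeignHit(dseq, sim$donors, donor_tax,
                           self_superkingdom = "Eukaryota", seed = 5)
  expect_identical(hit$donor_id, "DON_SYNF001")
  expect_identical(hit$donor_lineage$phylum, "Firmicutes")
  expect_gt(hit$percent_identity, 50)
  expect_lt(hit$e_value, 1e-5)

  # no donor left after the superkingdom filter
  expect_null(nearestForeignHit(dseq, sim$donors, donor_tax,
                                self_superkingdom = "Bacteria", seed = 5))
  # a zero threshold never accepts
  expect_null(nearestForeignHit(dseq, sim$donors, donor_tax,
                                self_superkingdom = "Eukaryota",
                                max_e = 0, seed = 5))
  # missing taxonomy is a data error naming the sequence
  expect_error(nearestForeignHit(dseq, sim$donors,
                                 donor_tax[-1, , drop = FALSE],
                                 self_superkingdom = "Eukaryota", seed = 5),
               donor_tax$sequence_id[1])
})

test_that("HGT calls follow the candidate, chimera and independent-events rules", {
  cls <- data.frame(family_id = c("FA", "FB", "FC"),
                    label = c("prokaryote_phage_typical",
                              "prokaryote_phage_typical", "unbiased"),
                    cell_wall_hydrolase = c(TRUE, TRUE, FALSE))
  oneTypical <- data.frame(protein_id = "P", family_id = "FA",
                           start = 0L, end = 50L, e_value = 1e-9,
                           bit_score = 60)
  call1 <- callHGT("P", oneTypical, cls)
  expect_true(call1$candidate)
  expect_false(call1$chimeric)
  expect_false(call1$independent_events)

  two <- data.frame(protein_id = "P", family_id = c("FA", "FB"),
                    start = c(0L, 100L), end = c(50L, 150L),
                    e_value = c(1e-9, 1e-8), bit_score = c(60, 55))
  fh <- list(
    list(donor_species = "d1",
         donor_lineage = list(superkingdom = "Bacteria", kingdom = "",
                              phylum = "Firmicutes")),
    list(donor_species = "d2",
         donor_lineage = list(superkingdom = "Bacteria", kingdom = "",
                              phylum = "Bacteroidetes")))
  call2 <- callHGT("P", two, cls, fh)
  expect_true(call2$candidate && call2$chimeric && call2$independent_events)
  expect_match(paste(call2$rationale, collapse = " "), "Firmicutes")

  onlyUnbiased <- data.frame(protein_id = "P", family_id = "FC",
                             start = 0L, end = 50L, e_value = 1e-6,
                             bit_score = 40)
  call3 <- callHGT("P", onlyUnbiased, cls)
  expect_false(call3$candidate || call3$chimeric || call3$independent_events)
})

test_that("call flags satisfy their implications on random inputs", {
  set.seed(33)
  labs <- c("prokaryote_phage_typical", "unbiased")
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria")
  for (k in 1:50) {
    n <- sample(0:4, 1)
    ann <- if (n > 0) data.frame(
      protein_id = "P",
      family_id = sample(paste0("F", 1:4), n),
      start = seq(0L, by = 100L, length.out = n),
      end = seq(50L, by = 100L, length.out = n),
      e_value = 10^-sample(3:12, n, replace = TRUE),
      bit_score = runif(n, 20, 90)) else
      data.frame(protein_id = character(0), family_id = character(0),
                 start = integer(0), end = integer(0),
                 e_value = numeric(0), bit_score = numeric(0))
    cls <- data.frame(family_id = paste0("F", 1:4),
                      label = sample(labs, 4, replace = TRUE),
                      cell_wall_hydrolase = sample(c(TRUE, FALSE), 4,
                                                   replace = TRUE))
    fh <- lapply(seq_len(n), function(i) {
      if (runif(1) < 0.4) NULL else list(
        donor_species = "d",
        donor_lineage = list(superkingdom = "Bacteria", kingdom = "",
                             phylum = sample(phyla, 1)))
    })
    call <- callHGT("P", ann, cls, fh)
    if (call$chimeric) expect_true(call$candidate)
    if (call$independent_events) {
      expect_true(call$chimeric)
      expect_gte(length(unique(na.omit(call$per_domain$donor_phylum))), 2L)
    }
  }
})

test_that("aggregate statistics respect their count invariants and rank tables", {
  sim <- generateProteome(smallConfig())
  prof <- buildProfile(sim$seed_msa)
  res <- iterativeSearch(prof, sim$proteins, seed = 4)
  h <- searchHits(res)
  ann <- resolveOverlaps(
    scanDomains(sim$proteins[names(sim$proteins) %in% h$target_id],
                sim$library, seed = 5))
  cls <- classifyLibrary(sim$library)
  stats <- aggregateStats(unique(h$target_id), ann, cls, sim$taxonomy)
  expect_lte(stats$n_prokaryote_typical_proteins, stats$n_with_domains)
  expect_lte(stats$n_with_domains, stats$n_hits)
  expect_equal(sum(stats$per_taxon_counts$superkingdom$n_proteins),
               stats$n_hits)
  expect_true(all(stats$per_taxon_counts$kingdom$taxon %in%
                    c("Fungi", "Metazoa", "(none)")))
  expect_error(aggregateStats(c(unique(h$target_id), "GHOST"), ann, cls,
                              sim$taxonomy), "GHOST")
})
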