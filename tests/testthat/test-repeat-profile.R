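test_that("border splitting reconstructs the sequence and validates its input", {
  expect_identical(splitRepeatPair("ABCDEF", 3), c("ABC", "DEF"))
  expect_identical(splitRepeatPair("ABCDEF"), "ABCDEF")
  expect_identical(splitRepeatPair("ABCDEF", c(2, 4)), c("AB", "CD", "EF"))
  expect_identical(paste0(splitRepeatPair("WXYZ", c(1, 3)), collapse = ""),
                   "WXYZ")
  expect_error(splitRepeatPair("ABCDEF", c(4, 2)), "sorted")
  expect_error(splitRepeatPair("ABCDEF", 6), "inside")
  expect_error(splitRepeatPair("ABCDEF", 0), "inside")
})

test_that("splitting a two-module repeat region at the module border recovers both truth modules", {
  sim <- generateProteome(smallConfig())
  ti <- sim$truth$implants
  mods <- ti[ti$implant_type == "repeat_module", ]
  mods <- mods[order(mods$protein_id, mods$start), ]
  # find an adjacent pair on one protein
  adj <- which(mods$protein_id[-1] == mods$protein_id[-nrow(mods)] &
                 mods$start[-1] == mods$end[-nrow(mods)])[1]
  expect_false(is.na(adj))
  a <- mods[adj, ]; b <- mods[adj + 1, ]
  region <- substr(as.character(sim$proteins)[[a$protein_id]],
                   a$start + 1, b$end)
  halves <- splitRepeatPair(region, a$end - a$start)
  expect_identical(halves, c(a$sequence, b$sequence))
  # invariant cysteines align across the two modules
  cfg <- sim$config
  for (p in cfg$invariant_positions) {
    expect_identical(substr(halves[1], p, p), substr(halves[2], p, p))
  }
})

test_that("self-alignment proposes period-length modules for tandem repeats", {
  set.seed(11)
  unit <- randomSeq(30)
  iv <- proposeRepeatModules(paste0(rep(unit, 3), collapse = ""))
  expect_equal(iv$start, c(0L, 30L, 60L))
  expect_equal(iv$end, c(30L, 60L, 90L))
})

test_that("self-alignment finds nothing in random sequence and excludes linkers", {
  set.seed(12)
  expect_equal(nrow(proposeRepeatModules(randomSeq(100), min_score = 60)), 0L)

  unit <- randomSeq(30)
  linked <- paste0(unit, randomSeq(10), unit)
  iv <- proposeRepeatModules(linked)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(0L, 40L))
  expect_equal(iv$end, c(30L, 70L))
})

test_that("match emissions follow the background-weighted pseudocount rule", {
  prof <- buildProfile(c("C", "C", "C"), pseudocount = 1,
                       background = rep(1 / 20, 20))
  expect_equal(unname(matchEmissions(prof)[1, "C"]), 0.7625)
  expect_equal(unname(matchEmissions(prof)[1, "A"]), 0.05 / 4)
})

test_that("profiles built from module alignments are stochastic and cysteine-anchored", {
  cfg <- syntheticConfig(substitution_rate = 0.1)
  set.seed(5)
  mods <- replicate(50, generateRepeatModule(cfg))
  prof <- buildProfile(mods)
  expect_s4_class(prof, "ProfileHMM")
  expect_equal(nMatch(prof), nchar(cfg$module_consensus))
  me <- matchEmissions(prof)
  expect_true(all(abs(rowSums(me) - 1) < 1e-9))
  expect_true(all(abs(rowSums(insertEmissions(prof)) - 1) < 1e-9))
  # invariant-cysteine columns have argmax emission C
  for (p in cfg$invariant_positions) {
    expect_identical(AA_ALPHABET20[which.max(me[p, ])], "C")
  }
})

test_that("an alignment with no match-qualifying column is a model-degeneracy error", {
  expect_error(buildProfile(c("A---", "----", "----", "----")), "occupancy")
})

test_that("raising the pseudocount weight pulls emissions toward the background", {
  cfg <- syntheticConfig(substitution_rate = 0.2)
  set.seed(6)
  mods <- replicate(12, generateRepeatModule(cfg))
  bg <- BACKGROUND_FREQS
  dist <- vapply(c(0.5, 1, 2, 5, 20), function(w) {
    me <- matchEmissions(buildProfile(mods, pseudocount = w))
    sum(abs(sweep(me, 2, bg)))
  }, numeric(1))
  expect_true(all(diff(dist) <= 1e-12))
})

test_that("profile JSON round-trip reproduces all probabilities to 1e-12", {
  cfg <- syntheticConfig()
  set.seed(7)
  prof <- buildProfile(replicate(20, generateRepeatModule(cfg)))
  path <- withr::local_tempfile(fileext = ".json")
  writeProfile(prof, path)
  back <- readProfile(path)
  for (sl in c("matchEmis", "insEmis", "entry", "transM", "transI",
               "transD", "background")) {
    expect_lt(max(abs(slot(prof, sl) - slot(back, sl))), 1e-12)
  }
  expect_identical(consensusSeq(prof), consensusSeq(back))
})

test_that("column statistics match their closed forms", {
  # point-mass emission against uniform background: log2(20) bits
  prof <- buildProfile(c("C", "C", "C"), pseudocount = 0,
                       background = rep(1 / 20, 20))
  cs <- columnStats(c("C", "C", "C"), prof)
  expect_equal(cs$information_content, log2(20), tolerance = 1e-12)
  expect_equal(cs$occupancy, 1)

  # emission equal to background: zero information
  bgprof <- new("ProfileHMM",
                matchEmis = matrix(BACKGROUND_FREQS, 1, 20, byrow = TRUE,
                                   dimnames = list(NULL, AA_ALPHABET20)),
                insEmis = matrix(BACKGROUND_FREQS, 1, 20, byrow = TRUE,
                                 dimnames = list(NULL, AA_ALPHABET20)),
                entry = 1,
                transM = matrix(c(0, 0, 0, 1), 1, 4,
                                dimnames = list(NULL, c("mm", "mi", "md", "me"))),
                transI = matrix(c(1, 0), 1, 2,
                                dimnames = list(NULL, c("im", "ii"))),
                transD = matrix(c(1, 0), 1, 2,
                                dimnames = list(NULL, c("dm", "dd"))),
                background = unname(BACKGROUND_FREQS), consensus = "L")
  cs0 <- columnStats(c("A", "A"), bgprof)
  expect_equal(cs0$information_content, 0, tolerance = 1e-12)
})

test_that("expected insert length is the geometric mean of the self-transition", {
  cfg <- syntheticConfig()
  set.seed(8)
  prof <- buildProfile(replicate(10, generateRepeatModule(cfg)))
  prof@transI[1, ] <- c(0.5, 0.5)
  cs <- columnStats(replicate(10, generateRepeatModule(cfg)), prof)
  expect_equal(cs$expected_insert_length[1], 2.0)
  expect_equal(cs$insert_probability, unname(prof@transM[, "mi"]))
})
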