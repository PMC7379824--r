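test_that("a single-state, single-residue hit scores its hand-computed log-odds", {
  prof <- toyProfile("C")
  v <- viterbiScore(prof, "C")
  expect_equal(v$bit_score, log2(20), tolerance = 1e-12)
  expect_equal(unname(v$envelope), c(0L, 1L))
  expect_equal(unname(v$path[, "state"]), 1L)     # one match state
  expect_equal(forwardScore(prof, "C"), v$bit_score, tolerance = 1e-12)
})

test_that("unknown residues score at background and empty input errors", {
  prof <- toyProfile("C")
  expect_equal(viterbiScore(prof, "X")$bit_score, 0, tolerance = 1e-12)
  expect_equal(viterbiScore(prof, "CXB")$bit_score, log2(20),
               tolerance = 1e-12)
  expect_error(viterbiScore(prof, ""), "non-empty")
  expect_error(forwardScore(prof, ""), "non-empty")
})

test_that("Viterbi and forward agree with exhaustive path enumeration", {
  set.seed(101)
  for (k in 1:60) {
    prof <- randomProfile(sample(1:4, 1))
    s <- randomSeq(sample(1:6, 1))
    sc <- enumPathScores(prof, s)
    expect_gt(length(sc), 0)
    expect_equal(viterbiScore(prof, s)$bit_score, max(sc),
                 tolerance = 1e-9)
    expect_equal(forwardScore(prof, s), log2sumexp(sc), tolerance = 1e-9)
  }
})

test_that("forward never falls below Viterbi", {
  set.seed(102)
  for (k in 1:40) {
    prof <- randomProfile(sample(2:6, 1))
    s <- randomSeq(sample(5:40, 1))
    expect_gte(forwardScore(prof, s) - viterbiScore(prof, s)$bit_score,
               -1e-9)
  }
})

test_that("profile-sampled sequences outscore background-sampled ones", {
  cfg <- syntheticConfig()
  set.seed(103)
  prof <- buildProfile(replicate(30, generateRepeatModule(cfg)))
  draws <- 300
  from_profile <- replicate(draws, {
    viterbiScore(prof, generateRepeatModule(cfg))$bit_score
  })
  from_bg <- replicate(draws, {
    viterbiScore(prof, randomSeq(nchar(cfg$module_consensus)))$bit_score
  })
  expect_gt(mean(from_profile), mean(from_bg))
  expect_gt(min(from_profile), max(from_bg))
})

test_that("calibration is deterministic and rejects degenerate scores", {
  cfg <- syntheticConfig()
  set.seed(107)
  prof <- buildProfile(replicate(15, generateRepeatModule(cfg)))
  p1 <- calibrateEvalues(prof, n_decoys = 120, decoy_lengths = 50, seed = 9)
  p2 <- calibrateEvalues(prof, n_decoys = 120, decoy_lengths = 50, seed = 9)
  expect_identical(p1, p2)
  expect_gt(p1$lambda, 0)
  expect_error(calibrateEvalues(prof, n_decoys = 50), ">= 100")

  # a background-emitting single-state profile scores every decoy 0
  flat <- toyProfile("C")
  flat@matchEmis[1, ] <- flat@background
  expect_error(calibrateEvalues(flat, n_decoys = 100, decoy_lengths = 30,
                                seed = 1), "variance")
})

test_that("the method-of-moments fit recovers known Gumbel parameters", {
  set.seed(104)
  fit <- fitGumbelMoments(rGumbel(1e5, mu = 5, lambda = 0.7))
  expect_lt(abs(fit$mu - 5), 0.05)
  expect_lt(abs(fit$lambda - 0.7), 0.02)
})

test_that("more decoys shrink the spread of recovered parameters", {
  set.seed(105)
  spread <- vapply(c(100, 800), function(n) {
    mus <- replicate(40, fitGumbelMoments(rGumbel(n, 5, 0.7))$mu)
    sd(mus)
  }, numeric(1))
  expect_lt(spread[2], spread[1])
})

test_that("E-values follow the Gumbel closed form and scale with database size", {
  params <- list(mu = 5, lambda = 0.7, n_decoys = 1000L)
  expect_equal(scoreToEvalue(5, params, 100), 100 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(scoreToEvalue(25, params, 1000), 8.315287e-4,
               tolerance = 1e-6)
  expect_equal(scoreToEvalue(1e6, params, 10), 0)
  # strictly decreasing in the bit score (away from saturation at db_size)
  ev <- scoreToEvalue(seq(0, 40, by = 0.5), params, 50)
  expect_true(all(diff(ev) < 0))
  # linear in db_size in the small-P regime
  e1 <- scoreToEvalue(20, params, 1)
  expect_lt(e1, 1e-3)
  expect_lt(abs(scoreToEvalue(20, params, 750) / (750 * e1) - 1), 1e-6)
})

test_that("a one-iteration search is a plain search against the seed profile", {
  sim <- generateProteome(smallConfig())
  prof <- buildProfile(sim$seed_msa)
  res <- iterativeSearch(prof, sim$proteins, iterations = 1, seed = 4)
  expect_length(iterationProfiles(res), 1L)
  h <- searchHits(res)
  # scores must equal direct seed-profile Viterbi scores
  for (k in seq_len(nrow(h))) {
    direct <- viterbiScore(prof,
                           as.character(sim$proteins)[[h$target_id[k]]])
    expect_equal(h$bit_score[k], direct$bit_score, tolerance = 1e-9)
  }
  expect_true(all(h$iteration_found == 1L))
})

test_that("the iterative search recovers implanted repeats with no background inclusions", {
  sim <- generateProteome(smallConfig())
  prof <- buildProfile(sim$seed_msa)
  res <- iterativeSearch(prof, sim$proteins, iterations = 3,
                         inclusion_e = 0.01, seed = 4)
  h <- searchHits(res)
  truth <- sim$truth$proteins
  implanted <- truth$protein_id[truth$category %in% c("repeat", "chimeric")]
  expect_setequal(h$target_id, implanted)
  expect_true(all(diff(h$e_value) >= 0))
  # per-protein module counts match the ground truth exactly
  ti <- sim$truth$implants
  truth_counts <- table(ti$protein_id[ti$implant_type == "repeat_module"])
  expect_equal(unname(h$repeat_count[match(names(truth_counts),
                                           h$target_id)]),
               unname(as.integer(truth_counts)))
})

test_that("searching the seed rows themselves includes every row", {
  sim <- generateProteome(smallConfig())
  prof <- buildProfile(sim$seed_msa)
  res <- iterativeSearch(prof, sim$seed_msa, iterations = 1,
                         inclusion_e = 0.01, seed = 2)
  expect_setequal(searchHits(res)$target_id, names(sim$seed_msa))
})

test_that("degenerate searches fail or warn as contracted", {
  cfg <- syntheticConfig()
  set.seed(106)
  prof <- buildProfile(replicate(15, generateRepeatModule(cfg)))
  expect_error(iterativeSearch(prof, character(0)), "empty")
  db <- setNames(vapply(1:5, function(i) randomSeq(30), character(1)),
                 paste0("r", 1:5))
  expect_warning(res <- iterativeSearch(prof, db, inclusion_e = 1e-30,
                                        seed = 2),
                 "no target")
  expect_equal(nrow(searchHits(res)), 0L)
})

test_that("hit tables survive the 1-based file convention round trip", {
  sim <- generateProteome(smallConfig())
  prof <- buildProfile(sim$seed_msa)
  res <- iterativeSearch(prof, sim$proteins, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHits(res, path)
  back <- readHits(path)
  h <- searchHits(res)
  expect_identical(back$target_id, h$target_id)
  expect_identical(back$env_start, h$env_start)
  expect_identical(back$env_end, h$env_end)
  expect_equal(back$e_value, h$e_value, tolerance = 1e-12)
  expect_identical(back$repeat_count, h$repeat_count)
})
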