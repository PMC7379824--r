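test_that("a single implanted family instance is annotated at its truth interval", {
  cfg <- smallConfig()
  lib <- generateProteome(cfg)$library
  fam <- getFamily(lib, "SYNF001")
  set.seed(21)
  flank1 <- randomSeq(30)
  protein <- paste0(flank1, fam@consensus, randomSeq(40))
  ann <- scanDomains(c(P1 = protein), lib, report_e = 1e-3, seed = 3)
  expect_equal(nrow(ann), 1L)
  expect_identical(ann$family_id, "SYNF001")
  expect_lte(abs(ann$start - 30L), 3L)
  expect_lte(abs(ann$end - (30L + nchar(fam@consensus))), 3L)
})

test_that("background proteins yield no annotations at a strict threshold", {
  lib <- generateProteome(smallConfig())$library
  set.seed(22)
  bg <- setNames(vapply(1:5, function(i) randomSeq(250), character(1)),
                 paste0("B", 1:5))
  ann <- scanDomains(bg, lib, report_e = 1e-5, seed = 3)
  expect_equal(nrow(ann), 0L)
})

test_that("a chimeric protein is annotated with both families in N-to-C order", {
  sim <- generateProteome(smallConfig())
  ann <- scanDomains(sim$proteins["CHM0001"], sim$library, seed = 3)
  ann <- resolveOverlaps(ann)
  expect_equal(ann$family_id, c("SYNF001", "SYNF002"))
  truth <- sim$truth$implants
  dom <- truth[truth$protein_id == "CHM0001" &
                 truth$implant_type == "domain", ]
  dom <- dom[order(dom$start), ]
  expect_true(all(abs(ann$start - dom$start) <= 3))
  expect_true(all(abs(ann$end - dom$end) <= 3))
})

test_that("overlap resolution keeps disjoint hits and drops dominated ones", {
  two <- data.frame(protein_id = "P", family_id = c("A", "B"),
                    start = c(0L, 50L), end = c(40L, 90L),
                    e_value = c(1e-5, 1e-4), bit_score = c(30, 25))
  expect_equal(nrow(resolveOverlaps(two)), 2L)

  dup <- data.frame(protein_id = "P", family_id = c("A", "B"),
                    start = c(10L, 10L), end = c(60L, 60L),
                    e_value = c(1e-10, 1e-3), bit_score = c(80, 20))
  kept <- resolveOverlaps(dup)
  expect_equal(nrow(kept), 1L)
  expect_identical(kept$family_id, "A")
})

test_that("greedy overlap resolution matches the exhaustive-subset oracle", {
  set.seed(23)
  for (case in 1:12) {
    n <- sample(3:5, 1)
    starts <- sample(0:60, n)
    ann <- data.frame(
      protein_id = sample(c("P", "Q"), n, replace = TRUE),
      family_id = paste0("F", seq_len(n)),
      start = starts,
      end = starts + sample(10:40, n, replace = TRUE),
      e_value = 10^-sample(2:12, n, replace = TRUE),
      bit_score = round(runif(n, 10, 90), 1))
    got <- resolveOverlaps(ann)
    want <- resolveOracle(ann)
    key <- function(d) paste(d$protein_id, d$family_id, d$start, d$end)
    expect_setequal(key(got), key(want))
    # every discarded annotation overlaps a kept one
    dropped <- ann[!key(ann) %in% key(got), , drop = FALSE]
    for (i in seq_len(nrow(dropped))) {
      same <- got[got$protein_id == dropped$protein_id[i], , drop = FALSE]
      expect_true(any(same$start < dropped$end[i] &
                        same$end > dropped$start[i]))
    }
  }
})

test_that("overlap resolution is order-independent", {
  set.seed(24)
  n <- 6
  starts <- sample(0:50, n)
  ann <- data.frame(protein_id = "P", family_id = paste0("F", 1:n),
                    start = starts, end = starts + 25L,
                    e_value = 10^-sample(3:9, n, replace = TRUE),
                    bit_score = runif(n, 20, 60))
  ref <- resolveOverlaps(ann)
  for (k in 1:5) {
    perm <- ann[sample(n), , drop = FALSE]
    expect_identical(resolveOverlaps(perm), ref)
  }
})

test_that("domain tables convert coordinates and reject malformed rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tfamily_id\tstart\tend\te_value",
               "P1\tPF00959\t10\t60\t1e-12"), path)
  ann <- readDomainTable(path)
  expect_equal(ann$start, 9L)
  expect_equal(ann$end, 60L)

  writeLines("protein_id\tfamily_id\tstart\tend\te_value", path)
  expect_equal(nrow(readDomainTable(path)), 0L)

  writeLines(c("protein_id\tfamily_id\tstart\te_value", "P1\tF\t1\t1e-3"),
             path)
  expect_error(readDomainTable(path), "missing column")

  writeLines(c("protein_id\tfamily_id\tstart\tend\te_value",
               "P1\tF\t10\tsixty\t1e-3"), path)
  expect_error(readDomainTable(path), "line\\(s\\) 2")

  writeLines(c("protein_id\tfamily_id\tstart\tend\te_value",
               "P1\tF\t60\t10\t1e-3"), path)
  expect_error(readDomainTable(path), "end < start")
})

test_that("scan results round-trip through the annotation table format", {
  sim <- generateProteome(smallConfig())
  ann <- scanDomains(sim$proteins["CHM0001"], sim$library, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDomainTable(ann, path)
  back <- readDomainTable(path)
  expect_identical(back$protein_id, ann$protein_id)
  expect_identical(back$family_id, ann$family_id)
  expect_identical(back$start, ann$start)
  expect_identical(back$end, ann$end)
  expect_equal(back$e_value, ann$e_value, tolerance = 1e-12)
})

test_that("domain libraries round-trip through JSON with classifications intact", {
  lib <- generateProteome(smallConfig())$library
  path <- withr::local_tempfile(fileext = ".json")
  writeDomainLibrary(lib, path)
  back <- readDomainLibrary(path)
  expect_identical(familyIds(back), familyIds(lib))
  for (id in familyIds(lib)) {
    a <- getFamily(lib, id); b <- getFamily(back, id)
    expect_identical(a@consensus, b@consensus)
    expect_identical(a@functionTags, b@functionTags)
    expect_identical(a@carrierLineages, b@carrierLineages)
    expect_identical(a@donorPhylum, b@donorPhylum)
  }
  expect_identical(classifyLibrary(back), classifyLibrary(lib))
})
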