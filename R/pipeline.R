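## pipeline_cli: orchestrate simulate -> build-profile -> search ->
## scan-domains -> classify -> call-hgt -> summarize as one reproducible
## run with config validation, logging and a checksum manifest.

#' Default run configuration
#'
#' @param out_dir Output directory for all stage products.
#' @param seed Integer seed governing every stochastic stage.
#' @param iterations,inclusion_e Search parameters.
#' @param report_e Domain-scan reporting threshold.
#' @param match_occ,pseudocount Profile-construction parameters.
#' @param max_e Foreign-hit E-value ceiling.
#' @param synthetic A `SyntheticConfig` for the simulate stage (its seed
#'   is overridden by `seed`).
#' @param stages Named logical vector enabling stages.
#' @return A `RunConfig` (list with class attribute).
#' @export
runConfig <- function(out_dir, seed = 42L, iterations = 3L,
                      inclusion_e = 0.01, report_e = 1e-3,
                      match_occ = 0.5, pseudocount = 1.0, max_e = 1e-5,
                      synthetic = NULL,
                      stages = c(simulate = TRUE, build_profile = TRUE,
                                 search = TRUE, scan_domains = TRUE,
                                 classify = TRUE, call_hgt = TRUE,
                                 summarize = TRUE)) {
  if (is.null(synthetic)) synthetic <- syntheticConfig(seed = seed)
  synthetic$seed <- as.integer(seed)
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              iterations = as.integer(iterations),
              inclusion_e = inclusion_e, report_e = report_e,
              match_occ = match_occ, pseudocount = pseudocount,
              max_e = max_e, synthetic = synthetic, stages = stages)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the [runConfig()] arguments; a `synthetic` section
#' overrides synthetic-generator fields.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `RunConfig`.
#' @export
readRunConfig <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  syn <- do.call(syntheticConfig, y$synthetic %||% list())
  args <- y[setdiff(names(y), "synthetic")]
  args$synthetic <- syn
  if (!is.null(out_dir)) args$out_dir <- out_dir
  if (!is.null(args$stages)) args$stages <- unlist(args$stages)
  do.call(runConfig, args)
}

#' Validate a run configuration
#'
#' @param config A `RunConfig`.
#' @return Character vector of problems (empty when valid). Unreadable
#'   files are reported as problems, not errors.
#' @export
validateRunConfig <- function(config) {
  problems <- character(0)
  add <- function(p) problems <<- c(problems, p)
  if (is.null(config$out_dir) || !nzchar(config$out_dir)) {
    add("out_dir is not set")
  }
  if (config$inclusion_e <= 0) add("inclusion_e must be > 0")
  if (config$report_e <= 0) add("report_e must be > 0")
  if (config$iterations < 1) add("iterations must be >= 1")
  if (config$match_occ <= 0 || config$match_occ > 1) {
    add("match_occ must be in (0, 1]")
  }
  st <- config$stages
  p <- function(f) file.path(config$out_dir, f)
  needFile <- function(stage, file, producer) {
    if (isTRUE(st[[stage]]) && !isTRUE(st[[producer]]) &&
        !file.exists(p(file))) {
      add(sprintf("stage %s enabled but %s is missing and stage %s disabled",
                  stage, file, producer))
    }
  }
  needFile("build_profile", "seed_modules.afa", "simulate")
  needFile("search", "profile.json", "build_profile")
  needFile("search", "proteins.fasta", "simulate")
  needFile("scan_domains", "proteins.fasta", "simulate")
  needFile("scan_domains", "library.json", "simulate")
  needFile("call_hgt", "hits.tsv", "search")
  needFile("call_hgt", "domains.tsv", "scan_domains")
  needFile("call_hgt", "taxonomy.tsv", "simulate")
  needFile("call_hgt", "donors.fasta", "simulate")
  needFile("summarize", "hits.tsv", "search")
  tryCatch(validateSyntheticConfig(config$synthetic),
           error = function(e) add(conditionMessage(e)))
  problems
}

#' Run the full screen
#'
#' Executes the enabled stages in order, failing fast with the failing
#' stage named, and writes `manifest.json` last: tool version, config
#' hash, per-stage output checksums and wall-clock seconds, and the
#' seed. Re-running with an identical config and seed reproduces
#' identical output checksums.
#'
#' @param config A `RunConfig`.
#' @return The manifest (list), invisibly.
#' @export
runPipeline <- function(config) {
  problems <- validateRunConfig(config)
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$out_dir, f)
  st <- config$stages
  manifest <- list(
    tool = "CRRscreen",
    version = as.character(utils::packageVersion("CRRscreen")),
    seed = config$seed,
    config_hash = configHash(config),
    status = "failed",
    stages = list())

  runStage <- function(name, fn) {
    if (!isTRUE(st[[name]])) return(invisible(NULL))
    screenLog("info", "stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fn(), error = function(e) {
      manifest$status <<- "failed"
      writeManifest(manifest, p("manifest.json"))
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      wall_clock_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = fileChecksums(outputs))
    invisible(NULL)
  }

  runStage("simulate", function() {
    sim <- generateProteome(config$synthetic)
    writeProteome(sim, config$out_dir)
  })
  runStage("build_profile", function() {
    msa <- readModuleAlignment(p("seed_modules.afa"))
    prof <- buildProfile(msa, match_occ = config$match_occ,
                         pseudocount = config$pseudocount)
    writeProfile(prof, p("profile.json"))
    writeColumnStats(columnStats(msa, prof), p("column_stats.tsv"))
    c(p("profile.json"), p("column_stats.tsv"))
  })
  runStage("search", function() {
    prof <- readProfile(p("profile.json"))
    db <- Biostrings::readAAStringSet(p("proteins.fasta"))
    res <- iterativeSearch(prof, db, iterations = config$iterations,
                           inclusion_e = config$inclusion_e,
                           pseudocount = config$pseudocount,
                           seed = config$seed)
    writeHits(res, p("hits.tsv"))
    for (i in seq_along(iterationProfiles(res))) {
      writeProfile(iterationProfiles(res)[[i]],
                   p(sprintf("profile_iter%d.json", i)))
    }
    c(p("hits.tsv"),
      p(sprintf("profile_iter%d.json", seq_along(iterationProfiles(res)))))
  })
  runStage("scan_domains", function() {
    db <- Biostrings::readAAStringSet(p("proteins.fasta"))
    lib <- readDomainLibrary(p("library.json"))
    hits <- if (file.exists(p("hits.tsv"))) readHits(p("hits.tsv")) else NULL
    targets <- if (!is.null(hits) && nrow(hits)) {
      db[names(db) %in% hits$target_id]
    } else db
    ann <- scanDomains(targets, lib, report_e = config$report_e,
                       seed = config$seed)
    writeDomainTable(resolveOverlaps(ann), p("domains.tsv"))
    p("domains.tsv")
  })
  runStage("classify", function() {
    lib <- readDomainLibrary(p("library.json"))
    cls <- classifyLibrary(lib)
    utils::write.table(cls, p("classifications.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p("classifications.tsv")
  })
  runStage("call_hgt", function() {
    db <- Biostrings::readAAStringSet(p("proteins.fasta"))
    hits <- readHits(p("hits.tsv"))
    ann <- readDomainTable(p("domains.tsv"))
    cls <- utils::read.delim(p("classifications.tsv"),
                             stringsAsFactors = FALSE)
    tax <- readTaxonomy(p("taxonomy.tsv"))
    donors <- Biostrings::readAAStringSet(p("donors.fasta"))
    calls <- screenHGT(db, unique(hits$target_id), ann, cls, tax,
                       donors, tax, max_e = config$max_e,
                       seed = config$seed)
    writeCalls(calls, p("calls.json"))
    p("calls.json")
  })
  runStage("summarize", function() {
    hits <- readHits(p("hits.tsv"))
    ann <- if (file.exists(p("domains.tsv"))) {
      readDomainTable(p("domains.tsv"))
    } else {
      data.frame(protein_id = character(0), family_id = character(0),
                 start = integer(0), end = integer(0),
                 e_value = numeric(0), bit_score = numeric(0))
    }
    cls <- if (file.exists(p("classifications.tsv"))) {
      utils::read.delim(p("classifications.tsv"), stringsAsFactors = FALSE)
    } else {
      data.frame(family_id = character(0), label = character(0),
                 cell_wall_hydrolase = logical(0))
    }
    tax <- readTaxonomy(p("taxonomy.tsv"))
    stats <- aggregateStats(unique(hits$target_id), ann, cls, tax)
    writeSummary(stats, p("summary.json"))
    p("summary.json")
  })

  manifest$status <- "ok"
  writeManifest(manifest, p("manifest.json"))
  screenLog("info", "run complete: ", p("manifest.json"))
  invisible(manifest)
}

configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(rapply(unclass(config), identity, how = "replace"), tmp)
  # serialisation is version-stable enough for a same-session identity
  # check; the manifest's purpose is detecting config drift between runs
  unname(tools::md5sum(tmp))
}

fileChecksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  sums <- tools::md5sum(paths)
  stats::setNames(as.list(unname(sums)), basename(paths))
}

writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
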