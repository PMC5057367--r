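#' @include io.R
NULL

#' Read a run configuration from YAML
#'
#' Nested sections \code{simulate}, \code{fragmap}, \code{phasemap},
#' \code{varcall}, \code{filters}, \code{qc} plus top-level
#' \code{rng_seed}, \code{out_dir}, \code{library_id}. Unknown keys are
#' rejected.
#'
#' @param file YAML path; NULL gives the all-defaults configuration.
#' @param overrides named list merged over the file contents.
#' @return A nested list of configuration sections.
#' @export
lfrRunConfig <- function(file = NULL, overrides = list()) {
  cfg <- if (is.null(file)) list() else read_yaml(file)
  cfg <- utils::modifyList(cfg, overrides)
  known <- c("simulate", "fragmap", "phasemap", "varcall", "filters", "qc",
             "rng_seed", "out_dir", "library_id")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  knownSub <- list(
    simulate = slotNames("LfrSimParams"),
    fragmap = c("binSize", "minReadsPerBin", "maxGapBins",
                "minFragmentLength", "mode"),
    phasemap = c("minReads", "minWells", "maxContradictionFrac",
                 "minLinkSupport", "mode"),
    varcall = c("mu", "errorRate", "hetPrior", "minMarginDb",
                "minAltReads"),
    filters = c("requirePass", "minWellCount", "sharedFrac",
                "minBlockSnps"),
    qc = c("minBlockSnps", "minTotalSnps"))
  for (sec in names(knownSub)) {
    bad <- setdiff(names(cfg[[sec]]), knownSub[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  cfg
}

.cfgGet <- function(cfg, sec, key, default) {
  v <- if (is.null(sec)) cfg[[key]] else cfg[[sec]][[key]]
  if (is.null(v)) default else v
}

#' Run the full LFR pipeline
#'
#' Simulate (or load) a co-barcoded library, then run the first mapping /
#' coverage map / fragment calling, the second mapping / strong het
#' collection / allele assignment, phasing-aware variant calling, the
#' high-confidence filters and genome QC. All stage outputs are written
#' under \code{outDir} together with a manifest of md5 checksums and a run
#' log of every parameter in effect.
#'
#' @param config a configuration list from [lfrRunConfig()].
#' @param outDir output directory (created if needed).
#' @param seed integer seed overriding the configured \code{rng_seed}.
#' @param genome optionally a pre-built
#'   \code{\linkS4class{DiploidGenome}} shared between replicate
#'   libraries.
#' @param reads optionally an \code{\linkS4class{LfrReadSet}} to analyse
#'   instead of simulating (requires \code{reference}).
#' @param reference reference \code{DNAString} when \code{reads} is given.
#' @param libraryId integer id used in hapLink fields.
#' @param writeReads also write the (possibly large) reads TSV (default
#'   FALSE).
#' @return A list with all stage objects (\code{genome}, \code{reads},
#'   \code{covMap}, \code{fragMap}, \code{sm}, \code{strongHets},
#'   \code{phase}, \code{records}, \code{filtered}, \code{blocks},
#'   \code{metrics}) plus \code{files} (the manifest data.frame).
#' @export
runLfrPipeline <- function(config = lfrRunConfig(), outDir = NULL,
                           seed = NULL, genome = NULL, reads = NULL,
                           reference = NULL, libraryId = NULL,
                           writeReads = FALSE) {
  t0 <- Sys.time()
  logLines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...))
    logLines <<- c(logLines, line)
    message(line)
  }
  if (is.null(seed)) seed <- .cfgGet(config, NULL, "rng_seed", 1L)
  seed <- config$rng_seed <- as.integer(if (is.null(seed)) 1L else seed)
  if (is.null(libraryId))
    libraryId <- as.integer(.cfgGet(config, NULL, "library_id", 1L))

  simArgs <- config$simulate
  simArgs$rngSeed <- seed
  params <- do.call(lfrSimParams, if (is.null(simArgs)) list() else simArgs)

  truthFragments <- NULL
  if (is.null(reads)) {
    if (is.null(genome)) {
      note("simulating diploid genome (%g bp)", params@genomeLength)
      genome <- simulateDiploidGenome(params, seed = seed)
    }
    note("simulating library (seed %d)", seed)
    lib <- simulateLibrary(genome, params, seed = seed + 1L)
    truthFragments <- lib$fragments
    reads <- lib$reads
    reference <- refSeq(genome)
  } else if (is.null(reference)) {
    stop("reads without a reference: supply `reference`")
  }
  g <- length(reference)
  note("library: %d mate-pairs in %d wells", length(reads), reads@nWells)

  mode1 <- .cfgGet(config, "fragmap", "mode", "fast")
  placed <- firstMap(reads, reference, mode = mode1)
  note("first mapping (%s): %d placed", mode1, nrow(placed))
  covMap <- buildCoverageMap(placed,
                             binSize = .cfgGet(config, "fragmap", "binSize",
                                               1000L),
                             nWells = reads@nWells, genomeLength = g)
  sp <- streakParams(
    minReadsPerBin = .cfgGet(config, "fragmap", "minReadsPerBin", 2L),
    maxGapBins = .cfgGet(config, "fragmap", "maxGapBins", 4L),
    minFragmentLength = .cfgGet(config, "fragmap", "minFragmentLength",
                                10000L))
  fragMap <- callFragments(covMap, sp)
  note("fragment map: %d fragments, %.1f cells of DNA",
       length(fragMap), cellsOfDna(fragMap, g))

  sm <- secondMap(reads, fragMap, reference,
                  mode = .cfgGet(config, "phasemap", "mode", "fast"))
  note("second mapping: %d placed, %d discordant bases",
       sm$counters[["placed"]], sm$counters[["discordantBases"]])
  sh <- strongHetSites(sm, reference,
                       minReads = .cfgGet(config, "phasemap", "minReads",
                                          NULL),
                       minWells = .cfgGet(config, "phasemap", "minWells",
                                          NULL))
  note("strong het sites: %d", length(sh))
  phase <- assignAlleles(sm, sh, fragMap,
                         maxContradictionFrac =
                           .cfgGet(config, "phasemap",
                                   "maxContradictionFrac", 0.25),
                         minLinkSupport = .cfgGet(config, "phasemap",
                                                  "minLinkSupport", 2L))
  note("phased contigs: %d (N50 %.0f kb)", length(phasedContigs(phase)),
       contigStats(phase)$n50Bp / 1000)

  records <- callVariants(
    sm, phase, reference,
    mu = .cfgGet(config, "varcall", "mu", 0.01),
    errorRate = .cfgGet(config, "varcall", "errorRate",
                        params@perBaseErrorRate),
    hetPrior = .cfgGet(config, "varcall", "hetPrior", 0.001),
    minMarginDb = .cfgGet(config, "varcall", "minMarginDb", 10),
    minAltReads = .cfgGet(config, "varcall", "minAltReads", NULL),
    libraryId = libraryId)
  note("variant records: %d (%d het)", nrow(records),
       sum(records$genotype == "het"))

  fcfg <- filterConfig(
    requirePass = .cfgGet(config, "filters", "requirePass", TRUE),
    minWellCount = .cfgGet(config, "filters", "minWellCount", 6L),
    sharedFrac = .cfgGet(config, "filters", "sharedFrac", 0.25),
    minBlockSnps = .cfgGet(config, "filters", "minBlockSnps", 10L))
  filtered <- applyHaplotypeFilters(records, fcfg)
  blocks <- haplotypeBlocks(filtered$kept, fcfg$minBlockSnps)
  note("filters: %d kept, %d rejected; %d haplotype blocks",
       nrow(filtered$kept), nrow(filtered$rejected), length(blocks))

  metrics <- genomeMetrics(filtered$kept, blocks, fragMap, g, sm = sm)
  note("phasing rate %.4f, N50 %.0f kb", metrics$phasingRate,
       metrics$n50Kb)

  files <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(outDir, x)
    if (!is.null(genome)) writeTruthVcf(genome, fp("truth.vcf"))
    if (!is.null(truthFragments))
      writeFragmentBed(truthFragments, fp("truth_fragments.bed"))
    if (writeReads) writeReadsTsv(reads, fp("reads.tsv"))
    writeCoverageTsv(covMap, fp("coverage_map.tsv"))
    writeFragmentBed(fragMap, fp("fragments_unphased.bed"))
    writeFragmentBed(phase@fragments, fp("fragments_phased.bed"))
    writeContigsTsv(phase, fp("phased_contigs.tsv"))
    writeVarTsv(records,
                fp(sprintf("var-GS%06d-ASM.tsv_with_wellcount_exc.txt",
                           libraryId)))
    writeVarTsv(filtered$kept, fp("var-highconfidence.tsv"))
    writeLfrVcf(records, fp("variants.vcf"), g,
                sampleId = sprintf("LFR_%03d", libraryId))
    writeReportJson(metrics, fp("qc_metrics.json"))
    writeLines(logLines, fp("run.log"))
    write_yaml(config, fp("config_used.yaml"))
    paths <- list.files(outDir, full.names = TRUE)
    paths <- setdiff(paths, fp("manifest.tsv"))
    files <- data.frame(file = basename(paths),
                        md5 = unname(md5sum(paths)),
                        bytes = file.size(paths))
    write.table(files, fp("manifest.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  list(params = params, genome = genome, truthFragments = truthFragments,
       reads = reads, placed = placed, covMap = covMap, fragMap = fragMap,
       sm = sm, strongHets = sh, phase = phase, records = records,
       filtered = filtered, blocks = blocks, metrics = metrics,
       files = files, log = logLines)
}
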