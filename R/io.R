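#' @include qc.R
NULL

## var-TSV dialect: fixed header, one row per variant site. Field names
## follow the LFR variant-file convention, including the verbatim
## "ecxclusiveWellCount" spelling.
.VAR_TSV_COLS <- c("position", "ref", "alt", "genotype", "varFilter",
                   "hapLink", "phase", "contig", "wellCount", "refWellCount",
                   "wellIDs", "ecxclusiveWellCount", "SharedWellCount",
                   "MinExclusiveWellCountInThisLocus",
                   "MaxExclusiveWellCountInThisLocus", "nReads",
                   "nAltReads", "marginDb")

#' Write / read LFR variant records as var-TSV
#'
#' Tab-separated dialect of the LFR variant file carrying the well-count
#' fields (canonical file name pattern
#' \code{var-*-ASM.tsv_with_wellcount_exc.txt}). Positions are 1-based.
#' \code{readVarTsv} refuses files whose header does not match the dialect.
#'
#' @param records variant records from [callVariants()].
#' @param file output path.
#' @return \code{writeVarTsv} returns \code{file} invisibly;
#'   \code{readVarTsv} returns the records data.frame.
#' @export
writeVarTsv <- function(records, file) {
  df <- records[, .VAR_TSV_COLS, drop = FALSE]
  fwrite(df, file, sep = "\t", quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname writeVarTsv
#' @export
readVarTsv <- function(file) {
  hdr <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, .VAR_TSV_COLS))
    stop("not an LFR var-TSV file (unexpected header): ", file)
  df <- as.data.frame(fread(file, sep = "\t", header = TRUE,
                            colClasses = list(character = c(
                              "ref", "alt", "genotype", "varFilter",
                              "hapLink", "wellIDs"))))
  df$hapLink[is.na(df$hapLink)] <- ""
  df$wellIDs[is.na(df$wellIDs)] <- ""
  df
}

#' Write / read reads as TSV
#'
#' Interchange format for co-barcoded mate-pairs: columns \code{well},
#' \code{arm1_pos}, \code{arm2_pos} (0-based leftmost), \code{arm1_bases},
#' \code{arm2_bases}, \code{fragment_id} (truth provenance; NA when
#' unknown).
#'
#' @param reads an \code{\linkS4class{LfrReadSet}}.
#' @param file path.
#' @param nWells,gapMin,gapMax library geometry for \code{readReadsTsv}
#'   (wells default to the maximum well id seen; the gap range defaults to
#'   the observed range).
#' @return \code{writeReadsTsv} returns \code{file} invisibly;
#'   \code{readReadsTsv} an \code{LfrReadSet}.
#' @export
writeReadsTsv <- function(reads, file) {
  fwrite(data.table(well = reads@well, arm1_pos = reads@arm1Pos,
                    arm2_pos = reads@arm2Pos, arm1_bases = reads@arm1,
                    arm2_bases = reads@arm2, fragment_id = reads@fragmentId),
         file, sep = "\t", quote = FALSE, na = "NA")
  invisible(file)
}

#' @rdname writeReadsTsv
#' @export
readReadsTsv <- function(file, nWells = NULL, gapMin = NULL, gapMax = NULL) {
  hdr <- strsplit(readLines(file, n = 1L), "\t", fixed = TRUE)[[1]]
  need <- c("well", "arm1_pos", "arm2_pos", "arm1_bases", "arm2_bases")
  if (!all(need %in% hdr))
    stop("not a reads TSV (missing columns): ", file)
  df <- as.data.frame(fread(file, sep = "\t", header = TRUE))
  armLen <- if (nrow(df)) nchar(df$arm1_bases[1]) else 0L
  gap <- df$arm2_pos - (df$arm1_pos + armLen)
  if (is.null(gapMin)) gapMin <- if (length(gap)) min(gap) else 0L
  if (is.null(gapMax)) gapMax <- if (length(gap)) max(gap) else 0L
  if (is.null(nWells)) nWells <- if (nrow(df)) max(df$well) else 1L
  fid <- if ("fragment_id" %in% names(df)) df$fragment_id
    else rep(NA_integer_, nrow(df))
  new("LfrReadSet", well = as.integer(df$well),
      arm1Pos = as.integer(df$arm1_pos), arm2Pos = as.integer(df$arm2_pos),
      arm1 = as.character(df$arm1_bases), arm2 = as.character(df$arm2_bases),
      fragmentId = as.integer(fid), armLen = as.integer(armLen),
      nWells = as.integer(nWells),
      gapRange = as.integer(c(gapMin, gapMax)))
}

#' Write / read a fragment map as BED6
#'
#' One BED record per fragment (0-based half-open, as BED requires), name
#' \code{well<id>:<allele>} with allele \code{0}, \code{1} or \code{.}
#' when unassigned, score = mate-pair support (capped at 1000 per the BED
#' spec).
#'
#' @param x a \code{\linkS4class{FragmentMap}} or fragment \code{GRanges}
#'   (truth fragments use their haplotype as the allele).
#' @param file path.
#' @param genomeLength genome length (used when reading back).
#' @param binSize bin size recorded in the reconstructed map.
#' @return \code{writeFragmentBed} returns \code{file} invisibly;
#'   \code{readFragmentBed} a fragment \code{GRanges} with \code{well} and
#'   \code{allele} columns.
#' @export
writeFragmentBed <- function(x, file) {
  gr <- if (is(x, "FragmentMap")) fragments(x) else x
  alleleCol <- if ("allele" %in% names(mcols(gr))) mcols(gr)$allele
    else mcols(gr)$haplotype
  allele <- ifelse(is.na(alleleCol), ".", as.character(alleleCol))
  support <- if ("support" %in% names(mcols(gr))) mcols(gr)$support
    else rep(0, length(gr))
  df <- data.table(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = sprintf("well%d:%s", mcols(gr)$well, allele),
                   score = pmin(as.integer(support), 1000L),
                   strand = ".")
  fwrite(df, file, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname writeFragmentBed
#' @export
readFragmentBed <- function(file) {
  df <- as.data.frame(fread(file, sep = "\t", header = FALSE,
                            col.names = c("chrom", "start", "end", "name",
                                          "score", "strand")))
  m <- regmatches(df$name, regexec("^well([0-9]+):([01.])$", df$name))
  well <- as.integer(vapply(m, `[`, character(1), 2L))
  alleleChr <- vapply(m, `[`, character(1), 3L)
  allele <- rep(NA_integer_, length(alleleChr))
  hasAllele <- alleleChr != "."
  allele[hasAllele] <- as.integer(alleleChr[hasAllele])
  GRanges(df$chrom, IRanges(df$start + 1L, df$end),
          well = well, support = df$score, allele = allele)
}

#' Export the well coverage map as TSV
#'
#' Sparse triplet export: one row per non-empty (well, bin) cell.
#'
#' @param covMap a \code{\linkS4class{WellCoverageMap}}.
#' @param file path.
#' @export
writeCoverageTsv <- function(covMap, file) {
  m <- as(covMap@counts, "TsparseMatrix")
  dt <- data.table(well = m@i + 1L, bin = m@j, count = m@x)
  dt <- dt[order(dt$well, dt$bin), ]
  fwrite(dt, file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' Write variant records as a single-sample VCF 4.2
#'
#' GT is phased (\code{|}) with a PS tag equal to the phased contig id for
#' het calls inside a phased contig, and unphased (\code{/}) otherwise.
#' Well-count fields are carried as INFO keys \code{WC}, \code{RWC},
#' \code{EWC}, \code{SWC}, \code{MINEWC}, \code{MAXEWC}, \code{WIDS}.
#' The allele order in phased genotypes is haplotype0|haplotype1.
#'
#' @param records variant records from [callVariants()].
#' @param file path.
#' @param genomeLength genome length (contig header line).
#' @param sampleId sample column name.
#' @export
writeLfrVcf <- function(records, file, genomeLength,
                        sampleId = "LFR_SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lfrphase",
    sprintf("##contig=<ID=%s,length=%d>", .SEQNAME,
            as.integer(genomeLength)),
    "##INFO=<ID=WC,Number=1,Type=Integer,Description=\"Wells with reads calling the variant allele\">",
    "##INFO=<ID=RWC,Number=1,Type=Integer,Description=\"Wells with reads calling the reference allele\">",
    "##INFO=<ID=EWC,Number=1,Type=Integer,Description=\"Wells calling only the variant allele\">",
    "##INFO=<ID=SWC,Number=1,Type=Integer,Description=\"Wells calling both alleles\">",
    "##INFO=<ID=MINEWC,Number=1,Type=Integer,Description=\"Minimum exclusive well count at this locus\">",
    "##INFO=<ID=MAXEWC,Number=1,Type=Integer,Description=\"Maximum exclusive well count at this locus\">",
    "##INFO=<ID=WIDS,Number=1,Type=String,Description=\"Well ids calling the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (phased contig id)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t"))
  n <- nrow(records)
  lines <- hdr
  if (n) {
    phased <- records$genotype == "het" & !is.na(records$phase)
    gt <- character(n)
    gt[records$genotype == "hom"] <- "1/1"
    gt[records$genotype == "het" & !phased] <- "0/1"
    gt[phased] <- ifelse(records$phase[phased] == 0L, "1|0", "0|1")
    ps <- ifelse(phased, as.character(records$contig), NA)
    fmt <- ifelse(phased, "GT:PS", "GT")
    sample <- ifelse(phased, paste0(gt, ":", ps), gt)
    wids <- gsub(";", ",", records$wellIDs)
    wids[wids == ""] <- "."
    info <- sprintf("WC=%d;RWC=%d;EWC=%d;SWC=%d;MINEWC=%d;MAXEWC=%d;WIDS=%s",
                    records$wellCount, records$refWellCount,
                    records$ecxclusiveWellCount, records$SharedWellCount,
                    records$MinExclusiveWellCountInThisLocus,
                    records$MaxExclusiveWellCountInThisLocus, wids)
    lines <- c(lines, paste(.SEQNAME, records$position, ".",
                            records$ref, records$alt, ".",
                            records$varFilter, info, fmt, sample,
                            sep = "\t"))
  }
  writeLines(lines, file)
  invisible(file)
}

#' Write the simulated truth haplotypes as a phased VCF
#'
#' All truth variants are emitted fully phased (\code{|}, PS=1): the
#' simulator's haplotypes are globally consistent.
#'
#' @param genome a \code{\linkS4class{DiploidGenome}}.
#' @param file path.
#' @export
writeTruthVcf <- function(genome, file) {
  v <- variantSites(genome)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=lfrphase-simulator",
           sprintf("##contig=<ID=%s,length=%d>", .SEQNAME,
                   length(refSeq(genome))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "TRUTH", sep = "\t"))
  gt <- c(het_hap0_alt = "1|0", het_hap1_alt = "0|1", hom_alt = "1|1")[
    mcols(v)$gt]
  lines <- c(hdr, paste(.SEQNAME, GenomicRanges::start(v), ".",
                        mcols(v)$ref, mcols(v)$alt, ".", "PASS", ".",
                        "GT:PS", paste0(gt, ":1"), sep = "\t"))
  writeLines(lines, file)
  invisible(file)
}

#' Write reads as paired FASTQ
#'
#' Unaligned paired FASTQ with the well id encoded in the read name
#' (\code{@read<i>_well<w>/1} and \code{/2}); constant placeholder
#' qualities (the simulator does not model base-quality scores).
#'
#' @param reads an \code{\linkS4class{LfrReadSet}}.
#' @param file1,file2 output paths for the two arm files.
#' @export
writeReadsFastq <- function(reads, file1, file2) {
  n <- length(reads)
  ids <- sprintf("read%d_well%d", seq_len(n), reads@well)
  qual <- strrep("I", reads@armLen)
  writeLines(paste0("@", ids, "/1\n", reads@arm1, "\n+\n", qual), file1)
  writeLines(paste0("@", ids, "/2\n", reads@arm2, "\n+\n", qual), file2)
  invisible(c(file1, file2))
}

#' Write phased contigs as TSV
#'
#' @param phase a \code{\linkS4class{PhaseResult}}.
#' @param file path.
#' @export
writeContigsTsv <- function(phase, file) {
  ctg <- phasedContigs(phase)
  fwrite(data.table(contig_id = mcols(ctg)$contigId,
                    start = GenomicRanges::start(ctg) - 1L,
                    end = GenomicRanges::end(ctg),
                    n_sites = mcols(ctg)$nSites,
                    contradiction_count = mcols(ctg)$contradictions,
                    n_fragments = mcols(ctg)$nFragments),
         file, sep = "\t", quote = FALSE)
  invisible(file)
}

#' Write a QC/discordance report as JSON
#'
#' @param report a list (e.g. from [genomeMetrics()]) or
#'   \code{lfrDiscordance} object.
#' @param file path.
#' @export
writeReportJson <- function(report, file) {
  x <- unclass(report)
  x$perBlock <- NULL
  write_json(x, file, auto_unbox = TRUE, digits = NA, pretty = TRUE,
             force = TRUE)
  invisible(file)
}
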