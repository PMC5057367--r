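#' @include filters.R
NULL

#' SNP phasing rate
#'
#' Fraction of heterozygous SNP records placed into retained haplotype
#' blocks: het records whose hapLink contig survives in \code{blocks},
#' divided by all het records.
#'
#' @param records LFR variant records (typically the kept set after
#'   [applyHaplotypeFilters()]).
#' @param blocks blocks from [haplotypeBlocks()]; when NULL, blocks are
#'   derived from \code{records} with the default minimum block size.
#' @return A fraction in \code{[0, 1]} (NaN when there are no het records).
#' @export
phasingRate <- function(records, blocks = NULL) {
  if (is.null(blocks)) blocks <- haplotypeBlocks(records)
  het <- records[records$genotype == "het", , drop = FALSE]
  if (!nrow(het)) return(NaN)
  if (!length(blocks)) return(0)
  keys <- sub("^Phased_([0-9]+)_([0-9]+)_[01]$", "\\1_\\2", het$hapLink)
  phased <- !is.na(het$hapLink) & het$hapLink != "" & keys %in% names(blocks)
  mean(phased)
}

#' Haplotype block N50
#'
#' Standard N50 over block spans (first to last SNP position), in kb.
#'
#' @param blocks blocks from [haplotypeBlocks()].
#' @return N50 in kb (0 for an empty block set).
#' @export
haplotypeN50 <- function(blocks) {
  spans <- vapply(blocks, function(b) as.numeric(attr(b, "spanBp")),
                  numeric(1))
  contigStats(spans)$n50Bp / 1000
}

#' Cells-worth of genomic DNA
#'
#' Total fragment length divided by twice the genome length: the number of
#' diploid genome equivalents represented by the (called or true)
#' fragments.
#'
#' @param fragmentsGr fragment \code{GRanges} or
#'   \code{\linkS4class{FragmentMap}}.
#' @param genomeLength genome length in bp.
#' @return Diploid genome equivalents (float).
#' @export
cellsOfDna <- function(fragmentsGr, genomeLength) {
  if (is(fragmentsGr, "FragmentMap")) fragmentsGr <- fragments(fragmentsGr)
  sum(as.numeric(GenomicRanges::width(fragmentsGr))) / (2 * genomeLength)
}

#' Replicate switch-discordance comparison
#'
#' Compares the phase of heterozygous SNPs in completely overlapping
#' blocks between two replicate libraries of the same genome. Blocks are
#' paired one-to-one, greedily by positional overlap. Within a block pair,
#' SNPs present in both blocks at identical positions with identical
#' ref/alt alleles are compared after choosing the relative orientation
#' (swap or not) that minimizes mismatches. Mismatching sites partition
#' into maximal runs: runs of length 1 are short switches (1 discordant
#' SNP each); runs of length >= 2 are one long switch event each (their
#' SNPs count in neither short tally). The short rate divides the total
#' number of discordant single SNPs, and the long rate the total number of
#' long switch events, by the total number of phased SNPs compared.
#'
#' @param blocksA,blocksB block sets from [haplotypeBlocks()], produced
#'   with identical filter settings.
#' @param minBlockSnps minimum shared SNPs for a block pair to be compared
#'   (default 10).
#' @param minTotalSnps comparisons with fewer total compared SNPs are
#'   flagged \code{belowThreshold} (default 1e6, the published reporting
#'   threshold; desk-scale comparisons will typically be flagged).
#' @return An object of class \code{lfrDiscordance}: a list with
#'   \code{nComparedBlocks}, \code{nPhasedSnpsCompared},
#'   \code{nDiscordantSnps}, \code{nLongSwitchEvents}, \code{shortRate},
#'   \code{longRate}, \code{belowThreshold}, and \code{perBlock} tallies
#'   (short/long event counts per block, binned 0 / 1 / 2-3 / >=4).
#' @export
compareReplicates <- function(blocksA, blocksB, minBlockSnps = 10L,
                              minTotalSnps = 1e6) {
  pairs <- .pairBlocks(blocksA, blocksB)
  shortSnps <- 0L; longEvents <- 0L; compared <- 0L
  perBlock <- data.frame(blockA = character(), blockB = character(),
                         nShared = integer(), nShort = integer(),
                         nLong = integer(), spanBp = numeric())
  for (p in pairs) {
    a <- blocksA[[p[1]]]; b <- blocksB[[p[2]]]
    mrg <- merge(a, b, by = "position", suffixes = c(".a", ".b"))
    mrg <- mrg[mrg$ref.a == mrg$ref.b & mrg$alt.a == mrg$alt.b, ,
               drop = FALSE]
    n <- nrow(mrg)
    if (n < minBlockSnps) next
    mrg <- mrg[order(mrg$position), ]
    d <- mrg$hap.a != mrg$hap.b
    if (sum(d) > n - sum(d)) d <- !d     # orientation alignment
    r <- rle(d)
    mlen <- r$lengths[r$values]
    nShort <- sum(mlen == 1L)
    nLong <- sum(mlen >= 2L)
    shortSnps <- shortSnps + nShort
    longEvents <- longEvents + nLong
    compared <- compared + n
    perBlock <- rbind(perBlock,
                      data.frame(blockA = p[1], blockB = p[2], nShared = n,
                                 nShort = nShort, nLong = nLong,
                                 spanBp = max(mrg$position) -
                                   min(mrg$position) + 1))
  }
  binned <- function(x) {
    c(`0` = sum(x == 0L), `1` = sum(x == 1L),
      `2-3` = sum(x >= 2L & x <= 3L), `>=4` = sum(x >= 4L))
  }
  structure(list(
    nComparedBlocks = nrow(perBlock),
    nPhasedSnpsCompared = compared,
    nDiscordantSnps = shortSnps,
    nLongSwitchEvents = longEvents,
    shortRate = if (compared > 0) shortSnps / compared else NA_real_,
    longRate = if (compared > 0) longEvents / compared else NA_real_,
    belowThreshold = compared < minTotalSnps,
    shortTally = binned(perBlock$nShort),
    longTally = binned(perBlock$nLong),
    perBlock = perBlock), class = "lfrDiscordance")
}

#' @export
print.lfrDiscordance <- function(x, ...) {
  cat(sprintf(paste0(
    "lfrDiscordance: %d block pairs, %d phased SNPs compared%s\n",
    "  short switches: %d (rate %.3g)\n",
    "  long switch events: %d (rate %.3g)\n"),
    x$nComparedBlocks, x$nPhasedSnpsCompared,
    if (x$belowThreshold) " [below reporting threshold]" else "",
    x$nDiscordantSnps,
    if (is.na(x$shortRate)) NA else x$shortRate,
    x$nLongSwitchEvents,
    if (is.na(x$longRate)) NA else x$longRate))
  invisible(x)
}

## One-to-one greedy pairing of blocks by positional overlap (bp).
.pairBlocks <- function(blocksA, blocksB) {
  if (!length(blocksA) || !length(blocksB)) return(list())
  rng <- function(b) c(min(b$position), max(b$position))
  ra <- lapply(blocksA, rng); rb <- lapply(blocksB, rng)
  cand <- list()
  for (i in names(blocksA)) for (j in names(blocksB)) {
    ov <- min(ra[[i]][2], rb[[j]][2]) - max(ra[[i]][1], rb[[j]][1]) + 1
    if (ov > 0) cand[[length(cand) + 1L]] <- list(i = i, j = j, ov = ov)
  }
  if (!length(cand)) return(list())
  ord <- order(-vapply(cand, `[[`, numeric(1), "ov"),
               vapply(cand, `[[`, character(1), "i"),
               vapply(cand, `[[`, character(1), "j"))
  usedA <- character(); usedB <- character()
  out <- list()
  for (k in ord) {
    i <- cand[[k]]$i; j <- cand[[k]]$j
    if (i %in% usedA || j %in% usedB) next
    usedA <- c(usedA, i); usedB <- c(usedB, j)
    out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

#' Genome-level quality metrics
#'
#' @param records LFR variant records.
#' @param blocks haplotype blocks from [haplotypeBlocks()].
#' @param fragMap the called \code{\linkS4class{FragmentMap}}.
#' @param genomeLength genome length in bp.
#' @param sm optional [secondMap()] result; when supplied, the genome call
#'   rate is estimated as the fraction of probe positions covered by at
#'   least one placed read.
#' @param probeSpacing spacing of call-rate probes in bp (default 997,
#'   co-prime with common bin sizes).
#' @return A list with \code{genomeCallRate}, \code{phasingRate},
#'   \code{n50Kb}, \code{meanFragmentLenKb}, \code{cellsOfDna},
#'   \code{hetHomRatio}, \code{tsTvRatio}, \code{nVariants}.
#' @export
genomeMetrics <- function(records, blocks, fragMap, genomeLength,
                          sm = NULL, probeSpacing = 997L) {
  callRate <- NA_real_
  if (!is.null(sm) && nrow(sm$placements)) {
    probes <- seq(1L, genomeLength, by = probeSpacing)
    arms <- GRanges(.SEQNAME,
                    IRanges(c(sm$placements$arm1Pos,
                              sm$placements$arm2Pos) + 1L,
                            width = sm$armLen))
    covered <- countOverlaps(GRanges(.SEQNAME, IRanges(probes, width = 1L)),
                             arms) > 0
    callRate <- mean(covered)
  }
  nHet <- sum(records$genotype == "het")
  nHom <- sum(records$genotype == "hom")
  isTs <- paste0(records$ref, records$alt) %in% c("AG", "GA", "CT", "TC")
  list(genomeCallRate = callRate,
       phasingRate = phasingRate(records, blocks),
       n50Kb = haplotypeN50(blocks),
       meanFragmentLenKb = if (length(fragments(fragMap)))
         mean(GenomicRanges::width(fragments(fragMap))) / 1000 else NA_real_,
       cellsOfDna = cellsOfDna(fragMap, genomeLength),
       hetHomRatio = if (nHom > 0) nHet / nHom else NA_real_,
       tsTvRatio = if (sum(!isTs) > 0) sum(isTs) / sum(!isTs) else NA_real_,
       nVariants = nrow(records))
}
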