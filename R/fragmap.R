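#' @include AllClasses.R
NULL

#' First mapping step: place mate-pairs on the reference
#'
#' Each placed pair is assigned a position equal to the average of the
#' 0-based leftmost positions of its two arms. In \code{"fast"} mode the
#' recorded arm positions are trusted (the simulator knows them). In
#' \code{"strict"} mode both arms are located by exact string search
#' against the reference; only pairs whose arms each occur exactly once and
#' whose mate gap lies in the configured range are kept, so pairs touching
#' repeats, or carrying any sequencing error, are dropped.
#'
#' @param reads an \code{\linkS4class{LfrReadSet}}.
#' @param reference a [Biostrings::DNAString] (required in strict mode).
#' @param mode \code{"fast"} or \code{"strict"}.
#' @return A data.frame of placements with columns \code{readId},
#'   \code{well}, \code{pos} (0-based pair position), \code{arm1Pos},
#'   \code{arm2Pos}; attribute \code{counters} tallies dropped pairs.
#' @export
firstMap <- function(reads, reference = NULL, mode = c("fast", "strict")) {
  mode <- match.arg(mode)
  armLen <- reads@armLen
  gapRange <- reads@gapRange
  if (mode == "fast") {
    keep <- seq_len(length(reads))
    a1 <- reads@arm1Pos
    a2 <- reads@arm2Pos
    counters <- c(input = length(reads), placed = length(reads),
                  nonUnique = 0L, noMatch = 0L, badGap = 0L)
  } else {
    if (is.null(reference))
      stop("strict mode requires the reference sequence")
    p1 <- .uniqueExactPos(reads@arm1, reference, armLen)
    p2 <- .uniqueExactPos(reads@arm2, reference, armLen)
    gap <- p2 - (p1 + armLen)
    ok <- !is.na(p1) & !is.na(p2) & p1 >= 0 & p2 >= 0 &
      !is.na(gap) & gap >= gapRange[1] & gap <= gapRange[2]
    counters <- c(input = length(reads), placed = sum(ok),
                  nonUnique = sum((!is.na(p1) & p1 == -1L) |
                                  (!is.na(p2) & p2 == -1L)),
                  noMatch = sum(is.na(p1) | is.na(p2)),
                  badGap = sum(!is.na(p1) & !is.na(p2) & p1 >= 0 & p2 >= 0 &
                               (gap < gapRange[1] | gap > gapRange[2])))
    keep <- which(ok)
    a1 <- p1[keep]
    a2 <- p2[keep]
  }
  out <- data.frame(readId = keep, well = reads@well[keep],
                    pos = (a1 + a2) %/% 2L,
                    arm1Pos = a1, arm2Pos = a2)
  attr(out, "counters") <- counters
  out
}

## 0-based position of the unique exact occurrence of each pattern;
## NA = no match, -1 = multiple matches.
.uniqueExactPos <- function(arms, reference, armLen) {
  dict <- PDict(DNAStringSet(arms))
  counts <- Biostrings::countPDict(dict, reference)
  m <- matchPDict(dict, reference)
  st <- startIndex(m)
  pos <- rep(NA_integer_, length(arms))
  one <- which(counts == 1L)
  pos[one] <- vapply(st[one], `[`, integer(1), 1L) - 1L
  pos[counts > 1L] <- -1L
  pos
}

#' Build the per-well coverage map
#'
#' Counts placed mate-pairs in \code{binSize}-wide bins per well:
#' \code{count[w, b] = #pairs with well w and floor(pos / binSize) = b}.
#'
#' @param placements placements from [firstMap()].
#' @param binSize bin width in bp (>= 100; default 1000).
#' @param nWells number of wells.
#' @param genomeLength genome length in bp.
#' @return A \code{\linkS4class{WellCoverageMap}}.
#' @export
buildCoverageMap <- function(placements, binSize = 1000L, nWells,
                             genomeLength) {
  if (binSize < 100L) stop("binSize must be >= 100")
  binSize <- as.integer(binSize)
  nBins <- as.integer(ceiling(genomeLength / binSize))
  if (nrow(placements)) {
    bin <- placements$pos %/% binSize
    m <- sparseMatrix(i = placements$well, j = bin + 1L, x = 1,
                      dims = c(nWells, nBins))
  } else {
    m <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(nWells, nBins))
  }
  new("WellCoverageMap", counts = as(m, "CsparseMatrix"),
      binSize = binSize, genomeLength = as.numeric(genomeLength))
}

#' Streak-calling parameters
#'
#' @param minReadsPerBin minimum mate-pairs for a bin to count as
#'   well-populated (default 2).
#' @param maxGapBins tolerated run of under-threshold bins inside a streak
#'   (default 4), allowing for missing coverage within a fragment.
#' @param minFragmentLength minimum retained fragment length in bp
#'   (default 10000; shorter fragments are discarded).
#' @return A named list of parameters.
#' @export
streakParams <- function(minReadsPerBin = 2L, maxGapBins = 4L,
                         minFragmentLength = 10000L) {
  stopifnot(minReadsPerBin >= 1, maxGapBins >= 0, minFragmentLength >= 0)
  list(minReadsPerBin = as.integer(minReadsPerBin),
       maxGapBins = as.integer(maxGapBins),
       minFragmentLength = as.integer(minFragmentLength))
}

#' Call fragments from the coverage map
#'
#' Within each well, maximal streaks of bins with count >=
#' \code{minReadsPerBin}, allowing interior gaps of at most
#' \code{maxGapBins} under-threshold bins, become fragments; streaks
#' spanning less than \code{minFragmentLength} are discarded. Fragment
#' extents are bin-quantized: \code{[startBin*binSize, (endBin+1)*binSize)}.
#'
#' @param covMap a \code{\linkS4class{WellCoverageMap}}.
#' @param params a [streakParams()] list.
#' @return A \code{\linkS4class{FragmentMap}} with fragments sorted by
#'   (well, start), alleles unassigned.
#' @export
callFragments <- function(covMap, params = streakParams()) {
  stopifnot(is(covMap, "WellCoverageMap"))
  if (params$minFragmentLength < covMap@binSize)
    stop("minFragmentLength must be >= binSize")
  m <- covMap@counts
  binSize <- covMap@binSize
  res <- vector("list", nrow(m))
  mT <- Matrix::t(m)   # bins in columns -> fast per-well slicing via dgCMatrix
  p <- mT@p
  ivals <- mT@i
  xvals <- mT@x
  for (w in seq_len(nrow(m))) {
    if (p[w + 1L] == p[w]) next
    sel <- (p[w] + 1L):p[w + 1L]
    bins <- ivals[sel]              # 0-based bin indices, ascending
    cnt <- xvals[sel]
    pop <- bins[cnt >= params$minReadsPerBin]
    if (!length(pop)) next
    brk <- which(diff(pop) > params$maxGapBins + 1L)
    sb <- pop[c(1L, brk + 1L)]
    eb <- pop[c(brk, length(pop))]
    lenBp <- (eb - sb + 1L) * binSize
    keep <- lenBp >= params$minFragmentLength
    if (!any(keep)) next
    sb <- sb[keep]; eb <- eb[keep]
    support <- vapply(seq_along(sb), function(k)
      sum(cnt[bins >= sb[k] & bins <= eb[k]]), numeric(1))
    res[[w]] <- data.frame(well = w, startBin = as.integer(sb),
                           endBin = as.integer(eb), support = support)
  }
  df <- do.call(rbind, res)
  if (is.null(df)) {
    fr <- GRanges(seqnames = character(), IRanges())
    mcols(fr) <- S4Vectors::DataFrame(well = integer(), support = numeric(),
                                      startBin = integer(),
                                      endBin = integer(),
                                      allele = integer())
  } else {
    df <- df[order(df$well, df$startBin), , drop = FALSE]
    fr <- GRanges(.SEQNAME,
                  IRanges(start = df$startBin * binSize + 1L,
                          end = pmin((df$endBin + 1L) * binSize,
                                     covMap@genomeLength)),
                  well = df$well, support = df$support,
                  startBin = df$startBin, endBin = df$endBin,
                  allele = NA_integer_)
  }
  new("FragmentMap", fragments = fr, binSize = binSize, params = params)
}

#' Fragment-length distribution diagnostics
#'
#' Called fragment lengths are left-truncated at \code{minFragmentLength};
#' by the memorylessness of the exponential the mean excess over the
#' truncation point estimates the decay length, so the estimator is
#' \code{mean(length - minFragmentLength)}. A Kolmogorov-Smirnov test
#' against that exponential is reported.
#'
#' @param x a \code{\linkS4class{FragmentMap}}, a fragment \code{GRanges},
#'   or a numeric vector of lengths in bp.
#' @param minFragmentLength truncation point in bp (taken from the map's
#'   params when \code{x} is a \code{FragmentMap}; 0 for raw lengths).
#' @return A list with \code{nFragments}, \code{meanLengthKb},
#'   \code{decayEstimateKb} and \code{ksPvalueVsExponential}.
#' @export
fragmentLengthStats <- function(x, minFragmentLength = NULL) {
  if (is(x, "FragmentMap")) {
    if (is.null(minFragmentLength))
      minFragmentLength <- x@params$minFragmentLength
    lens <- GenomicRanges::width(x@fragments)
  } else if (is(x, "GRanges")) {
    if (is.null(minFragmentLength)) minFragmentLength <- 0
    lens <- GenomicRanges::width(x)
  } else {
    if (is.null(minFragmentLength)) minFragmentLength <- 0
    lens <- as.numeric(x)
  }
  if (!length(lens))
    return(list(nFragments = 0L, meanLengthKb = NA_real_,
                decayEstimateKb = NA_real_,
                ksPvalueVsExponential = NA_real_))
  excess <- lens - minFragmentLength
  decayBp <- mean(excess)
  ks <- if (decayBp > 0 && length(lens) > 1) {
    suppressWarnings(ks.test(excess, "pexp", rate = 1 / decayBp))$p.value
  } else {
    0
  }
  list(nFragments = length(lens),
       meanLengthKb = mean(lens) / 1000,
       decayEstimateKb = decayBp / 1000,
       ksPvalueVsExponential = ks)
}

#' Fragment coverage histogram and Poisson fit
#'
#' Counts how many fragments overlap each of a set of probe positions and
#' compares the counts to the Poisson distribution whose mean is the
#' analytic coverage \code{total fragment bp / genome length}. Probes are
#' placed on a regular grid; the default spacing of three decay lengths
#' keeps neighbouring probes approximately independent.
#'
#' @param fragmentsGr fragment \code{GRanges} (truth or called) or a
#'   \code{FragmentMap}.
#' @param genomeLength genome length in bp.
#' @param probeSpacing distance between probe positions in bp (default
#'   3 x mean fragment length, floor 1000).
#' @return A list with the probe \code{counts} histogram (table), fitted
#'   \code{lambda}, chi-square \code{chisqPvalue} and \code{nProbes}.
#' @export
fragmentCoverageStats <- function(fragmentsGr, genomeLength,
                                  probeSpacing = NULL) {
  if (is(fragmentsGr, "FragmentMap")) fragmentsGr <- fragments(fragmentsGr)
  totalBp <- sum(as.numeric(GenomicRanges::width(fragmentsGr)))
  lambda <- totalBp / genomeLength
  if (is.null(probeSpacing)) {
    meanLen <- if (length(fragmentsGr))
      mean(GenomicRanges::width(fragmentsGr)) else genomeLength
    probeSpacing <- max(1000, 3 * meanLen)
  }
  probes <- seq(probeSpacing %/% 2, genomeLength - 1, by = probeSpacing)
  counts <- countOverlaps(GRanges(.SEQNAME, IRanges(probes + 1, width = 1L)),
                          fragmentsGr)
  pv <- .poissonGofPvalue(counts, lambda)
  list(counts = table(counts), lambda = lambda, chisqPvalue = pv,
       nProbes = length(probes))
}

## Chi-square goodness of fit of counts to Poisson(lambda), pooling cells
## so every expected count is >= 5. df = cells - 1 (lambda is analytic,
## not estimated from the probe counts).
.poissonGofPvalue <- function(counts, lambda) {
  n <- length(counts)
  if (n < 10 || lambda <= 0) return(NA_real_)
  kMax <- max(counts, qpois(0.9999, lambda))
  pk <- dpois(0:kMax, lambda)
  pk[kMax + 1L] <- pk[kMax + 1L] + ppois(kMax, lambda, lower.tail = FALSE)
  obs <- tabulate(counts + 1L, nbins = kMax + 1L)
  exp <- n * pk
  ## pool adjacent cells until all expected >= 5
  grp <- integer(kMax + 1L)
  g <- 1L; acc <- 0
  for (k in seq_len(kMax + 1L)) {
    grp[k] <- g
    acc <- acc + exp[k]
    if (acc >= 5) { g <- g + 1L; acc <- 0 }
  }
  if (acc > 0 && g > 1L) grp[grp == g] <- g - 1L
  o <- tapply(obs, grp, sum)
  e <- tapply(exp, grp, sum)
  if (length(o) < 2) return(NA_real_)
  stat <- sum((o - e)^2 / e)
  pchisq(stat, df = length(o) - 1L, lower.tail = FALSE)
}
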