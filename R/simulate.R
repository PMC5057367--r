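#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")
.BASE_RAW <- charToRaw("ACGT")
## transition partner of each base (A<->G, C<->T)
.TS <- c(A = "G", C = "T", G = "A", T = "C")

.maybeSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate a diploid genome with known haplotypes
#'
#' Draws a uniform-random reference sequence and places SNP sites by
#' independent per-base Bernoulli trials (binomial placement). Heterozygous
#' sites put the alt allele on haplotype 0 or 1 with probability 1/2 each;
#' a configurable fraction of sites is homozygous-alt on both haplotypes.
#' Alt alleles are transitions with probability \code{tsProb}.
#'
#' @param params an [lfrSimParams()] object.
#' @param seed integer seed; defaults to \code{params@rngSeed}. Identical
#'   parameters and seed give byte-identical genomes.
#' @return A \code{\linkS4class{DiploidGenome}}.
#' @examples
#' g <- simulateDiploidGenome(lfrSimParams(genomeLength = 5e4, rngSeed = 1))
#' g
#' @export
simulateDiploidGenome <- function(params = lfrSimParams(), seed = params@rngSeed) {
  stopifnot(is(params, "LfrSimParams"))
  if (params@genomeLength < 1e4)
    stop("genomeLength must be >= 10,000")
  if (params@hetSnpDensity > 0.01)
    stop("hetSnpDensity must be <= 0.01 (denser SNPs would collide at 1 bp resolution)")
  .maybeSeed(seed)
  n <- as.integer(params@genomeLength)
  refChar <- sample(.BASES, n, replace = TRUE)

  homD <- .homDensity(params)
  pTot <- params@hetSnpDensity + homD
  pos <- which(runif(n) < pTot)
  nv <- length(pos)
  refAt <- refChar[pos]

  isHom <- runif(nv) < homD / pTot
  ## alt allele: transition with prob tsProb, else one of the two transversions
  alt <- ifelse(runif(nv) < params@tsProb,
                .TS[refAt],
                vapply(refAt, function(b) {
                  sample(setdiff(.BASES, c(b, .TS[[b]])), 1L)
                }, character(1)))
  names(alt) <- NULL
  altOn0 <- runif(nv) < 0.5
  gt <- ifelse(isHom, "hom_alt",
               ifelse(altOn0, "het_hap0_alt", "het_hap1_alt"))
  hap0 <- ifelse(isHom | altOn0, alt, refAt)
  hap1 <- ifelse(isHom | !altOn0, alt, refAt)

  v <- GRanges(rep(.SEQNAME, nv), IRanges(pos, width = 1L),
               ref = refAt, alt = alt, gt = gt, hap0 = hap0, hap1 = hap1)
  new("DiploidGenome",
      refSeq = DNAString(paste(refChar, collapse = "")), variants = v)
}

#' Sample long fragments for each well
#'
#' Per well the fragment count is Poisson with the configured (or
#' mass-derived) mean; lengths are i.i.d. exponential with mean
#' \code{decayLengthKb * 1000} bp, starts uniform, and the parental
#' haplotype of each fragment is Bernoulli(1/2). Fragments overhanging the
#' genome end are clipped.
#'
#' @param genome a \code{\linkS4class{DiploidGenome}}, or NULL for a
#'   fragment-level simulation using \code{params@genomeLength} (fragment
#'   sampling does not touch the sequence).
#' @param params an [lfrSimParams()] object.
#' @param seed integer seed (default \code{params@rngSeed}).
#' @return A \code{GRanges} of true fragments with metadata columns
#'   \code{well}, \code{haplotype} (0/1) and \code{fragmentId}.
#' @export
sampleFragments <- function(genome, params = lfrSimParams(),
                            seed = params@rngSeed) {
  stopifnot(is.null(genome) || is(genome, "DiploidGenome"))
  if (params@decayLengthKb < 1 || params@decayLengthKb > 200)
    stop("decayLengthKb outside the supported 1-200 kb range")
  .maybeSeed(seed)
  g <- if (is.null(genome)) params@genomeLength else length(refSeq(genome))
  counts <- rpois(params@nWells, meanFragmentsPerWell(params))
  nf <- sum(counts)
  well <- rep(seq_len(params@nWells), counts)
  len <- pmax(1, round(rexp(nf, rate = 1 / (params@decayLengthKb * 1000))))
  start0 <- floor(runif(nf, 0, g))          # 0-based
  end0 <- pmin(start0 + len, g)
  hap <- as.integer(runif(nf) < 0.5)
  gr <- GRanges(.SEQNAME, IRanges(start0 + 1, end0),
                well = well, haplotype = hap, fragmentId = seq_len(nf))
  metadata(gr)$genomeLength <- g
  gr
}

## Extract constant-width windows [starts0, starts0+width) from a raw
## sequence vector as a raw matrix (width x n).
.rawWindows <- function(seqRaw, starts0, width) {
  idx <- rep(starts0, each = width) + seq_len(width)  # 1-based
  matrix(seqRaw[idx], nrow = width)
}

## Flip k bases of a raw base vector uniformly to one of the 3 other bases.
.injectErrors <- function(bigRaw, rate) {
  nb <- length(bigRaw)
  k <- rbinom(1L, nb, rate)
  if (k == 0L) return(list(raw = bigRaw, n = 0L))
  at <- sample.int(nb, k)
  cur <- match(bigRaw[at], .BASE_RAW)
  shift <- sample.int(3L, k, replace = TRUE)
  bigRaw[at] <- .BASE_RAW[((cur - 1L + shift) %% 4L) + 1L]
  list(raw = bigRaw, n = k)
}

#' Simulate barcoded mate-pair reads from true fragments
#'
#' Mate-pairs are sampled uniformly within each fragment at
#' \code{readsPerKb} pairs per kb of fragment, with a uniform mate gap in
#' \code{[gapMin, gapMax]} (shrunk when a fragment cannot hold the full
#' span). Arm bases are copied from the fragment's parental haplotype, then
#' flipped i.i.d. at \code{perBaseErrorRate} to a uniformly chosen other
#' base. A \code{wellContaminationRate} fraction of pairs finally has its
#' well id replaced by a uniformly random other well (positions and bases
#' untouched). Fragments shorter than \code{2*armLen + gapMin} yield no
#' reads.
#'
#' @param genome a \code{\linkS4class{DiploidGenome}}.
#' @param fragmentsGr true fragments from [sampleFragments()].
#' @param params an [lfrSimParams()] object.
#' @param seed integer seed (default \code{params@rngSeed}).
#' @return An \code{\linkS4class{LfrReadSet}}.
#' @export
simulateReads <- function(genome, fragmentsGr, params = lfrSimParams(),
                          seed = params@rngSeed) {
  stopifnot(is(genome, "DiploidGenome"))
  .maybeSeed(seed)
  armLen <- params@armLen
  minSpan <- 2L * armLen + params@gapMin
  fr <- fragmentsGr
  w <- GenomicRanges::width(fr)
  nPairs <- rpois(length(fr), w / 1000 * params@readsPerKb)
  nPairs[w < minSpan] <- 0L
  tot <- sum(nPairs)
  if (tot == 0L)
    return(new("LfrReadSet", well = integer(), arm1Pos = integer(),
               arm2Pos = integer(), arm1 = character(), arm2 = character(),
               fragmentId = integer(), armLen = armLen,
               nWells = params@nWells,
               gapRange = c(params@gapMin, params@gapMax)))

  fi <- rep(seq_along(fr), nPairs)
  fStart0 <- GenomicRanges::start(fr)[fi] - 1L
  fWidth <- w[fi]
  gapMaxEff <- pmin(params@gapMax, fWidth - 2L * armLen)
  gap <- params@gapMin +
    floor(runif(tot) * (gapMaxEff - params@gapMin + 1))
  span <- 2L * armLen + gap
  arm1 <- fStart0 + floor(runif(tot) * (fWidth - span + 1))
  arm2 <- arm1 + armLen + gap

  hapOf <- mcols(fr)$haplotype[fi]
  hapRaw <- list(charToRaw(as.character(haplotypeSeq(genome, 0L))),
                 charToRaw(as.character(haplotypeSeq(genome, 1L))))

  extractArms <- function(starts0) {
    out <- character(length(starts0))
    chunk <- 2e6L
    for (lo in seq(1L, length(starts0), by = chunk)) {
      hi <- min(lo + chunk - 1L, length(starts0))
      sel <- lo:hi
      big <- raw(length(sel) * armLen)
      for (h in 0:1) {
        on <- hapOf[sel] == h
        if (!any(on)) next
        slots <- rep(on, each = armLen)
        big[slots] <- .rawWindows(hapRaw[[h + 1]], starts0[sel][on], armLen)
      }
      inj <- .injectErrors(big, params@perBaseErrorRate)
      s <- rawToChar(inj$raw)
      nn <- length(sel)
      out[sel] <- substring(s, (seq_len(nn) - 1L) * armLen + 1L,
                            seq_len(nn) * armLen)
    }
    out
  }
  arm1Seq <- extractArms(arm1)
  arm2Seq <- extractArms(arm2)

  well <- mcols(fr)$well[fi]
  if (params@wellContaminationRate > 0 && params@nWells > 1L) {
    hit <- which(runif(tot) < params@wellContaminationRate)
    if (length(hit)) {
      other <- 1L + floor(runif(length(hit)) * (params@nWells - 1L))
      other <- other + (other >= well[hit])   # uniform over the other wells
      well[hit] <- other
    }
  }

  new("LfrReadSet",
      well = as.integer(well), arm1Pos = as.integer(arm1),
      arm2Pos = as.integer(arm2), arm1 = arm1Seq, arm2 = arm2Seq,
      fragmentId = as.integer(mcols(fr)$fragmentId[fi]),
      armLen = armLen, nWells = params@nWells,
      gapRange = c(params@gapMin, params@gapMax))
}

#' Simulate a complete LFR library
#'
#' Convenience wrapper: [sampleFragments()] then [simulateReads()] with a
#' single seed controlling both.
#'
#' @inheritParams simulateReads
#' @param seed integer seed for the whole library.
#' @return A list with elements \code{fragments} (truth \code{GRanges}) and
#'   \code{reads} (\code{LfrReadSet}).
#' @export
simulateLibrary <- function(genome, params = lfrSimParams(),
                            seed = params@rngSeed) {
  .maybeSeed(seed)
  fragmentsGr <- sampleFragments(genome, params, seed = NULL)
  reads <- simulateReads(genome, fragmentsGr, params, seed = NULL)
  list(fragments = fragmentsGr, reads = reads)
}
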