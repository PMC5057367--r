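#' @include phasemap.R
NULL

#' Per-read likelihood of an observed base given an allele
#'
#' \code{P(observed | allele) = 1 - e} when the bases agree and \code{e/3}
#' otherwise, with \code{e} the per-base error rate; the four observed
#' bases sum to 1.
#'
#' @param observed observed base(s), character vector over A/C/G/T.
#' @param allele allele base(s).
#' @param errorRate per-base error rate \code{e}.
#' @return Numeric vector of probabilities.
#' @export
pairLikelihood <- function(observed, allele, errorRate = 0.005) {
  stopifnot(all(observed %in% .BASES), all(allele %in% .BASES))
  ifelse(observed == allele, 1 - errorRate, errorRate / 3)
}

#' Hypothesis probability without phasing information
#'
#' For a hypothesis H with alleles A0 and A1, a mate-pair has equal prior
#' probability of originating from each allele:
#' \code{P(H | mp) \eqn{\propto} (P(mp | A0) + P(mp | A1)) / 2}.
#' Symmetric under swapping the alleles.
#'
#' @param p0,p1 \code{P(mate-pair | A0)} and \code{P(mate-pair | A1)}.
#' @return The unnormalized hypothesis probability.
#' @export
hypothesisProbUnphased <- function(p0, p1) (p0 + p1) / 2

#' Hypothesis probability for a phased mate-pair
#'
#' When the phased fragment map assigned the mate-pair to allele 0:
#' \code{P(H | mp) \eqn{\propto} (1 - mu) P(mp | A0) + mu P(mp | A1)}
#' (and symmetrically for allele 1). \code{mu} is small (default 0.01) and
#' reflects the uncertainty of the fragment phasing process; at
#' \code{mu = 0.5} the expression reduces exactly to the unphased form, and
#' for \code{mu < 0.5} it is no longer invariant under swapping the two
#' alleles — hypothesis evaluation automatically takes phasing into
#' account.
#'
#' @param p0,p1 \code{P(mate-pair | A0)} and \code{P(mate-pair | A1)}.
#' @param assignedAllele 0 or 1, the allele the fragment map assigned the
#'   mate-pair to. Unassigned pairs must be scored with
#'   [hypothesisProbUnphased()].
#' @param mu phasing uncertainty in \code{[0, 0.5]} (default 0.01).
#' @return The unnormalized hypothesis probability.
#' @examples
#' hypothesisProbPhased(0.9, 0.1, 0, mu = 0.01)   # 0.892
#' hypothesisProbPhased(0.9, 0.1, 1, mu = 0.01)   # 0.108
#' @export
hypothesisProbPhased <- function(p0, p1, assignedAllele, mu = 0.01) {
  stopifnot(all(assignedAllele %in% c(0L, 1L)), all(mu >= 0), all(mu <= 0.5))
  ifelse(assignedAllele == 0L,
         (1 - mu) * p0 + mu * p1,
         mu * p0 + (1 - mu) * p1)
}

#' Table-1 style well-count fields at one locus
#'
#' Given the wells and bases of the reads observed at a locus and the two
#' called alleles, computes: the number of distinct wells with reads
#' calling the variant (\code{wellCount}) and the reference
#' (\code{refWellCount}); the number of wells calling only the variant
#' (\code{ecxclusiveWellCount}, field name preserved verbatim from the LFR
#' variant-file dialect); the number calling both alleles
#' (\code{SharedWellCount}); the min and max of the two alleles' exclusive
#' counts; and the ascending ids of the variant-calling wells.
#'
#' @param wells integer well ids of the reads at the locus.
#' @param bases observed base of each read.
#' @param altBase,refBase the two called alleles.
#' @return A list with \code{wellCount}, \code{refWellCount},
#'   \code{wellIDs}, \code{ecxclusiveWellCount}, \code{SharedWellCount},
#'   \code{MinExclusiveWellCountInThisLocus},
#'   \code{MaxExclusiveWellCountInThisLocus}.
#' @examples
#' wellFields(c(1, 2, 3, 4, 5, 6, 6), c("T", "T", "T", "A", "A", "T", "A"),
#'            altBase = "T", refBase = "A")
#' @export
wellFields <- function(wells, bases, altBase, refBase) {
  altW <- unique(wells[bases == altBase])
  refW <- unique(wells[bases == refBase])
  shared <- intersect(altW, refW)
  exAlt <- setdiff(altW, refW)
  exRef <- setdiff(refW, altW)
  list(wellCount = length(altW),
       refWellCount = length(refW),
       wellIDs = sort(altW),
       ecxclusiveWellCount = length(exAlt),
       SharedWellCount = length(shared),
       MinExclusiveWellCountInThisLocus = min(length(exAlt), length(exRef)),
       MaxExclusiveWellCountInThisLocus = max(length(exAlt), length(exRef)))
}

#' Phasing-aware variant calling
#'
#' Scores diallelic ordered-pair hypotheses (A0, A1) at candidate sites.
#' Reads whose fragment was assigned to an allele of the site's phased
#' contig are scored with [hypothesisProbPhased()]; all other reads with
#' [hypothesisProbUnphased()]. The winning unordered genotype must beat the
#' runner-up by \code{minMarginDb} decibels to be a confident call
#' (\code{varFilter = "PASS"}, otherwise \code{"VQLOW"}); best-is-hom-ref
#' sites produce no record. For het calls inside a phased contig the
#' orientation of the winning ordered pair sets the haplotype carrying the
#' variant, exported as \code{hapLink = "Phased_<library>_<contig>_<hap>"}.
#'
#' Candidate sites are positions where some non-reference base is seen in
#' at least \code{minAltReads} reads (plus all strong het sites). By
#' default \code{minAltReads} is auto-calibrated from the observed mismatch
#' rate so that the expected number of error-driven candidates is below
#' 0.001 per genome base.
#'
#' @param sm result of [secondMap()].
#' @param phase a \code{\linkS4class{PhaseResult}} (or NULL for fully
#'   unphased calling).
#' @param reference a [Biostrings::DNAString].
#' @param mu phasing uncertainty (default 0.01).
#' @param errorRate per-base error rate used in the read likelihoods.
#' @param hetPrior prior for any non-reference genotype (default 0.001).
#' @param minMarginDb no-call margin in dB (default 10).
#' @param minAltReads candidate threshold override.
#' @param libraryId integer, first field of \code{hapLink}.
#' @return A data.frame of LFR variant records (one row per variant site)
#'   with Table-1 well fields; attribute \code{nScored} counts scored
#'   candidate sites (including best-is-hom-ref ones).
#' @export
callVariants <- function(sm, phase, reference, mu = 0.01,
                         errorRate = 0.005, hetPrior = 0.001,
                         minMarginDb = 10, minAltReads = NULL,
                         libraryId = 1L) {
  disc <- sm$discordances
  g <- sm$genomeLength

  if (is.null(minAltReads)) {
    alignedBases <- max(1, nrow(sm$placements) * 2 * sm$armLen)
    obsErr <- nrow(disc) / alignedBases
    lamErr <- (alignedBases / g) * obsErr / 3
    k <- 2L
    while (3 * g * ppois(k - 1, lamErr, lower.tail = FALSE) > 0.001 * g &&
           k < 50L)
      k <- k + 1L
    minAltReads <- k
  }

  candPos <- integer(0)
  if (nrow(disc)) {
    dt <- data.table(pos = disc$pos, base = disc$base)
    agg <- dt[, list(n = .N), by = c("pos", "base")]
    candPos <- unique(agg$pos[agg$n >= minAltReads])
  }
  if (!is.null(phase) && length(phase@strongHets))
    candPos <- union(candPos, GenomicRanges::start(phase@strongHets) - 1L)
  candPos <- sort(candPos)
  emptyRec <- .emptyRecords()
  if (!length(candPos)) return(emptyRec)

  refBases <- .refBaseAt(reference, candPos)
  obs <- .siteObservations(sm, candPos, refBases = refBases)
  if (!nrow(obs)) return(emptyRec)

  ## read -> allele assignment via its fragment (valid only within the
  ## site's phased contig)
  fragAllele <- rep(NA_integer_, max(obs$fragIdx, 1L))
  fragContig <- rep(NA_integer_, max(obs$fragIdx, 1L))
  siteContig <- rep(NA_integer_, length(candPos))
  if (!is.null(phase)) {
    fa <- mcols(phase@fragments)$allele
    fc <- mcols(phase@fragments)$contig
    fragAllele[seq_along(fa)] <- fa
    fragContig[seq_along(fc)] <- fc
    if (length(phase@contigs)) {
      ov <- findOverlaps(GRanges(.SEQNAME, IRanges(candPos + 1L, width = 1L)),
                         phase@contigs)
      siteContig[queryHits(ov)] <- mcols(phase@contigs)$contigId[subjectHits(ov)]
    }
  }

  bySite <- split(seq_len(nrow(obs)), obs$siteIdx)
  rows <- vector("list", length(bySite))
  nScored <- 0L
  logHet <- log(hetPrior)
  for (ii in seq_along(bySite)) {
    k <- as.integer(names(bySite)[ii])
    oi <- bySite[[ii]]
    bs <- obs$base[oi]
    refB <- refBases[k]
    tb <- table(bs)
    alleles <- union(refB, names(tb)[tb >= 2L])
    if (length(alleles) < 1L) next
    nScored <- nScored + 1L
    if (length(alleles) == 1L) next  # only ref observed: hom-ref, no record

    asg <- fragAllele[obs$fragIdx[oi]]
    ctg <- fragContig[obs$fragIdx[oi]]
    sCtg <- siteContig[k]
    asg[is.na(asg) | is.na(ctg) | is.na(sCtg) | ctg != sCtg] <- NA_integer_

    rec <- .scoreSite(bs, asg, alleles, refB, errorRate, mu,
                      logHet, minMarginDb)
    if (is.null(rec)) next
    wf <- wellFields(obs$well[oi], bs, rec$alt, refB)
    phased <- rec$genotype == "het" && !is.na(sCtg) && rec$oriented &&
      any(!is.na(asg))
    hapAlt <- if (phased) {
      if (rec$a0 == rec$alt) 0L else 1L
    } else NA_integer_
    rows[[ii]] <- data.frame(
      position = candPos[k] + 1L,
      ref = refB, alt = rec$alt, genotype = rec$genotype,
      varFilter = rec$varFilter,
      hapLink = if (phased) sprintf("Phased_%d_%d_%d", libraryId, sCtg,
                                    hapAlt) else "",
      phase = hapAlt, contig = if (phased) sCtg else NA_integer_,
      wellCount = wf$wellCount, refWellCount = wf$refWellCount,
      wellIDs = paste(wf$wellIDs, collapse = ";"),
      ecxclusiveWellCount = wf$ecxclusiveWellCount,
      SharedWellCount = wf$SharedWellCount,
      MinExclusiveWellCountInThisLocus = wf$MinExclusiveWellCountInThisLocus,
      MaxExclusiveWellCountInThisLocus = wf$MaxExclusiveWellCountInThisLocus,
      nReads = length(oi), nAltReads = sum(bs == rec$alt),
      marginDb = rec$marginDb)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- emptyRec
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nScored") <- nScored
  attr(out, "minAltReads") <- minAltReads
  out
}

.emptyRecords <- function() {
  data.frame(position = integer(), ref = character(), alt = character(),
             genotype = character(), varFilter = character(),
             hapLink = character(), phase = integer(), contig = integer(),
             wellCount = integer(), refWellCount = integer(),
             wellIDs = character(), ecxclusiveWellCount = integer(),
             SharedWellCount = integer(),
             MinExclusiveWellCountInThisLocus = integer(),
             MaxExclusiveWellCountInThisLocus = integer(),
             nReads = integer(), nAltReads = integer(),
             marginDb = numeric())
}

## Score all ordered diallelic hypotheses over `alleles` at one site.
## bs: observed bases; asg: 0/1/NA per read; returns the winning call or
## NULL when hom-ref wins.
.scoreSite <- function(bs, asg, alleles, refB, errorRate, mu,
                       logHet, minMarginDb) {
  nb <- length(alleles)
  ## per-read likelihood of each candidate allele
  L <- vapply(alleles, function(a) pairLikelihood(bs, a, errorRate),
              numeric(length(bs)))
  L <- matrix(L, ncol = nb)
  is0 <- !is.na(asg) & asg == 0L
  is1 <- !is.na(asg) & asg == 1L
  isU <- is.na(asg)
  S <- matrix(NA_real_, nb, nb)   # S[i, j] = log score of hypothesis (Ai, Aj)
  for (i in seq_len(nb)) for (j in seq_len(nb)) {
    p0 <- L[, i]; p1 <- L[, j]
    S[i, j] <- sum(log((1 - mu) * p0[is0] + mu * p1[is0])) +
      sum(log(mu * p0[is1] + (1 - mu) * p1[is1])) +
      sum(log((p0[isU] + p1[isU]) / 2))
  }
  refIdx <- match(refB, alleles)
  ## genotype-level scores with priors
  combos <- list()
  for (i in seq_len(nb)) for (j in i:nb) {
    logPrior <- if (!is.na(refIdx) && i == refIdx && j == refIdx) 0 else logHet
    sc <- if (i == j) S[i, i] else .logsumexp(c(S[i, j], S[j, i])) - log(2)
    combos[[length(combos) + 1L]] <-
      list(i = i, j = j, score = sc + logPrior)
  }
  scores <- vapply(combos, `[[`, numeric(1), "score")
  bestK <- which.max(scores)
  marginDb <- if (length(scores) > 1)
    10 * (scores[bestK] - max(scores[-bestK])) / log(10) else Inf
  best <- combos[[bestK]]
  if (!is.na(refIdx) && best$i == refIdx && best$j == refIdx)
    return(NULL)                               # hom-ref: suppressed
  varFilter <- if (marginDb >= minMarginDb) "PASS" else "VQLOW"
  if (best$i == best$j) {
    allele <- alleles[best$i]
    return(list(genotype = "hom", alt = allele, a0 = allele, a1 = allele,
                oriented = FALSE, varFilter = varFilter,
                marginDb = marginDb))
  }
  x <- alleles[best$i]; y <- alleles[best$j]
  ## variant allele: the non-reference base (better-supported one if both)
  alt <- if (x == refB) {
    y
  } else if (y == refB) {
    x
  } else {
    c(x, y)[which.max(c(sum(bs == x), sum(bs == y)))]
  }
  ## orientation of the winning ordered pair
  d <- S[best$i, best$j] - S[best$j, best$i]
  a0 <- if (d >= 0) x else y
  a1 <- if (d >= 0) y else x
  list(genotype = "het", alt = alt, a0 = a0, a1 = a1,
       oriented = abs(d) > 1e-9, varFilter = varFilter, marginDb = marginDb)
}

.logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
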