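#' @include AllClasses.R fragmap.R
NULL

#' Second mapping step: place reads within their well's fragments
#'
#' Mate-pairs are mapped only against the subset of the reference covered
#' by the called fragments of their own well; a pair whose position falls
#' outside every fragment of its well is dropped (and counted). Placements
#' with more than one mismatch in an arm are rejected. Every mismatch
#' against the reference is tracked as (position, base, well, fragment).
#'
#' In \code{"fast"} mode the recorded arm positions are trusted and
#' mismatches are read off by direct comparison with the reference; in
#' \code{"strict"} mode each arm is re-located within its well's fragment
#' sequence allowing at most one mismatch (intended for small inputs).
#'
#' @param reads an \code{\linkS4class{LfrReadSet}}.
#' @param fragMap a \code{\linkS4class{FragmentMap}} from [callFragments()].
#' @param reference a [Biostrings::DNAString].
#' @param mode \code{"fast"} or \code{"strict"}.
#' @return A list with \code{placements} (data.frame: \code{readId},
#'   \code{well}, \code{fragIdx} index into \code{fragments(fragMap)},
#'   \code{pos}, \code{arm1Pos}, \code{arm2Pos}), \code{discordances}
#'   (data.frame: \code{readId}, \code{well}, \code{fragIdx}, \code{pos}
#'   0-based, \code{base}), \code{counters}, and bookkeeping
#'   (\code{armLen}, \code{genomeLength}, \code{nWells}).
#' @export
secondMap <- function(reads, fragMap, reference, mode = c("fast", "strict")) {
  mode <- match.arg(mode)
  armLen <- reads@armLen
  fr <- fragments(fragMap)
  pos0 <- (reads@arm1Pos + reads@arm2Pos) %/% 2L

  ## restrict to pairs falling inside a fragment of their own well
  fragOf <- .fragmentOfWell(pos0, reads@well, fr)
  readIdx <- which(!is.na(fragOf))
  fragIdx <- fragOf[readIdx]
  nDroppedOutside <- length(reads) - length(readIdx)

  refRaw <- charToRaw(as.character(reference))
  keepList <- vector("list", 0L)
  discList <- vector("list", 0L)
  chunk <- 1e6L
  nIn <- length(readIdx)
  rejected <- 0L
  for (lo in seq(1L, max(nIn, 1L), by = chunk)) {
    if (nIn == 0L) break
    hi <- min(lo + chunk - 1L, nIn)
    sel <- lo:hi
    ri <- readIdx[sel]
    mm <- .armMismatches(reads, ri, refRaw, armLen)
    ok <- mm$n1 <= 1L & mm$n2 <= 1L
    rejected <- rejected + sum(!ok)
    okIdx <- which(ok)
    keepList[[length(keepList) + 1L]] <-
      data.frame(readId = ri[okIdx], well = reads@well[ri][okIdx],
                 fragIdx = fragIdx[sel][okIdx],
                 pos = pos0[ri][okIdx],
                 arm1Pos = reads@arm1Pos[ri][okIdx],
                 arm2Pos = reads@arm2Pos[ri][okIdx])
    if (nrow(mm$disc)) {
      d <- mm$disc
      d$keep <- ok[d$localIdx]
      d <- d[d$keep, , drop = FALSE]
      if (nrow(d)) {
        discList[[length(discList) + 1L]] <-
          data.frame(readId = ri[d$localIdx], well = reads@well[ri][d$localIdx],
                     fragIdx = fragIdx[sel][d$localIdx],
                     pos = d$pos, base = d$base)
      }
    }
  }
  placements <- if (length(keepList)) do.call(rbind, keepList)
    else data.frame(readId = integer(), well = integer(), fragIdx = integer(),
                    pos = integer(), arm1Pos = integer(), arm2Pos = integer())
  discordances <- if (length(discList)) do.call(rbind, discList)
    else data.frame(readId = integer(), well = integer(), fragIdx = integer(),
                    pos = integer(), base = character())

  if (mode == "strict" && nrow(placements))
    placements <- .strictRefine(placements, reads, fr, reference, armLen)

  list(placements = placements, discordances = discordances,
       counters = c(input = length(reads),
                    droppedOutsideFragment = nDroppedOutside,
                    rejectedMismatches = rejected,
                    placed = nrow(placements),
                    discordantBases = nrow(discordances)),
       armLen = armLen, genomeLength = length(reference),
       nWells = reads@nWells)
}

## For each (0-based position, well), the index of the well's fragment
## containing the position, or NA. Fragments are disjoint within a well.
.fragmentOfWell <- function(pos0, well, fr) {
  out <- rep(NA_integer_, length(pos0))
  if (!length(fr) || !length(pos0)) return(out)
  fw <- mcols(fr)$well
  fs <- GenomicRanges::start(fr) - 1L   # 0-based inclusive
  fe <- GenomicRanges::end(fr)          # 0-based exclusive
  byWell <- split(seq_along(fr), fw)
  readsByWell <- split(seq_along(pos0), well)
  for (w in names(readsByWell)) {
    fi <- byWell[[w]]
    if (is.null(fi)) next
    ri <- readsByWell[[w]]
    o <- order(fs[fi])
    fi <- fi[o]
    k <- findInterval(pos0[ri], fs[fi])
    ok <- k > 0L
    ok[ok] <- pos0[ri][ok] < fe[fi[k[ok]]]
    out[ri[ok]] <- fi[k[ok]]
  }
  out
}

## Compare both arms of the selected reads against the reference.
## Returns per-read mismatch counts and a table of mismatch observations
## (localIdx into `ri`, 0-based genomic pos, observed base).
.armMismatches <- function(reads, ri, refRaw, armLen) {
  n <- length(ri)
  disc <- list()
  counts <- list()
  for (a in 1:2) {
    armPos <- if (a == 1L) reads@arm1Pos[ri] else reads@arm2Pos[ri]
    armStr <- if (a == 1L) reads@arm1[ri] else reads@arm2[ri]
    obs <- matrix(charToRaw(paste(armStr, collapse = "")), nrow = armLen)
    refM <- .rawWindows(refRaw, armPos, armLen)
    neq <- obs != refM
    counts[[a]] <- .colSumsLogical(neq)
    idx <- which(neq)
    if (length(idx)) {
      row <- (idx - 1L) %% armLen + 1L
      col <- (idx - 1L) %/% armLen + 1L
      disc[[a]] <- data.frame(localIdx = col,
                              pos = armPos[col] + row - 1L,
                              base = .BASES[match(obs[idx], .BASE_RAW)])
    }
  }
  d <- if (length(disc)) do.call(rbind, disc)
    else data.frame(localIdx = integer(), pos = integer(),
                    base = character())
  list(n1 = counts[[1]], n2 = counts[[2]], disc = d)
}

.colSumsLogical <- function(m) {
  if (!length(m)) return(integer(0))
  as.integer(colSums(m))
}

## Strict refinement: re-locate each arm within the union of its well's
## fragments allowing <= 1 mismatch; drop pairs without a unique such
## placement at their recorded position. Quadratic-ish; small inputs only.
.strictRefine <- function(placements, reads, fr, reference, armLen) {
  keep <- logical(nrow(placements))
  for (k in seq_len(nrow(placements))) {
    ri <- placements$readId[k]
    fragsW <- fr[mcols(fr)$well == placements$well[k]]
    ok <- TRUE
    for (a in 1:2) {
      arm <- DNAString(if (a == 1) reads@arm1[ri] else reads@arm2[ri])
      nHits <- 0L
      for (j in seq_along(fragsW)) {
        sub <- Biostrings::subseq(reference,
                                  GenomicRanges::start(fragsW)[j],
                                  GenomicRanges::end(fragsW)[j])
        nHits <- nHits +
          Biostrings::countPattern(arm, sub, max.mismatch = 1)
      }
      if (nHits != 1L) { ok <- FALSE; break }
    }
    keep[k] <- ok
  }
  placements[keep, , drop = FALSE]
}

#' Collect strong heterozygous SNP sites
#'
#' Positions where exactly two different bases each have robust read
#' support — at least \code{minReads} reads from at least \code{minWells}
#' distinct wells — are collected as strong het sites, the anchors of
#' fragment-to-allele assignment. Positions with three or more supported
#' bases are excluded.
#'
#' By default the read threshold is auto-calibrated: using the observed
#' per-base mismatch rate of the second mapping step, the smallest
#' \code{k >= 2} is chosen such that the expected number of error-driven
#' candidate (position, base) pairs genome-wide is at most 0.5; the well
#' threshold is \code{max(2, k - 1)}. This keeps the collector sensitive in
#' sparse, clean libraries and strict at deep coverage, where single-well
#' concentrated errors (the MDA failure mode) must not seed false hets.
#'
#' @param sm result of [secondMap()].
#' @param reference a [Biostrings::DNAString].
#' @param minReads,minWells explicit thresholds (both >= 2) overriding the
#'   auto rule.
#' @return A \code{GRanges} of strong het sites with columns \code{baseA},
#'   \code{baseB} (baseA is the reference base when the site is
#'   ref/alt), \code{readsA}, \code{readsB}, \code{wellsA}, \code{wellsB};
#'   metadata records the thresholds used.
#' @export
strongHetSites <- function(sm, reference, minReads = NULL, minWells = NULL) {
  disc <- sm$discordances
  empty <- GRanges(seqnames = character(), IRanges())
  mcols(empty) <- S4Vectors::DataFrame(baseA = character(),
                                       baseB = character(),
                                       readsA = integer(), readsB = integer(),
                                       wellsA = integer(), wellsB = integer(),
                                       refBase = character())
  if (!nrow(disc)) return(empty)

  alignedBases <- nrow(sm$placements) * 2 * sm$armLen
  errRate <- nrow(disc) / alignedBases
  depth <- alignedBases / sm$genomeLength
  if (is.null(minReads)) {
    lamErr <- depth * errRate / 3
    k <- 2L
    while (3 * sm$genomeLength *
           ppois(k - 1, lamErr, lower.tail = FALSE) > 0.5 && k < 50L)
      k <- k + 1L
    minReads <- k
  }
  if (is.null(minWells)) minWells <- max(2L, as.integer(minReads) - 1L)
  if (minReads < 2L || minWells < 2L)
    stop("strong-het thresholds must be >= 2")

  ## support per (pos, base) among tracked discordances
  key <- paste(disc$pos, disc$base)
  dt <- data.table(pos = disc$pos, base = disc$base, well = disc$well)
  altSup <- dt[, list(reads = .N, wells = length(unique(well))),
               by = c("pos", "base")]
  cand <- altSup[altSup$reads >= minReads & altSup$wells >= minWells, ]
  if (!nrow(cand)) return(empty)

  posU <- sort(unique(cand$pos))
  refSup <- .refSupportAt(sm, posU)
  refBase <- .refBaseAt(reference, posU)

  out <- vector("list", length(posU))
  for (k in seq_along(posU)) {
    p <- posU[k]
    sup <- cand[cand$pos == p, ]
    bases <- sup$base
    reads <- sup$reads
    wells <- sup$wells
    ## add the reference base's support unless already among candidates
    if (!(refBase[k] %in% bases)) {
      bases <- c(refBase[k], bases)
      reads <- c(refSup$reads[k], reads)
      wells <- c(refSup$wells[k], wells)
    }
    strong <- reads >= minReads & wells >= minWells
    if (sum(strong) != 2L) next
    ix <- which(strong)
    ## baseA: reference base first when present, else alphabetical
    if (refBase[k] %in% bases[ix]) {
      aPos <- ix[bases[ix] == refBase[k]][1]
      bPos <- setdiff(ix, aPos)[1]
    } else {
      o <- ix[order(bases[ix])]
      aPos <- o[1]; bPos <- o[2]
    }
    out[[k]] <- data.frame(pos = p, baseA = bases[aPos], baseB = bases[bPos],
                           readsA = reads[aPos], readsB = reads[bPos],
                           wellsA = wells[aPos], wellsB = wells[bPos],
                           refBase = refBase[k])
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(empty)
  gr <- GRanges(.SEQNAME, IRanges(df$pos + 1L, width = 1L),
                baseA = df$baseA, baseB = df$baseB,
                readsA = df$readsA, readsB = df$readsB,
                wellsA = df$wellsA, wellsB = df$wellsB,
                refBase = df$refBase)
  metadata(gr)$minReads <- as.integer(minReads)
  metadata(gr)$minWells <- as.integer(minWells)
  metadata(gr)$errRate <- errRate
  gr
}

## Reads (and wells) supporting the reference base at 0-based positions:
## covering placed reads minus those with a tracked discordance there.
.refSupportAt <- function(sm, pos0) {
  pl <- sm$placements
  armLen <- sm$armLen
  q <- GRanges(.SEQNAME, IRanges(pos0 + 1L, width = 1L))
  arms <- GRanges(.SEQNAME,
                  IRanges(c(pl$arm1Pos, pl$arm2Pos) + 1L, width = armLen))
  rid <- c(pl$readId, pl$readId)
  wid <- c(pl$well, pl$well)
  ov <- findOverlaps(q, arms)
  covPos <- queryHits(ov)
  covRead <- rid[subjectHits(ov)]
  covWell <- wid[subjectHits(ov)]
  ## remove reads discordant at that position (any base)
  disc <- sm$discordances
  dKey <- paste(disc$pos, disc$readId)
  cKey <- paste(pos0[covPos], covRead)
  isRef <- !(cKey %in% dKey)
  dt <- data.table(k = covPos[isRef], well = covWell[isRef])
  agg <- dt[, list(reads = .N, wells = length(unique(well))), by = "k"]
  reads <- integer(length(pos0)); wells <- integer(length(pos0))
  reads[agg$k] <- agg$reads
  wells[agg$k] <- agg$wells
  list(reads = reads, wells = wells)
}

.refBaseAt <- function(reference, pos0) {
  as.character(Biostrings::extractAt(reference,
                                     IRanges(pos0 + 1L, width = 1L)))
}

#' Assign fragments to alleles by contradiction minimization
#'
#' Builds a graph with called fragments as nodes; every pair of fragments
#' voting at a shared strong het site gets an edge accumulating +1
#' agreement (same base) or +1 disagreement (opposite bases) per site. A
#' two-coloring per connected component is computed by greedy BFS seeding
#' followed by iterated single-fragment flips until no flip reduces the
#' total contradiction weight (the number of violated per-site pair
#' relations). Fragments whose contradiction fraction exceeds
#' \code{maxContradictionFrac} are left unassigned. Regions assignable
#' without breaks become phased contigs: a break is placed between
#' consecutive strong hets co-covered by fewer than \code{minLinkSupport}
#' assigned fragments.
#'
#' @param sm result of [secondMap()].
#' @param strongHets result of [strongHetSites()].
#' @param fragMap the unphased \code{\linkS4class{FragmentMap}}.
#' @param maxContradictionFrac maximum tolerated fraction of contradicting
#'   pair relations per fragment (default 0.25).
#' @param minLinkSupport minimum number of assigned fragments linking two
#'   consecutive strong hets (default 2).
#' @return A \code{\linkS4class{PhaseResult}}; the fragment \code{GRanges}
#'   gains \code{allele} (0/1/NA) and \code{contig} columns. Allele labels
#'   are consistent within a contig and arbitrary across contigs.
#' @export
assignAlleles <- function(sm, strongHets, fragMap,
                          maxContradictionFrac = 0.25,
                          minLinkSupport = 2L) {
  fr <- fragments(fragMap)
  nFrag <- length(fr)
  emptyContigs <- GRanges(seqnames = character(), IRanges())
  mcols(emptyContigs) <- S4Vectors::DataFrame(contigId = integer(),
                                              nSites = integer(),
                                              contradictions = integer(),
                                              nFragments = integer())
  mcols(fr)$allele <- NA_integer_
  mcols(fr)$contig <- NA_integer_
  sh <- strongHets
  if (!length(sh) || nFrag == 0L) {
    if (length(sh)) { mcols(sh)$contig <- NA_integer_; mcols(sh)$hapA <- NA_integer_ }
    return(new("PhaseResult", fragments = fr, contigs = emptyContigs,
               strongHets = sh, stats = list(votes = 0L)))
  }

  votes <- .fragmentVotes(sm, sh)   # fragIdx, siteIdx, vote (0=baseA,1=baseB)
  if (!nrow(votes)) {
    mcols(sh)$contig <- NA_integer_; mcols(sh)$hapA <- NA_integer_
    return(new("PhaseResult", fragments = fr, contigs = emptyContigs,
               strongHets = sh, stats = list(votes = 0L)))
  }

  edges <- .voteEdges(votes)        # f, g, agree, disagree  (f < g)
  fragStart <- GenomicRanges::start(fr)
  s <- .twoColor(edges, nFrag, votes, fragStart)  # +1/-1; 0 = no votes

  ## per-fragment contradiction fraction over incident pair relations
  cost <- .edgeCosts(edges, s)
  confl <- numeric(nFrag); tot <- numeric(nFrag)
  for (cn in c("f", "g")) {
    confl <- confl + .sumBy(cost$cost, edges[[cn]], nFrag)
    tot <- tot + .sumBy(edges$agree + edges$disagree, edges[[cn]], nFrag)
  }
  frac <- ifelse(tot > 0, confl / tot, 1)
  assigned <- s != 0 & frac <= maxContradictionFrac
  s[!assigned] <- 0L

  ## site orientation: haplotype label carrying baseA, from assigned voters
  vA <- votes[s[votes$fragIdx] != 0L, , drop = FALSE]
  nSites <- length(sh)
  hapA <- rep(NA_integer_, nSites)
  siteConfl <- integer(nSites)
  if (nrow(vA)) {
    ## voter color mapped through vote: baseA voter contributes its color,
    ## baseB voter the opposite color
    colr <- s[vA$fragIdx] * ifelse(vA$vote == 0L, 1L, -1L)
    up <- .sumBy(as.integer(colr > 0), vA$siteIdx, nSites)
    dn <- .sumBy(as.integer(colr < 0), vA$siteIdx, nSites)
    hapA[up + dn > 0] <- ifelse(up >= dn, 0L, 1L)[up + dn > 0]
    siteConfl <- pmin(up, dn)
  }

  ## contig breaks between consecutive phased strong hets with weak or
  ## ambiguous linkage
  phasedIdx <- which(!is.na(hapA))
  contigOfSite <- rep(NA_integer_, nSites)
  contigRows <- NULL
  if (length(phasedIdx)) {
    ord <- phasedIdx[order(GenomicRanges::start(sh)[phasedIdx])]
    link <- .linkSupport(vA, ord, s, hapA)
    breaks <- which(link < minLinkSupport)
    cid <- cumsum(c(1L, seq_along(ord)[-1] %in% (breaks + 1L)))
    contigOfSite[ord] <- cid
    pos <- GenomicRanges::start(sh)[ord]
    contigRows <- data.frame(contigId = seq_len(max(cid)),
                             start = tapply(pos, cid, min)[as.character(seq_len(max(cid)))],
                             end = tapply(pos, cid, max)[as.character(seq_len(max(cid)))],
                             nSites = as.integer(table(factor(cid, seq_len(max(cid))))),
                             contradictions = as.integer(
                               .sumBy(siteConfl[ord], cid, max(cid))))
  }

  ## fragment -> contig: majority contig of its voted sites
  fragContig <- rep(NA_integer_, nFrag)
  if (nrow(vA)) {
    vc <- vA[!is.na(contigOfSite[vA$siteIdx]), , drop = FALSE]
    if (nrow(vc)) {
      dt <- data.table(f = vc$fragIdx, c = contigOfSite[vc$siteIdx])
      cnt <- dt[, list(n = .N), by = c("f", "c")]
      cnt <- cnt[order(cnt$f, -cnt$n, cnt$c), ]
      first <- !duplicated(cnt$f)
      fragContig[cnt$f[first]] <- cnt$c[first]
    }
  }

  allele <- rep(NA_integer_, nFrag)
  allele[s > 0] <- 0L
  allele[s < 0] <- 1L
  allele[is.na(fragContig)] <- NA_integer_
  mcols(fr)$allele <- allele
  mcols(fr)$contig <- fragContig

  mcols(sh)$contig <- contigOfSite
  mcols(sh)$hapA <- hapA

  contigs <- emptyContigs
  if (!is.null(contigRows)) {
    nFragPerContig <- as.integer(table(factor(fragContig,
                                              contigRows$contigId)))
    contigs <- GRanges(.SEQNAME,
                       IRanges(contigRows$start, contigRows$end),
                       contigId = contigRows$contigId,
                       nSites = contigRows$nSites,
                       contradictions = contigRows$contradictions,
                       nFragments = nFragPerContig)
  }
  new("PhaseResult", fragments = fr, contigs = contigs, strongHets = sh,
      stats = list(votes = nrow(votes),
                   totalPairContradictions = sum(cost$cost),
                   assignedFragments = sum(!is.na(allele)),
                   unassignedFragments = nFrag - sum(!is.na(allele))))
}

## Majority vote of each fragment at each strong het site.
## Returns data.frame(fragIdx, siteIdx, vote 0/1, nA, nB).
.fragmentVotes <- function(sm, sh) {
  obs <- .siteObservations(sm, GenomicRanges::start(sh) - 1L,
                           refBases = mcols(sh)$refBase)
  if (!nrow(obs)) return(data.frame(fragIdx = integer(), siteIdx = integer(),
                                    vote = integer()))
  bA <- mcols(sh)$baseA[obs$siteIdx]
  bB <- mcols(sh)$baseB[obs$siteIdx]
  isA <- obs$base == bA
  isB <- obs$base == bB
  sel <- isA | isB
  dt <- data.table(f = obs$fragIdx[sel], s = obs$siteIdx[sel],
                   a = as.integer(isA[sel]))
  agg <- dt[, list(nA = sum(a), nB = .N - sum(a)), by = c("f", "s")]
  agg <- agg[agg$nA != agg$nB, ]    # ties carry no information
  data.frame(fragIdx = agg$f, siteIdx = agg$s,
             vote = as.integer(agg$nB > agg$nA),
             nA = agg$nA, nB = agg$nB)
}

## All read-base observations at the given 0-based positions.
## `refBases` (one per position) fills in the base of reads matching the
## reference; with refBases = NULL those reads get base "".
## Returns data.frame(siteIdx, readId, well, fragIdx, base, isRef).
.siteObservations <- function(sm, pos0, refBases = NULL) {
  pl <- sm$placements
  armLen <- sm$armLen
  if (!nrow(pl) || !length(pos0))
    return(data.frame(siteIdx = integer(), readId = integer(),
                      well = integer(), fragIdx = integer(),
                      base = character(), isRef = logical()))
  q <- GRanges(.SEQNAME, IRanges(pos0 + 1L, width = 1L))
  arms <- GRanges(.SEQNAME,
                  IRanges(c(pl$arm1Pos, pl$arm2Pos) + 1L, width = armLen))
  ov <- findOverlaps(q, arms)
  pi <- (subjectHits(ov) - 1L) %% nrow(pl) + 1L
  siteIdx <- queryHits(ov)
  out <- data.frame(siteIdx = siteIdx,
                    readId = pl$readId[pi],
                    well = pl$well[pi],
                    fragIdx = pl$fragIdx[pi],
                    base = NA_character_)
  ## default: reference base; overridden by tracked discordances
  disc <- sm$discordances
  if (nrow(disc)) {
    dKey <- paste(disc$pos, disc$readId)
    oKey <- paste(pos0[siteIdx], out$readId)
    m <- match(oKey, dKey)
    out$base <- ifelse(is.na(m), "", disc$base[m])
  } else {
    out$base <- ""
  }
  out$isRef <- out$base == ""
  if (!is.null(refBases))
    out$base[out$isRef] <- refBases[siteIdx[out$isRef]]
  out
}

## Pairwise agreement/disagreement edges from fragment votes.
.voteEdges <- function(votes) {
  parts <- list()
  sp <- split(seq_len(nrow(votes)), votes$siteIdx)
  for (rows in sp) {
    if (length(rows) < 2L) next
    f <- votes$fragIdx[rows]
    v <- votes$vote[rows]
    o <- order(f)
    f <- f[o]; v <- v[o]
    n <- length(f)
    i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
    j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
    parts[[length(parts) + 1L]] <-
      data.frame(f = f[i], g = f[j], same = as.integer(v[i] == v[j]))
  }
  if (!length(parts))
    return(data.frame(f = integer(), g = integer(), agree = integer(),
                      disagree = integer()))
  e <- do.call(rbind, parts)
  dt <- data.table(f = e$f, g = e$g, same = e$same)
  agg <- dt[, list(agree = sum(same), disagree = .N - sum(same)),
            by = c("f", "g")]
  as.data.frame(agg)
}

.edgeCosts <- function(edges, s) {
  same <- s[edges$f] == s[edges$g]
  active <- s[edges$f] != 0L & s[edges$g] != 0L
  cost <- ifelse(!active, 0L,
                 ifelse(same, edges$disagree, edges$agree))
  list(cost = cost)
}

.sumBy <- function(x, idx, n) {
  out <- numeric(n)
  t <- tapply(x, idx, sum)
  out[as.integer(names(t))] <- t
  out
}

## Two-coloring of the fragment agreement graph, minimizing the number of
## violated pair-site relations. Connected components with at most
## `exactLimit` fragments are solved exactly by enumeration (fixing the
## lowest fragment id to +1); larger components get greedy BFS seeding
## refined by (a) suffix-flip sweeps in genomic order, which repair whole
## mis-oriented sections that single flips cannot reach, and (b) iterated
## best-improvement single flips. Returns +1/-1 colors; 0 for fragments
## with no votes/edges.
.twoColor <- function(edges, nFrag, votes, fragStart = NULL,
                      exactLimit = 15L) {
  s <- integer(nFrag)
  inGraph <- sort(unique(c(edges$f, edges$g, votes$fragIdx)))
  if (!length(inGraph)) return(s)
  adj <- .adjacencyList(edges, nFrag)

  ## discover components from lowest fragment id first
  comp <- integer(nFrag)
  nComp <- 0L
  for (seed in inGraph) {
    if (comp[seed]) next
    nComp <- nComp + 1L
    queue <- seed
    comp[seed] <- nComp
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[u]]
      if (is.null(nb)) next
      fresh <- nb$g[comp[nb$g] == 0L]
      comp[fresh] <- nComp
      queue <- c(queue, fresh)
    }
  }

  eComp <- if (nrow(edges)) comp[edges$f] else integer(0)
  for (k in seq_len(nComp)) {
    ids <- which(comp == k)
    e <- edges[eComp == k, , drop = FALSE]
    if (length(ids) == 1L || !nrow(e)) {
      s[ids] <- 1L
    } else if (length(ids) <= exactLimit) {
      s[ids] <- .exactTwoColor(ids, e)
    } else {
      s[ids] <- .greedyTwoColor(ids, e, adj)
    }
  }

  ## refinement rounds: suffix-flip sweep (section inversions), then
  ## iterated best-improvement single flips
  w <- edges$agree - edges$disagree
  W <- sparseMatrix(i = c(edges$f, edges$g), j = c(edges$g, edges$f),
                    x = c(w, w), dims = c(nFrag, nFrag))
  for (round in 1:6) {
    changed <- FALSE
    if (!is.null(fragStart) && nrow(edges))
      changed <- changed || ({
        sNew <- .suffixFlipSweep(edges, s, fragStart, comp, nComp)
        moved <- any(sNew != s)
        s <- sNew
        moved
      })
    ## single flips
    Ws <- as.numeric(W %*% s)
    repeat {
      delta <- s * Ws        # flipping f changes the cost by -2 * delta[f]
      delta[s == 0L] <- Inf
      f <- which.min(delta)
      if (!length(f) || delta[f] >= 0) break
      changed <- TRUE
      sOld <- s[f]
      s[f] <- -sOld
      col <- W[, f, drop = FALSE]
      Ws[col@i + 1L] <- Ws[col@i + 1L] + (-2L * sOld) * col@x
    }
    if (!changed) break
  }
  s
}

## One pass of suffix flips per component: fragments are ordered by
## genomic start; flipping every fragment from rank k onward changes the
## cost by sum over cut-crossing edges of s_f * s_g * w_e. The best
## negative cut is applied, repeatedly, until no cut improves.
.suffixFlipSweep <- function(edges, s, fragStart, comp, nComp) {
  w <- edges$agree - edges$disagree
  for (k in seq_len(nComp)) {
    ids <- which(comp == k & s != 0L)
    if (length(ids) < 3L) next
    ids <- ids[order(fragStart[ids], ids)]
    rank <- integer(length(s))
    rank[ids] <- seq_along(ids)
    sel <- which(comp[edges$f] == k & s[edges$f] != 0L & s[edges$g] != 0L)
    if (!length(sel)) next
    rf <- rank[edges$f[sel]]
    rg <- rank[edges$g[sel]]
    lo <- pmin(rf, rg)
    hi <- pmax(rf, rg)
    repeat {
      v <- s[edges$f[sel]] * s[edges$g[sel]] * w[sel]
      ## delta(cut at rank r) = sum of v over edges with lo < r <= hi
      d <- numeric(length(ids) + 1L)
      ok <- hi > lo
      if (!any(ok)) break
      dAdd <- tapply(v[ok], lo[ok] + 1L, sum)
      dSub <- tapply(v[ok], hi[ok] + 1L, sum)
      d[as.integer(names(dAdd))] <- d[as.integer(names(dAdd))] + dAdd
      d[as.integer(names(dSub))] <- d[as.integer(names(dSub))] - dSub
      cum <- cumsum(d)[seq_along(ids)]
      r <- which.min(cum)
      if (cum[r] >= 0) break
      s[ids[seq(r, length(ids))]] <- -s[ids[seq(r, length(ids))]]
    }
  }
  s
}

## Exhaustive minimum-contradiction coloring of one small component.
.exactTwoColor <- function(ids, e) {
  kN <- length(ids)
  fi <- match(e$f, ids)
  gi <- match(e$g, ids)
  M <- 2L^(kN - 1L)
  masks <- 0:(M - 1L)
  S <- matrix(1L, M, kN)
  for (j in 2:kN)
    S[, j] <- ifelse(bitwAnd(masks, 2L^(j - 2L)) > 0L, 1L, -1L)
  cost <- numeric(M)
  for (r in seq_len(nrow(e))) {
    same <- S[, fi[r]] == S[, gi[r]]
    cost <- cost + ifelse(same, e$disagree[r], e$agree[r])
  }
  S[which.min(cost), ]
}

## Greedy BFS coloring of one large component: each fragment is colored by
## the accumulated weight to its already-colored neighbours.
.greedyTwoColor <- function(ids, e, adj) {
  sLoc <- integer(max(ids))
  seed <- ids[1L]
  sLoc[seed] <- 1L
  queue <- seed
  visited <- logical(max(ids))
  visited[seed] <- TRUE
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[u]]
    if (is.null(nb)) next
    for (vIdx in seq_len(nrow(nb))) {
      v <- nb$g[vIdx]
      if (!visited[v]) {
        visited[v] <- TRUE
        nbv <- adj[[v]]
        acc <- sum(nbv$w * sLoc[nbv$g])
        sLoc[v] <- if (acc > 0) {
          1L
        } else if (acc < 0) {
          -1L
        } else {
          sLoc[u] * (if (nb$w[vIdx] >= 0) 1L else -1L)
        }
        queue <- c(queue, v)
      }
    }
  }
  sLoc[ids]
}

.adjacencyList <- function(edges, nFrag) {
  if (!nrow(edges)) return(vector("list", nFrag))
  both <- data.frame(u = c(edges$f, edges$g), g = c(edges$g, edges$f),
                     w = c(edges$agree - edges$disagree,
                           edges$agree - edges$disagree))
  both <- both[order(both$u, both$g), ]
  sp <- split(both[c("g", "w")], both$u)
  adj <- vector("list", nFrag)
  adj[as.integer(names(sp))] <- sp
  adj
}

## Linking evidence between consecutive phased strong hets: for each
## assigned fragment voting at both sites, its two votes either support
## the current relative orientation of the sites (both votes consistent
## with the fragment's color, or both inconsistent — flipping the fragment
## would fix both) or conflict with it (exactly one consistent). The link
## strength is supporting minus conflicting fragments, so a junction
## carried by few fragments, or by fragments that disagree, breaks the
## contig.
.linkSupport <- function(vAssigned, orderedSiteIdx, s, hapA) {
  n <- length(orderedSiteIdx)
  if (n < 2L) return(integer(0))
  allele <- ifelse(s > 0L, 0L, 1L)      # color -> allele label
  ## consistency of each assigned vote with (fragment allele, site hapA)
  consistent <- (vAssigned$vote == 0L) ==
    (allele[vAssigned$fragIdx] == hapA[vAssigned$siteIdx])
  bySite <- split(data.frame(f = vAssigned$fragIdx, c = consistent),
                  vAssigned$siteIdx)
  out <- integer(n - 1L)
  prev <- bySite[[as.character(orderedSiteIdx[1])]]
  for (k in 2:n) {
    cur <- bySite[[as.character(orderedSiteIdx[k])]]
    m <- match(prev$f, cur$f)
    hit <- !is.na(m)
    nSupp <- sum(prev$c[hit] == cur$c[m[hit]])
    out[k - 1L] <- 2L * nSupp - sum(hit)    # support - conflict
    prev <- cur
  }
  out
}

#' Phased contig length summary
#'
#' N50 is the length L such that contigs of length >= L cover at least half
#' of the total phased length.
#'
#' @param x a \code{\linkS4class{PhaseResult}}, a \code{GRanges} of
#'   contigs, or a numeric vector of lengths in bp.
#' @return A list with \code{count}, \code{totalBp}, \code{maxBp},
#'   \code{n50Bp}.
#' @export
contigStats <- function(x) {
  lens <- if (is(x, "PhaseResult")) GenomicRanges::width(x@contigs)
    else if (is(x, "GRanges")) GenomicRanges::width(x)
    else as.numeric(x)
  if (!length(lens))
    return(list(count = 0L, totalBp = 0, maxBp = 0, n50Bp = 0))
  srt <- sort(lens, decreasing = TRUE)
  tot <- sum(srt)
  n50 <- srt[which(cumsum(srt) >= tot / 2)[1]]
  list(count = length(lens), totalBp = tot, maxBp = max(srt), n50Bp = n50)
}
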