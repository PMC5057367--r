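## Independent brute-force oracles used to check the package's algorithms.

## Run-length oracle: explicit left-to-right state machine over a dense bin
## count vector. Returns data.frame(startBin, endBin) of retained streaks
## (0-based bins), allowing <= maxGapBins under-threshold bins inside a
## streak and discarding streaks spanning < minLenBins bins.
oracleStreaks <- function(counts, minReads, maxGapBins, minLenBins) {
  out <- list()
  start <- NA; last <- NA; gap <- 0
  flush <- function() {
    if (!is.na(start) && (last - start + 1) >= minLenBins)
      out[[length(out) + 1]] <<- c(start, last)
    start <<- NA; last <<- NA; gap <<- 0
  }
  for (b in seq_along(counts)) {
    if (counts[b] >= minReads) {
      if (is.na(start)) start <- b - 1
      last <- b - 1
      gap <- 0
    } else if (!is.na(start)) {
      gap <- gap + 1
      if (gap > maxGapBins) flush()
    }
  }
  flush()
  if (!length(out))
    return(data.frame(startBin = integer(), endBin = integer()))
  m <- do.call(rbind, out)
  data.frame(startBin = m[, 1], endBin = m[, 2])
}

## Exhaustive minimum-contradiction two-coloring over +/-1 labelings.
## edges: data.frame(f, g, agree, disagree). Returns the minimum total
## cost (agree edges cut + disagree edges uncut).
oracleMinContradiction <- function(edges, nFrag) {
  if (!nrow(edges)) return(0)
  ids <- sort(unique(c(edges$f, edges$g)))
  n <- length(ids)
  fi <- match(edges$f, ids)
  gi <- match(edges$g, ids)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    s <- c(1, ifelse(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0, 1, -1))
    same <- s[fi] == s[gi]
    cost <- sum(ifelse(same, edges$disagree, edges$agree))
    if (cost < best) best <- cost
  }
  best
}

## N50 by definition: the largest length L present such that elements
## >= L sum to at least half the total.
oracleN50 <- function(lens) {
  if (!length(lens)) return(0)
  tot <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) if (sum(lens[lens >= L]) >= tot / 2) return(L)
  min(lens)
}

## Well-count fields by explicit per-well loops.
oracleWellFields <- function(wells, bases, altBase, refBase) {
  alt <- c(); ref <- c(); both <- c()
  for (w in unique(wells)) {
    hasA <- any(wells == w & bases == altBase)
    hasR <- any(wells == w & bases == refBase)
    if (hasA) alt <- c(alt, w)
    if (hasR) ref <- c(ref, w)
    if (hasA && hasR) both <- c(both, w)
  }
  exAlt <- sum(!(alt %in% both))
  exRef <- sum(!(ref %in% both))
  list(wellCount = length(alt), refWellCount = length(ref),
       ecxclusiveWellCount = exAlt, SharedWellCount = length(both),
       MinExclusiveWellCountInThisLocus = min(exAlt, exRef),
       MaxExclusiveWellCountInThisLocus = max(exAlt, exRef))
}

## Switch-run oracle: explicit loop partitioning a mismatch vector into
## maximal runs; returns c(nShortSnps, nLongEvents).
oracleSwitchRuns <- function(d) {
  nShort <- 0; nLong <- 0; len <- 0
  for (x in c(d, FALSE)) {
    if (x) {
      len <- len + 1
    } else if (len > 0) {
      if (len == 1) nShort <- nShort + 1 else nLong <- nLong + 1
      len <- 0
    }
  }
  c(nShort, nLong)
}
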