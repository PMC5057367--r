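test_that("pair position is the average of the two arm positions", {
  reads <- new("LfrReadSet", well = 5L, arm1Pos = 1000L, arm2Pos = 1500L,
               arm1 = strrep("A", 35), arm2 = strrep("A", 35),
               fragmentId = 1L, armLen = 35L, nWells = 10L,
               gapRange = c(100L, 500L))
  pl <- firstMap(reads)
  expect_equal(pl$pos, 1250L)
  cm <- buildCoverageMap(pl, 1000L, nWells = 10L, genomeLength = 1e4)
  expect_equal(as.numeric(wellCounts(cm)[5, 2]), 1)  # bin 1 (0-based)
})

test_that("strict first mapping keeps only unique exact matches with a sane gap", {
  set.seed(100)
  p <- lfrSimParams(genomeLength = 5e4, perBaseErrorRate = 0,
                    wellContaminationRate = 0, meanFragmentsPerWell = 0.1,
                    rngSeed = 100)
  g <- simulateDiploidGenome(p)
  ## plant an exact repeat by appending a copy of 30000..30999 at the end
  refc <- as.character(refSeq(g))
  rep1 <- substr(refc, 30001, 31000)
  gRep <- g
  gRep@refSeq <- Biostrings::DNAString(paste0(refc, rep1))

  fr <- sampleFragments(g, p, seed = 101)
  reads <- simulateReads(g, fr, p, seed = 102)
  pl <- firstMap(reads, refSeq(gRep), mode = "strict")
  cnt <- attr(pl, "counters")
  expect_true(unname(sum(cnt[c("placed", "nonUnique", "noMatch",
                               "badGap")]) >= cnt[["input"]] * 0.99))
  ## reads whose arms fall fully in the duplicated segment must be dropped
  inRepeat <- reads@arm1Pos >= 30000 & reads@arm2Pos + 35 <= 31000
  if (any(inRepeat))
    expect_false(any(pl$readId %in% which(inRepeat)))
  ## placed reads outside the repeat sit at their true positions
  outside <- setdiff(pl$readId, which(inRepeat))
  expect_gte(mean(pl$arm1Pos[match(outside, pl$readId)] ==
                  reads@arm1Pos[outside]), 0.99)
})

test_that("coverage map uses floor binning and conserves counts", {
  pl <- data.frame(readId = 1:3, well = c(5L, 5L, 5L),
                   pos = c(500L, 999L, 1000L),
                   arm1Pos = 0L, arm2Pos = 0L)
  cm <- buildCoverageMap(pl, 1000L, nWells = 6L, genomeLength = 5000)
  expect_equal(as.numeric(wellCounts(cm)[5, 1]), 2)
  expect_equal(as.numeric(wellCounts(cm)[5, 2]), 1)
  expect_equal(sum(wellCounts(cm)), nrow(pl))

  cmEmpty <- buildCoverageMap(pl[0, ], 1000L, nWells = 6L,
                              genomeLength = 5000)
  expect_equal(sum(wellCounts(cmEmpty)), 0)
  expect_error(buildCoverageMap(pl, 50L, 6L, 5000), "binSize")
})

test_that("streak calling handles clean, short and gapped streaks", {
  m <- matrix(0, nrow = 3, ncol = 60)
  m[1, 11:30] <- 3            # 20 kb clean streak (bins 10..29 0-based)
  m[2, 11:19] <- 3            # 9 kb: below the 10 kb minimum
  cm <- covMapFromMatrix(m)
  fm <- callFragments(cm, streakParams())
  fr <- fragments(fm)
  expect_equal(length(fr), 1L)
  expect_equal(S4Vectors::mcols(fr)$well, 1L)
  expect_equal(GenomicRanges::start(fr), 10001L)
  expect_equal(GenomicRanges::end(fr), 30000L)
  expect_equal(S4Vectors::mcols(fr)$support, 60)

  ## gap tolerance: bins 10-20 and 23-35 populated
  m2 <- matrix(0, nrow = 1, ncol = 60)
  m2[1, 11:21] <- 2
  m2[1, 24:36] <- 2
  fmMerge <- callFragments(covMapFromMatrix(m2),
                           streakParams(maxGapBins = 2))
  expect_equal(length(fmMerge), 1L)
  expect_equal(S4Vectors::mcols(fragments(fmMerge))$startBin, 10L)
  expect_equal(S4Vectors::mcols(fragments(fmMerge))$endBin, 35L)
  fmSplit <- callFragments(covMapFromMatrix(m2),
                           streakParams(maxGapBins = 1))
  expect_equal(length(fmSplit), 2L)
  expect_equal(GenomicRanges::width(fragments(fmSplit)), c(11000, 13000))
})

test_that("streak calling agrees with the exhaustive run-length oracle", {
  set.seed(202)
  for (rep in 1:60) {
    nBins <- sample(20:200, 1)
    counts <- rpois(nBins, 1.2)
    minReads <- sample(1:3, 1)
    maxGap <- sample(0:4, 1)
    minLenBins <- sample(3:12, 1)
    cm <- covMapFromMatrix(matrix(counts, nrow = 1))
    fm <- callFragments(cm, streakParams(minReadsPerBin = minReads,
                                         maxGapBins = maxGap,
                                         minFragmentLength = minLenBins * 1000))
    got <- S4Vectors::mcols(fragments(fm))[, c("startBin", "endBin")]
    want <- oracleStreaks(counts, minReads, maxGap, minLenBins)
    expect_equal(as.integer(got$startBin), want$startBin)
    expect_equal(as.integer(got$endBin), want$endBin)
  }
})

test_that("no called fragment is ever shorter than the minimum length", {
  set.seed(203)
  for (rep in 1:20) {
    counts <- matrix(rpois(5 * 100, 1), nrow = 5)
    fm <- callFragments(covMapFromMatrix(counts), streakParams())
    if (length(fm))
      expect_true(all(GenomicRanges::width(fragments(fm)) >= 10000))
  }
})

test_that("fragment recovery on a clean simulated library", {
  ## at ~3 cell-equivalents same-well fragment collisions are rare, so
  ## called streaks should recover true fragments with tight boundaries
  r <- zeroNoiseRun()
  truth <- r$truthFragments
  called <- fragments(r$fragMap)
  big <- truth[GenomicRanges::width(truth) >= 15000]
  hit <- 0
  for (i in seq_along(big)) {
    cand <- called[S4Vectors::mcols(called)$well ==
                   S4Vectors::mcols(big)$well[i]]
    if (!length(cand)) next
    ds <- abs(GenomicRanges::start(cand) - GenomicRanges::start(big)[i])
    de <- abs(GenomicRanges::end(cand) - GenomicRanges::end(big)[i])
    if (any(ds <= 2000 & de <= 2000)) hit <- hit + 1
  }
  expect_gte(hit / length(big), 0.95)
})

test_that("fragment length diagnostics recover the decay and reject degenerate input", {
  st <- fragmentLengthStats(rep(25000, 500), minFragmentLength = 10000)
  expect_lt(st$ksPvalueVsExponential, 0.01)

  r <- smallRun()
  st2 <- fragmentLengthStats(r$fragMap)
  ## called lengths are bin-quantized; allow the +1 bin bias
  expect_gt(st2$decayEstimateKb, 20)
  expect_lt(st2$decayEstimateKb, 50)
})
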