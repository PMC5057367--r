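test_that("genome simulation places het sites binomially and deterministically", {
  p <- lfrSimParams(genomeLength = 1e6, hetSnpDensity = 1 / 1500,
                    homSnpDensity = 0, rngSeed = 7)
  g1 <- simulateDiploidGenome(p)
  g2 <- simulateDiploidGenome(p)
  expect_identical(as.character(refSeq(g1)), as.character(refSeq(g2)))
  expect_identical(variantSites(g1), variantSites(g2))

  nHet <- length(hetSites(g1))
  mu <- 1e6 / 1500
  sigma <- sqrt(1e6 * (1 / 1500) * (1 - 1 / 1500))
  expect_lt(abs(nHet - mu), 3 * sigma)

  v <- variantSites(g1)
  expect_true(all(GenomicRanges::start(v) ==
                  sort(unique(GenomicRanges::start(v)))))
  refAt <- as.character(Biostrings::extractAt(
    refSeq(g1), IRanges::IRanges(GenomicRanges::start(v), width = 1)))
  expect_identical(refAt, S4Vectors::mcols(v)$ref)
  expect_true(all(S4Vectors::mcols(v)$ref != S4Vectors::mcols(v)$alt))
})

test_that("zero variant density gives identical haplotypes", {
  p <- lfrSimParams(genomeLength = 2e4, hetSnpDensity = 0,
                    homSnpDensity = 0, rngSeed = 3)
  g <- simulateDiploidGenome(p)
  expect_identical(length(variantSites(g)), 0L)
  expect_identical(as.character(haplotypeSeq(g, 0)),
                   as.character(haplotypeSeq(g, 1)))
})

test_that("fragment lengths are exponential and counts Poisson", {
  p <- lfrSimParams(genomeLength = 5e6, decayLengthKb = 30,
                    meanFragmentsPerWell = 26, rngSeed = 11)
  g <- simulateDiploidGenome(lfrSimParams(genomeLength = 5e6,
                                          rngSeed = 11))
  fr <- sampleFragments(g, p, seed = 13)
  n <- length(fr)
  ## total fragment count ~ Poisson(384 * 26)
  lambda <- 384 * 26
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  ## unclipped interior fragments: sample mean within 3 sigma of 30 kb
  lens <- GenomicRanges::width(fr)
  interior <- GenomicRanges::end(fr) < 5e6
  m <- mean(lens[interior])
  expect_lt(abs(m - 30000), 3 * 30000 / sqrt(sum(interior)))
  ## exponential MLE (= sample mean) recovers decay within 5 %
  expect_lt(abs(m - 30000) / 30000, 0.05)
})

test_that("fragment coverage is Poisson with the analytic mean", {
  ## fragment-level simulation; the sequence is irrelevant for coverage
  p <- lfrSimParams(genomeLength = 2e7, rngSeed = 5)
  fr <- sampleFragments(NULL, p, seed = 5)
  fc <- fragmentCoverageStats(fr, 2e7)
  expect_gt(fc$chisqPvalue, 0.01)
  totalBp <- sum(as.numeric(GenomicRanges::width(fr)))
  expect_lt(abs(fc$lambda - totalBp / 2e7) / fc$lambda, 1e-9)
})

test_that("reads respect fragment boundaries, error and contamination settings", {
  p <- lfrSimParams(genomeLength = 1e5, perBaseErrorRate = 0,
                    wellContaminationRate = 0, meanFragmentsPerWell = 0.5,
                    rngSeed = 21)
  g <- simulateDiploidGenome(p)
  fr <- sampleFragments(g, p, seed = 22)
  reads <- simulateReads(g, fr, p, seed = 23)
  expect_gt(length(reads), 0)

  ## truth closure: arms inside the source fragment
  fi <- match(reads@fragmentId, S4Vectors::mcols(fr)$fragmentId)
  expect_true(all(reads@arm1Pos >= GenomicRanges::start(fr)[fi] - 1L))
  expect_true(all(reads@arm2Pos + reads@armLen <=
                  GenomicRanges::end(fr)[fi]))
  ## no contamination: well matches the fragment's well
  expect_identical(reads@well, S4Vectors::mcols(fr)$well[fi])

  ## error-free arms match the source haplotype exactly
  hap <- S4Vectors::mcols(fr)$haplotype[fi]
  for (h in 0:1) {
    idx <- which(hap == h)[seq_len(min(200, sum(hap == h)))]
    hs <- haplotypeSeq(g, h)
    got <- as.character(Biostrings::extractAt(
      hs, IRanges::IRanges(reads@arm1Pos[idx] + 1L, width = reads@armLen)))
    expect_identical(got, reads@arm1[idx])
  }
})

test_that("injected error count matches the binomial expectation", {
  p <- lfrSimParams(genomeLength = 1e5, perBaseErrorRate = 0.01,
                    wellContaminationRate = 0, meanFragmentsPerWell = 0.6,
                    rngSeed = 31)
  g <- simulateDiploidGenome(lfrSimParams(genomeLength = 1e5,
                                          hetSnpDensity = 1e-12,
                                          homSnpDensity = 0, rngSeed = 31))
  fr <- sampleFragments(g, p, seed = 32)
  reads <- simulateReads(g, fr, p, seed = 33)
  refc <- as.character(refSeq(g))
  nb <- 0L; mism <- 0L
  for (a in 1:2) {
    pos <- if (a == 1) reads@arm1Pos else reads@arm2Pos
    arm <- if (a == 1) reads@arm1 else reads@arm2
    got <- substring(paste(refc), pos + 1L, pos + reads@armLen)
    obs <- charToRaw(paste(arm, collapse = ""))
    ref <- charToRaw(paste(got, collapse = ""))
    mism <- mism + sum(obs != ref)
    nb <- nb + length(obs)
  }
  expect_lt(abs(mism - nb * 0.01), 3 * sqrt(nb * 0.01 * 0.99))
})

test_that("contamination relabels the configured fraction of wells", {
  p <- lfrSimParams(genomeLength = 1e5, perBaseErrorRate = 0,
                    wellContaminationRate = 0.05,
                    meanFragmentsPerWell = 0.6, rngSeed = 41)
  g <- simulateDiploidGenome(p)
  fr <- sampleFragments(g, p, seed = 42)
  reads <- simulateReads(g, fr, p, seed = 43)
  fi <- match(reads@fragmentId, S4Vectors::mcols(fr)$fragmentId)
  frac <- mean(reads@well != S4Vectors::mcols(fr)$well[fi])
  n <- length(reads)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("identical seeds reproduce identical libraries", {
  p <- lfrSimParams(genomeLength = 5e4, meanFragmentsPerWell = 0.3,
                    rngSeed = 51)
  g <- simulateDiploidGenome(p)
  l1 <- simulateLibrary(g, p, seed = 52)
  l2 <- simulateLibrary(g, p, seed = 52)
  expect_identical(l1$fragments, l2$fragments)
  expect_identical(l1$reads@arm1, l2$reads@arm1)
  expect_identical(l1$reads@well, l2$reads@well)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(lfrSimParams(gapMin = 500, gapMax = 100), "gapMin")
  expect_error(lfrSimParams(decayLengthKb = -1), "decayLengthKb")
  expect_error(lfrSimParams(bogus = 1), "unknown")
  expect_error(simulateDiploidGenome(lfrSimParams(genomeLength = 5000)),
               ">= 10,000")
  expect_error(simulateDiploidGenome(lfrSimParams(genomeLength = 1e5,
                                                  hetSnpDensity = 0.02)))
})
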