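## Shared fixtures. The heavy simulation runs are memoised so the
## acceptance tests and the module tests reuse one computation.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, fun) {
  if (!exists(name, envir = .fixtureEnv))
    assign(name, fun(), envir = .fixtureEnv)
  get(name, envir = .fixtureEnv)
}

## Small default-noise library (300 kb) for module-level tests.
smallRun <- function() memoFixture("smallRun", function() {
  runLfrPipeline(config = list(simulate = list(genomeLength = 3e5)),
                 seed = 7L)
})

## Desk-scale replicate pair: one 2 Mb genome, two independent libraries
## at default noise, full pipeline + high-confidence filters on each.
replicateRun <- function() memoFixture("replicateRun", function() {
  cfg <- list(simulate = list(genomeLength = 2e6))
  params <- lfrSimParams(genomeLength = 2e6)
  genome <- simulateDiploidGenome(params, seed = 42L)
  a <- runLfrPipeline(cfg, seed = 1042L, genome = genome, libraryId = 1L)
  b <- runLfrPipeline(cfg, seed = 2042L, genome = genome, libraryId = 2L)
  list(genome = genome, a = a, b = b)
})

## Zero-noise run: ~3 cell-equivalents of fragments, no sequencing error,
## no well contamination, 2 Mb genome.
zeroNoiseRun <- function() memoFixture("zeroNoiseRun", function() {
  g <- 2e6
  mfpw <- 2 * 3 * g / (384 * 30 * 1000)   # ~3 diploid cell-equivalents
  cfg <- list(simulate = list(genomeLength = g, perBaseErrorRate = 0,
                              wellContaminationRate = 0,
                              meanFragmentsPerWell = mfpw))
  runLfrPipeline(cfg, seed = 99L)
})

## Toy secondMap-like structure built from an explicit observation table:
## obs = data.frame(fragIdx, pos (0-based), base, well), one read each.
## Arms are 35 bp starting at the observed position; the mate arm is
## placed far away so it covers no site of interest.
toySecondMap <- function(obs, genomeLength = 1e6, armLen = 35L,
                         refBaseAt = function(pos) "A") {
  n <- nrow(obs)
  placements <- data.frame(readId = seq_len(n), well = obs$well,
                           fragIdx = obs$fragIdx, pos = obs$pos,
                           arm1Pos = obs$pos,
                           arm2Pos = obs$pos + 500L)
  refB <- vapply(obs$pos, refBaseAt, character(1))
  isDisc <- obs$base != refB
  discordances <- data.frame(readId = seq_len(n)[isDisc],
                             well = obs$well[isDisc],
                             fragIdx = obs$fragIdx[isDisc],
                             pos = obs$pos[isDisc],
                             base = obs$base[isDisc])
  list(placements = placements, discordances = discordances,
       counters = c(input = n, placed = n),
       armLen = armLen, genomeLength = genomeLength, nWells = 384L)
}

## FragmentMap whose fragment i spans the whole genome in well wells[i].
toyFragMap <- function(wells, genomeLength = 1e6) {
  fr <- GenomicRanges::GRanges("genome",
                               IRanges::IRanges(rep(1, length(wells)),
                                                genomeLength),
                               well = wells,
                               support = rep(100, length(wells)),
                               startBin = 0L,
                               endBin = as.integer(genomeLength / 1000) - 1L,
                               allele = NA_integer_)
  new("FragmentMap", fragments = fr, binSize = 1000L,
      params = streakParams())
}

## Strong-het GRanges at the given 0-based positions with alleles A/B.
toyStrongHets <- function(pos, baseA = "A", baseB = "C", refBase = baseA) {
  n <- length(pos)
  GenomicRanges::GRanges("genome", IRanges::IRanges(pos + 1L, width = 1L),
                         baseA = rep(baseA, n), baseB = rep(baseB, n),
                         readsA = rep(10L, n), readsB = rep(10L, n),
                         wellsA = rep(5L, n), wellsB = rep(5L, n),
                         refBase = rep(refBase, n))
}

## Random small phasing instance with known structure for the oracle
## equivalence checks: nFrag fragments, nSites strong hets, observation
## probability pObs, vote flip probability pFlip.
randomPhasingInstance <- function(nFrag, nSites, pObs = 0.7, pFlip = 0.1) {
  trueHap <- sample(0:1, nFrag, replace = TRUE)
  orient <- sample(0:1, nSites, replace = TRUE)
  rows <- list()
  for (f in seq_len(nFrag)) for (s in seq_len(nSites)) {
    if (runif(1) > pObs) next
    v <- xor(trueHap[f] == 1L, orient[s] == 1L)
    if (runif(1) < pFlip) v <- !v
    rows[[length(rows) + 1]] <-
      data.frame(fragIdx = f, siteIdx = s, vote = as.integer(v))
  }
  if (!length(rows)) return(NULL)
  votes <- do.call(rbind, rows)
  votes$nA <- ifelse(votes$vote == 0L, 1L, 0L)
  votes$nB <- 1L - votes$nA
  votes
}

## Build a coverage map directly from a dense well x bin count matrix.
covMapFromMatrix <- function(m, binSize = 1000L) {
  new("WellCoverageMap",
      counts = as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
      binSize = as.integer(binSize),
      genomeLength = as.numeric(ncol(m) * binSize))
}
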