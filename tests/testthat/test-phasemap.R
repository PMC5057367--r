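test_that("second mapping tracks planted SNPs and rejects noisy arms", {
  ## one fragment spanning the genome in well 1; reference is all A
  refc <- strrep("A", 10000)
  reference <- Biostrings::DNAString(refc)
  fm <- toyFragMap(wells = 1L, genomeLength = 10000)
  mkArm <- function(base, at) {
    x <- strrep("A", 35)
    for (k in seq_along(at)) substr(x, at[k], at[k]) <- base
    x
  }
  reads <- new("LfrReadSet",
               well = c(1L, 1L, 2L),
               arm1Pos = c(1000L, 2000L, 3000L),
               arm2Pos = c(1300L, 2300L, 3300L),
               arm1 = c(mkArm("C", 5), mkArm("G", c(3, 9)), strrep("A", 35)),
               arm2 = rep(strrep("A", 35), 3),
               fragmentId = c(1L, 1L, 1L),
               armLen = 35L, nWells = 4L, gapRange = c(100L, 500L))
  sm <- secondMap(reads, fm, reference)
  ## read 3 is in well 2 with no fragment: dropped
  expect_equal(sm$counters[["droppedOutsideFragment"]], 1L)
  ## read 2 has two mismatches in one arm: rejected
  expect_equal(sm$counters[["rejectedMismatches"]], 1L)
  ## read 1 contributes exactly one tracked discordance at 1004 (0-based)
  expect_equal(nrow(sm$discordances), 1L)
  expect_equal(sm$discordances$pos, 1004L)
  expect_equal(sm$discordances$base, "C")
})

test_that("strong het collection follows the support thresholds", {
  ## 12 ref reads over 6 wells and 9 alt reads over 5 wells: strong het.
  ## A second position with 3 alt reads all in one well: not strong.
  ## A hom-alt position (all reads alt): only one supported base.
  obs <- rbind(
    data.frame(fragIdx = 1L, pos = 1000L,
               base = rep(c("A", "C"), c(12, 9)),
               well = c(rep(1:6, 2), rep(10:14, length.out = 9))),
    data.frame(fragIdx = 1L, pos = 3000L,
               base = rep(c("A", "G"), c(10, 3)),
               well = c(1:10, 20, 20, 20)),
    data.frame(fragIdx = 1L, pos = 5000L,
               base = rep("T", 10), well = 1:10))
  sm <- toySecondMap(obs)
  reference <- Biostrings::DNAString(strrep("A", 10000))
  sh <- strongHetSites(sm, reference, minReads = 3, minWells = 3)
  expect_equal(length(sh), 1L)
  expect_equal(GenomicRanges::start(sh), 1001L)
  expect_equal(S4Vectors::mcols(sh)$baseA, "A")
  expect_equal(S4Vectors::mcols(sh)$baseB, "C")
  expect_error(strongHetSites(sm, reference, minReads = 1, minWells = 1),
               ">= 2")
})

test_that("clean overlapping fragments get opposite alleles with zero contradictions", {
  ## two fragments in different wells, 3 strong hets, fully consistent
  sites <- c(1000L, 2000L, 3000L)
  obs <- rbind(
    data.frame(fragIdx = 1L, pos = sites, base = "A", well = 1L),
    data.frame(fragIdx = 2L, pos = sites, base = "C", well = 2L))
  sm <- toySecondMap(obs)
  fm <- toyFragMap(wells = c(1L, 2L))
  sh <- toyStrongHets(sites)
  ph <- assignAlleles(sm, sh, fm)
  al <- S4Vectors::mcols(phasedFragments(ph))$allele
  expect_false(any(is.na(al)))
  expect_true(al[1] != al[2])
  expect_equal(sum(S4Vectors::mcols(phasedContigs(ph))$contradictions), 0L)
  expect_equal(length(phasedContigs(ph)), 1L)
})

test_that("a single flipped observation is tolerated and counted", {
  ## 10 fragments voting at 5 shared sites; fragment 1 has one flipped vote
  sites <- seq(1000L, 5000L, by = 1000L)
  rows <- list()
  for (f in 1:10) {
    hap <- f %% 2L           # alternate haplotypes
    base <- ifelse(hap == 0L, "A", "C")
    for (s in sites) {
      b <- base
      if (f == 1L && s == 3000L) b <- ifelse(base == "A", "C", "A")
      rows[[length(rows) + 1]] <-
        data.frame(fragIdx = f, pos = s, base = b, well = f)
    }
  }
  obs <- do.call(rbind, rows)
  sm <- toySecondMap(obs)
  fm <- toyFragMap(wells = 1:10)
  sh <- toyStrongHets(sites)
  ph <- assignAlleles(sm, sh, fm, maxContradictionFrac = 0.25)
  al <- S4Vectors::mcols(phasedFragments(ph))$allele
  expect_false(any(is.na(al)))                 # fragment 1 still assigned
  expect_equal(length(unique(al[c(2, 4, 6, 8, 10) - 1])), 1L)
  expect_equal(sum(S4Vectors::mcols(phasedContigs(ph))$contradictions), 1L)
})

test_that("strong hets with no spanning fragment split into two contigs", {
  sites1 <- c(1000L, 2000L)
  sites2 <- c(500000L, 501000L)
  obs <- rbind(
    data.frame(fragIdx = 1L, pos = sites1, base = "A", well = 1L),
    data.frame(fragIdx = 2L, pos = sites1, base = "C", well = 3L),
    data.frame(fragIdx = 3L, pos = sites2, base = "A", well = 5L),
    data.frame(fragIdx = 4L, pos = sites2, base = "C", well = 7L))
  ## fragments 1-2 cover the left sites only, 3-4 the right sites only
  fr <- GenomicRanges::GRanges("genome",
    IRanges::IRanges(c(1, 1, 400001, 400001),
                     c(100000, 100000, 600000, 600000)),
    well = c(1L, 3L, 5L, 7L), support = 100,
    startBin = 0L, endBin = 99L, allele = NA_integer_)
  fm <- new("FragmentMap", fragments = fr, binSize = 1000L,
            params = streakParams())
  sm <- toySecondMap(obs)
  sh <- toyStrongHets(c(sites1, sites2))
  ph <- assignAlleles(sm, sh, fm)
  expect_equal(length(phasedContigs(ph)), 2L)
})

test_that("the local-search coloring attains the exhaustive minimum on random instances", {
  set.seed(303)
  for (rep in 1:60) {
    votes <- randomPhasingInstance(nFrag = sample(4:10, 1),
                                   nSites = sample(2:6, 1),
                                   pFlip = 0.15)
    if (is.null(votes)) next
    edges <- lfrphase:::.voteEdges(votes)
    if (!nrow(edges)) next
    s <- lfrphase:::.twoColor(edges, max(votes$fragIdx), votes)
    got <- sum(lfrphase:::.edgeCosts(edges, s)$cost)
    want <- oracleMinContradiction(edges, max(votes$fragIdx))
    expect_equal(got, want)
  }
})

test_that("allele labels are swap-symmetric within a contig", {
  ## the contradiction count must be invariant under flipping all labels
  set.seed(304)
  votes <- randomPhasingInstance(8, 5, pFlip = 0.2)
  edges <- lfrphase:::.voteEdges(votes)
  s <- lfrphase:::.twoColor(edges, 8, votes)
  c1 <- sum(lfrphase:::.edgeCosts(edges, s)$cost)
  c2 <- sum(lfrphase:::.edgeCosts(edges, -s)$cost)
  expect_equal(c1, c2)
})

test_that("lowering the contradiction tolerance never assigns more fragments", {
  set.seed(305)
  sites <- seq(1000L, 8000L, by = 1000L)
  rows <- list()
  for (f in 1:12) {
    base <- ifelse(f %% 2L == 0L, "A", "C")
    for (s in sites) {
      b <- if (runif(1) < 0.2) ifelse(base == "A", "C", "A") else base
      rows[[length(rows) + 1]] <-
        data.frame(fragIdx = f, pos = s, base = b, well = f)
    }
  }
  sm <- toySecondMap(do.call(rbind, rows))
  fm <- toyFragMap(wells = 1:12)
  sh <- toyStrongHets(sites)
  fracs <- c(0, 0.1, 0.25, 0.5, 1)
  nAssigned <- vapply(fracs, function(fr) {
    ph <- assignAlleles(sm, sh, fm, maxContradictionFrac = fr)
    sum(!is.na(S4Vectors::mcols(phasedFragments(ph))$allele))
  }, numeric(1))
  expect_true(all(diff(nAssigned) >= 0))
})

test_that("contig N50 summary matches its definition", {
  expect_equal(contigStats(c(100, 200, 300))$n50Bp, 300)
  expect_equal(contigStats(c(100, 200, 300))$n50Bp,
               oracleN50(c(100, 200, 300)))
  expect_equal(contigStats(500)$n50Bp, 500)
  expect_equal(contigStats(numeric(0))$n50Bp, 0)
  expect_equal(contigStats(numeric(0))$count, 0L)
  set.seed(306)
  for (rep in 1:25) {
    lens <- sample(1:2000, sample(1:40, 1), replace = TRUE)
    expect_equal(contigStats(lens)$n50Bp, oracleN50(lens))
  }
})
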