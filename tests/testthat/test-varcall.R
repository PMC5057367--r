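test_that("read likelihoods are normalized and match their definition", {
  expect_equal(pairLikelihood("A", "A", 0.005), 0.995)
  expect_equal(pairLikelihood("C", "A", 0.005), 0.005 / 3)
  tot <- sum(vapply(c("A", "C", "G", "T"),
                    function(b) pairLikelihood(b, "G", 0.005), numeric(1)))
  expect_equal(tot, 1)
})

test_that("unphased hypothesis probability averages the two alleles", {
  expect_equal(hypothesisProbUnphased(0.9, 0.1), 0.5)
  expect_equal(hypothesisProbUnphased(0.3, 0.3), 0.3)  # A0 == A1 case
  ## symmetry
  set.seed(1)
  p0 <- runif(50); p1 <- runif(50)
  expect_equal(hypothesisProbUnphased(p0, p1),
               hypothesisProbUnphased(p1, p0))
})

test_that("phased hypothesis probability matches the printed equation", {
  expect_equal(hypothesisProbPhased(0.9, 0.1, 0, mu = 0.01),
               0.99 * 0.9 + 0.01 * 0.1)      # 0.892
  expect_equal(hypothesisProbPhased(0.9, 0.1, 0, mu = 0.01), 0.892)
  expect_equal(hypothesisProbPhased(0.9, 0.1, 1, mu = 0.01), 0.108)
  ## at mu = 0.5 it reduces exactly to the unphased form
  set.seed(2)
  p0 <- runif(100); p1 <- runif(100)
  a <- sample(0:1, 100, replace = TRUE)
  expect_equal(hypothesisProbPhased(p0, p1, a, mu = 0.5),
               hypothesisProbUnphased(p0, p1))
  ## asymmetry under allele swap for mu < 0.5
  expect_false(isTRUE(all.equal(hypothesisProbPhased(0.9, 0.1, 0, 0.01),
                                hypothesisProbPhased(0.1, 0.9, 0, 0.01))))
  expect_error(hypothesisProbPhased(0.9, 0.1, 0, mu = 0.7), "mu")
})

## helper: a toy phased state with one whole-genome contig and two
## fragments per well group assigned to opposite alleles
.toyPhase <- function(sm, fm, sh, ...) assignAlleles(sm, sh, fm, ...)

test_that("phased reads drive a phased het call that beats unphased scoring", {
  sites <- seq(1000L, 11000L, by = 1000L)   # 11 strong hets
  target <- 6000L
  obs <- rbind(
    data.frame(fragIdx = 1L, pos = sites, base = "C", well = 1L),
    data.frame(fragIdx = 2L, pos = sites, base = "C", well = 2L),
    data.frame(fragIdx = 3L, pos = sites, base = "A", well = 3L),
    data.frame(fragIdx = 4L, pos = sites, base = "A", well = 4L),
    data.frame(fragIdx = 5L, pos = sites, base = "C", well = 5L),
    data.frame(fragIdx = 6L, pos = sites, base = "A", well = 6L),
    data.frame(fragIdx = 7L, pos = sites, base = "C", well = 7L),
    data.frame(fragIdx = 8L, pos = sites, base = "A", well = 8L))
  sm <- toySecondMap(obs)
  fm <- toyFragMap(wells = 1:8)
  sh <- toyStrongHets(sites)
  ph <- .toyPhase(sm, fm, sh)
  rec <- callVariants(sm, ph, Biostrings::DNAString(strrep("A", 1e6)))
  r <- rec[rec$position == target + 1L, ]
  expect_equal(nrow(r), 1L)
  expect_equal(r$genotype, "het")
  expect_equal(r$alt, "C")
  expect_equal(r$varFilter, "PASS")
  expect_match(r$hapLink, "^Phased_1_1_[01]$")
  ## alt-carrying wells: those whose fragments were assigned the C allele
  expect_equal(r$wellCount, 4L)
  expect_equal(r$refWellCount, 4L)
  expect_equal(r$SharedWellCount, 0L)

  ## the phased posterior of the winning het exceeds the unphased one
  asg <- S4Vectors::mcols(phasedFragments(ph))$allele[obs$fragIdx[obs$pos == target]]
  bs <- obs$base[obs$pos == target]
  pC <- pairLikelihood(bs, "C", 0.005)
  pA <- pairLikelihood(bs, "A", 0.005)
  phasedScore <- sum(log(hypothesisProbPhased(
    ifelse(asg == 0, pC, pC), ifelse(asg == 0, pA, pA), asg, 0.01)))
  ## equivalently score the ordered pair (C on allele0's base, A on 1)
  sPhased <- sum(log(ifelse(asg == 0, 0.99 * pC + 0.01 * pA,
                            0.01 * pC + 0.99 * pA)))
  sUnphased <- sum(log((pC + pA) / 2))
  expect_gt(max(sPhased, sum(log(ifelse(asg == 0, 0.99 * pA + 0.01 * pC,
                                        0.01 * pA + 0.99 * pC)))),
            sUnphased)
})

test_that("mu = 0.5 collapses phased and unphased site calls", {
  r <- smallRun()
  refD <- refSeq(r$genome)
  recPhased <- callVariants(r$sm, r$phase, refD, mu = 0.5)
  recUnphased <- callVariants(r$sm, NULL, refD)
  cols <- c("position", "ref", "alt", "genotype")
  expect_equal(recPhased[, cols], recUnphased[, cols],
               ignore_attr = TRUE)
})

test_that("hom-ref sites are suppressed and isolated alt reads do not call", {
  obs <- rbind(
    data.frame(fragIdx = 1L, pos = 1000L, base = rep("A", 20),
               well = rep(1:10, 2)),
    ## 2 alt reads in one well among 20 ref reads at another site
    data.frame(fragIdx = 1L, pos = 5000L,
               base = rep(c("A", "G"), c(20, 2)),
               well = c(rep(1:10, 2), 11L, 11L)))
  sm <- toySecondMap(obs)
  rec <- callVariants(sm, NULL, Biostrings::DNAString(strrep("A", 1e6)),
                      minAltReads = 2)
  ## site 1000: all ref -> no record
  expect_false((1000L + 1L) %in% rec$position)
  r <- rec[rec$position == 5001L, ]
  if (nrow(r)) {
    ## if called at all, the well filter must be able to remove it
    expect_lt(r$wellCount, 6)
    fl <- applyHaplotypeFilters(r)
    expect_equal(nrow(fl$kept), 0L)
  }
})

test_that("well-count fields match the brute-force oracle", {
  ## spec example: wells 1-3 alt-only, 4-5 ref-only, 6 both
  wells <- c(1, 2, 3, 4, 5, 6, 6)
  bases <- c("T", "T", "T", "A", "A", "T", "A")
  wf <- wellFields(wells, bases, "T", "A")
  expect_equal(wf$wellCount, 4L)
  expect_equal(wf$ecxclusiveWellCount, 3L)
  expect_equal(wf$SharedWellCount, 1L)
  expect_equal(wf$MinExclusiveWellCountInThisLocus, 2L)
  expect_equal(wf$MaxExclusiveWellCountInThisLocus, 3L)
  expect_equal(wf$wellIDs, c(1, 2, 3, 6))

  ## hom-alt: every well calls the variant, none the reference
  wfHom <- wellFields(1:8, rep("G", 8), "G", "A")
  expect_equal(wfHom$wellCount, 8L)
  expect_equal(wfHom$refWellCount, 0L)
  expect_equal(wfHom$SharedWellCount, 0L)
  expect_equal(wfHom$MinExclusiveWellCountInThisLocus, 0L)

  ## empty locus
  wf0 <- wellFields(integer(0), character(0), "G", "A")
  expect_equal(wf0$wellCount, 0L)
  expect_equal(wf0$SharedWellCount, 0L)

  set.seed(404)
  for (rep in 1:50) {
    n <- sample(1:60, 1)
    wells <- sample(1:12, n, replace = TRUE)
    bases <- sample(c("A", "T", "G"), n, replace = TRUE,
                    prob = c(0.45, 0.45, 0.1))
    wf <- wellFields(wells, bases, "T", "A")
    want <- oracleWellFields(wells, bases, "T", "A")
    for (f in names(want)) expect_equal(wf[[f]], want[[f]], ignore_attr = TRUE)
    ## conservation: exclusive(alt) + exclusive(ref) + shared = wells with
    ## any read calling either allele
    expect_equal(wf$ecxclusiveWellCount +
                 (wf$refWellCount - wf$SharedWellCount) +
                 wf$SharedWellCount,
                 length(unique(wells[bases %in% c("A", "T")])))
  }
})

test_that("phased genotypes agree with the simulator truth up to per-contig swap", {
  r <- smallRun()
  tv <- variantSites(r$genome)
  truthHet <- tv[grepl("^het", S4Vectors::mcols(tv)$gt)]
  truthHap <- setNames(
    ifelse(S4Vectors::mcols(truthHet)$gt == "het_hap0_alt", 0L, 1L),
    as.character(GenomicRanges::start(truthHet)))
  k <- r$records
  k <- k[k$genotype == "het" & k$hapLink != "", ]
  k$truthHap <- truthHap[as.character(k$position)]
  k <- k[!is.na(k$truthHap), ]
  expect_gt(nrow(k), 50)
  agr <- vapply(split(k, k$contig), function(b) {
    a <- mean(b$phase == b$truthHap)
    max(a, 1 - a)
  }, numeric(1))
  expect_true(all(agr == 1))
})
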