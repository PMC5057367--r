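#' @include lfrphase-package.R
NULL

## Single-contig scope: every range in the package lives on this seqname.
## Multi-chromosome inputs are handled by running per (concatenated) contig.
.SEQNAME <- "genome"

#' Simulation parameters for a co-barcoded LFR library
#'
#' Holds the physical and protocol parameters of a simulated Long Fragment
#' Read library. Defaults follow the published library design: a 384-well
#' plate with ~0.54 pg of DNA per well (~200 pg per library, about 31
#' diploid-cell-equivalents dispensed), long fragments with exponentially
#' distributed lengths (30 kb decay, within the typical 20-50 kb range), and
#' 35 bp mate-pair arms sequenced to ~100X total read-base coverage.
#'
#' @slot genomeLength genome length in bp.
#' @slot hetSnpDensity heterozygous SNP density per bp (default 1/1500).
#' @slot homSnpDensity homozygous-alt SNP density per bp (default
#'   hetSnpDensity/1.5, giving a Het/Hom ratio of ~1.5).
#' @slot tsProb probability that a simulated alt allele is a transition
#'   (default 2/3, Ts/Tv ~ 2).
#' @slot nWells number of barcoded wells (default 384).
#' @slot decayLengthKb exponential decay length of fragment sizes, kb.
#' @slot wellDnaPg mass of DNA dispensed per well, pg (default 0.54).
#' @slot haploidGenomePg mass of one haploid genome copy, pg (default 3.28,
#'   the human value); together with \code{wellDnaPg} this sets the expected
#'   number of fragments per well when \code{meanFragmentsPerWell} is NA.
#' @slot meanFragmentsPerWell expected fragments per well; NA (default)
#'   derives it as \code{wellDnaPg/haploidGenomePg * genomeLength /
#'   (decayLengthKb*1000)}.
#' @slot readsPerKb expected mate-pairs sampled per kb of fragment
#'   (default 23, ~100X total read-base coverage at the default fragment
#'   coverage).
#' @slot armLen read arm length in bp (default 35).
#' @slot gapMin,gapMax mate gap range in bp (defaults 100, 500).
#' @slot perBaseErrorRate per-base sequencing error rate (default 0.005).
#' @slot wellContaminationRate fraction of read pairs whose well id is
#'   replaced by a uniformly random other well (default 0.002).
#' @slot rngSeed integer seed used by the simulator functions; NA leaves the
#'   RNG state untouched.
#'
#' @seealso [lfrSimParams()]
#' @export
setClass("LfrSimParams",
  representation(
    genomeLength = "numeric",
    hetSnpDensity = "numeric",
    homSnpDensity = "numeric",
    tsProb = "numeric",
    nWells = "integer",
    decayLengthKb = "numeric",
    wellDnaPg = "numeric",
    haploidGenomePg = "numeric",
    meanFragmentsPerWell = "numeric",
    readsPerKb = "numeric",
    armLen = "integer",
    gapMin = "integer",
    gapMax = "integer",
    perBaseErrorRate = "numeric",
    wellContaminationRate = "numeric",
    rngSeed = "numeric"
  ),
  prototype(
    genomeLength = 2e6,
    hetSnpDensity = 1 / 1500,
    homSnpDensity = NA_real_,
    tsProb = 2 / 3,
    nWells = 384L,
    decayLengthKb = 30,
    wellDnaPg = 0.54,
    haploidGenomePg = 3.28,
    meanFragmentsPerWell = NA_real_,
    readsPerKb = 23,
    armLen = 35L,
    gapMin = 100L,
    gapMax = 500L,
    perBaseErrorRate = 0.005,
    wellContaminationRate = 0.002,
    rngSeed = NA_real_
  )
)

setValidity("LfrSimParams", function(object) {
  msg <- character()
  rates <- c(object@hetSnpDensity, object@perBaseErrorRate,
             object@wellContaminationRate, object@tsProb)
  if (any(rates < 0 | rates > 1, na.rm = TRUE))
    msg <- c(msg, "all rates must lie in [0, 1]")
  if (!is.na(object@homSnpDensity) &&
      (object@homSnpDensity < 0 || object@homSnpDensity > 1))
    msg <- c(msg, "homSnpDensity must lie in [0, 1]")
  if (object@decayLengthKb <= 0)
    msg <- c(msg, "decayLengthKb must be > 0")
  if (object@nWells < 1L)
    msg <- c(msg, "nWells must be >= 1")
  if (object@gapMin > object@gapMax)
    msg <- c(msg, "gapMin must be <= gapMax")
  if (object@armLen < 10L)
    msg <- c(msg, "armLen must be >= 10")
  if (length(msg)) msg else TRUE
})

#' Construct simulation parameters
#'
#' @param ... named values overriding the slots of
#'   \code{\linkS4class{LfrSimParams}}. Integer-valued slots accept plain
#'   numerics.
#' @return An \code{LfrSimParams} object.
#' @examples
#' p <- lfrSimParams(genomeLength = 1e6, rngSeed = 7)
#' meanFragmentsPerWell(p)
#' @export
lfrSimParams <- function(...) {
  args <- list(...)
  intSlots <- c("nWells", "armLen", "gapMin", "gapMax")
  for (s in intSlots) if (!is.null(args[[s]])) args[[s]] <- as.integer(args[[s]])
  known <- slotNames("LfrSimParams")
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop("unknown simulation parameter(s): ", paste(bad, collapse = ", "))
  do.call(new, c("LfrSimParams", args))
}

#' @describeIn lfrSimParams Expected fragments per well (resolving the
#'   mass-derived default).
#' @param object an \code{LfrSimParams} object.
#' @export
meanFragmentsPerWell <- function(object) {
  stopifnot(is(object, "LfrSimParams"))
  if (!is.na(object@meanFragmentsPerWell))
    return(object@meanFragmentsPerWell)
  object@wellDnaPg / object@haploidGenomePg *
    object@genomeLength / (object@decayLengthKb * 1000)
}

setMethod("show", "LfrSimParams", function(object) {
  cat("LfrSimParams\n")
  cat(sprintf("  genome: %g bp, het density 1/%.0f, hom density 1/%.0f\n",
              object@genomeLength, 1 / object@hetSnpDensity,
              1 / .homDensity(object)))
  cat(sprintf("  wells: %d (%.2f pg each), fragments/well ~ %.1f, decay %g kb\n",
              object@nWells, object@wellDnaPg, meanFragmentsPerWell(object),
              object@decayLengthKb))
  cat(sprintf("  reads: %.0f pairs/kb, 2 x %d bp arms, gap [%d, %d]\n",
              object@readsPerKb, object@armLen, object@gapMin, object@gapMax))
  cat(sprintf("  noise: error %.4g, contamination %.4g\n",
              object@perBaseErrorRate, object@wellContaminationRate))
})

.homDensity <- function(params) {
  if (is.na(params@homSnpDensity)) params@hetSnpDensity / 1.5
  else params@homSnpDensity
}

#' Diploid genome with known haplotypes
#'
#' A reference sequence plus the set of variant sites and the alleles each
#' parental haplotype carries there; the ground truth of the simulator.
#'
#' @slot refSeq a [Biostrings::DNAString] reference.
#' @slot variants a [GenomicRanges::GRanges] of width-1 SNP sites (1-based)
#'   with metadata columns \code{ref}, \code{alt}, \code{gt} (one of
#'   \code{"het_hap0_alt"}, \code{"het_hap1_alt"}, \code{"hom_alt"}),
#'   \code{hap0} and \code{hap1} (the base carried by each haplotype).
#' @export
setClass("DiploidGenome",
  representation(refSeq = "DNAString", variants = "GRanges"))

setValidity("DiploidGenome", function(object) {
  v <- object@variants
  msg <- character()
  need <- c("ref", "alt", "gt", "hap0", "hap1")
  if (!all(need %in% names(mcols(v))))
    return(paste("variants must carry columns", paste(need, collapse = ", ")))
  if (length(v)) {
    pos <- GenomicRanges::start(v)
    if (is.unsorted(pos, strictly = TRUE))
      msg <- c(msg, "variant positions must be strictly increasing")
    if (any(pos < 1L) || any(pos > length(object@refSeq)))
      msg <- c(msg, "variant positions out of genome range")
    if (any(mcols(v)$ref == mcols(v)$alt))
      msg <- c(msg, "alt allele must differ from ref")
    het <- grepl("^het", mcols(v)$gt)
    if (any(mcols(v)$hap0[het] == mcols(v)$hap1[het]))
      msg <- c(msg, "het sites must differ between haplotypes")
    if (any(mcols(v)$hap0[!het] != mcols(v)$hap1[!het]))
      msg <- c(msg, "hom sites must agree between haplotypes")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DiploidGenome-class the reference sequence.
#' @param x a \code{DiploidGenome}.
#' @export
refSeq <- function(x) x@refSeq

#' @describeIn DiploidGenome-class the variant site \code{GRanges}.
#' @export
variantSites <- function(x) x@variants

#' @describeIn DiploidGenome-class the heterozygous subset of
#'   \code{variantSites}.
#' @export
hetSites <- function(x) x@variants[grepl("^het", mcols(x@variants)$gt)]

#' @describeIn DiploidGenome-class the full sequence of one haplotype.
#' @param hap haplotype index, 0 or 1.
#' @export
haplotypeSeq <- function(x, hap) {
  stopifnot(hap %in% c(0L, 1L))
  v <- x@variants
  col <- if (hap == 0) "hap0" else "hap1"
  if (!length(v)) return(x@refSeq)
  at <- rep(FALSE, length(x@refSeq))
  at[GenomicRanges::start(v)] <- TRUE
  replaceLetterAt(x@refSeq, at, paste(mcols(v)[[col]], collapse = ""))
}

setMethod("show", "DiploidGenome", function(object) {
  gt <- mcols(object@variants)$gt
  cat(sprintf("DiploidGenome: %d bp, %d variant sites (%d het, %d hom-alt)\n",
              length(object@refSeq), length(object@variants),
              sum(grepl("^het", gt)), sum(gt == "hom_alt")))
})

#' Barcoded mate-pair read set
#'
#' Column-oriented container for co-barcoded mate-pair reads. Arm positions
#' are 0-based leftmost coordinates on the (single-contig) reference;
#' \code{fragmentId} records the true fragment of origin (provenance, used
#' only by truth-aware checks).
#'
#' @slot well integer well id (1..nWells).
#' @slot arm1Pos,arm2Pos 0-based leftmost positions of the two arms.
#' @slot arm1,arm2 arm base strings (constant width \code{armLen}).
#' @slot fragmentId integer true fragment of origin.
#' @slot armLen arm length in bp.
#' @slot nWells number of wells in the library.
#' @slot gapRange configured mate-gap range, length-2 integer.
#' @export
setClass("LfrReadSet",
  representation(
    well = "integer", arm1Pos = "integer", arm2Pos = "integer",
    arm1 = "character", arm2 = "character",
    fragmentId = "integer",
    armLen = "integer", nWells = "integer", gapRange = "integer"))

setValidity("LfrReadSet", function(object) {
  n <- length(object@well)
  lens <- c(length(object@arm1Pos), length(object@arm2Pos),
            length(object@arm1), length(object@arm2),
            length(object@fragmentId))
  if (any(lens != n)) return("column lengths differ")
  if (n) {
    gap <- object@arm2Pos - (object@arm1Pos + object@armLen)
    if (any(gap < object@gapRange[1] | gap > object@gapRange[2]))
      return("mate gaps outside configured range")
    if (any(object@arm1Pos < 0L))
      return("arm positions must be >= 0")
  }
  TRUE
})

setMethod("length", "LfrReadSet", function(x) length(x@well))

setMethod("show", "LfrReadSet", function(object) {
  cat(sprintf("LfrReadSet: %d mate-pairs, %d wells, 2 x %d bp arms, gap [%d, %d]\n",
              length(object), object@nWells, object@armLen,
              object@gapRange[1], object@gapRange[2]))
})

setMethod("[", "LfrReadSet", function(x, i, j, ..., drop = TRUE) {
  initialize(x,
    well = x@well[i], arm1Pos = x@arm1Pos[i], arm2Pos = x@arm2Pos[i],
    arm1 = x@arm1[i], arm2 = x@arm2[i], fragmentId = x@fragmentId[i])
})

#' Per-well binned mate-pair coverage map
#'
#' Sparse matrix of mate-pair counts per (well, 1 kb bin), the direct
#' product of the first mapping step. Bins are 0-based:
#' bin b covers \code{[b*binSize, (b+1)*binSize)}.
#'
#' @slot counts a sparse \code{dgCMatrix}, wells x bins.
#' @slot binSize bin width in bp.
#' @slot genomeLength genome length in bp.
#' @export
setClass("WellCoverageMap",
  representation(counts = "dgCMatrix", binSize = "integer",
                 genomeLength = "numeric"))

setValidity("WellCoverageMap", function(object) {
  if (any(object@counts@x < 0)) return("counts must be non-negative")
  nb <- ceiling(object@genomeLength / object@binSize)
  if (ncol(object@counts) != nb)
    return("column count must equal ceiling(genomeLength / binSize)")
  TRUE
})

#' @describeIn WellCoverageMap-class the bin width in bp.
#' @param x a \code{WellCoverageMap}.
#' @export
binSize <- function(x) x@binSize

#' @describeIn WellCoverageMap-class the wells x bins count matrix.
#' @export
wellCounts <- function(x) x@counts

setMethod("show", "WellCoverageMap", function(object) {
  cat(sprintf("WellCoverageMap: %d wells x %d bins of %d bp (%.3g mate-pairs)\n",
              nrow(object@counts), ncol(object@counts), object@binSize,
              sum(object@counts)))
})

#' Unphased (or phased) fragment map
#'
#' Fragments called per well from streaks of well-populated bins. Extents
#' are bin-quantized. The \code{allele} column is NA until
#' [assignAlleles()] phases the map.
#'
#' @slot fragments a \code{GRanges} with metadata columns \code{well},
#'   \code{support} (mate-pairs in the streak), \code{startBin},
#'   \code{endBin}, \code{allele} (0/1/NA) and, once phased, \code{contig}.
#' @slot binSize bin width used to call the fragments.
#' @slot params the [streakParams()] used.
#' @export
setClass("FragmentMap",
  representation(fragments = "GRanges", binSize = "integer", params = "list"))

#' @describeIn FragmentMap-class the fragment \code{GRanges}.
#' @param x a \code{FragmentMap}.
#' @export
fragments <- function(x) x@fragments

setMethod("length", "FragmentMap", function(x) length(x@fragments))

setMethod("show", "FragmentMap", function(object) {
  fr <- object@fragments
  ph <- sum(!is.na(mcols(fr)$allele))
  cat(sprintf(
    "FragmentMap: %d fragments in %d wells (%d phased), mean length %.1f kb\n",
    length(fr), length(unique(mcols(fr)$well)), ph,
    if (length(fr)) mean(GenomicRanges::width(fr)) / 1000 else 0))
})

#' Result of fragment-to-allele assignment
#'
#' @slot fragments the phased fragment \code{GRanges} (columns \code{well},
#'   \code{allele} 0/1/NA, \code{contig}).
#' @slot contigs a \code{GRanges} of phased contigs with columns
#'   \code{contigId}, \code{nSites}, \code{contradictions},
#'   \code{nFragments}.
#' @slot strongHets the strong heterozygous SNP \code{GRanges} with columns
#'   \code{baseA}, \code{baseB}, \code{contig}, \code{hapA} (haplotype label
#'   carrying baseA; NA when unphased).
#' @slot stats list of counters from the assignment.
#' @export
setClass("PhaseResult",
  representation(fragments = "GRanges", contigs = "GRanges",
                 strongHets = "GRanges", stats = "list"))

#' @describeIn PhaseResult-class the phased contig \code{GRanges}.
#' @param x a \code{PhaseResult}.
#' @export
phasedContigs <- function(x) x@contigs

#' @describeIn PhaseResult-class the phased fragment \code{GRanges}.
#' @export
phasedFragments <- function(x) x@fragments

setMethod("show", "PhaseResult", function(object) {
  cat(sprintf(
    "PhaseResult: %d contigs over %d strong hets; %d/%d fragments assigned (%d contradictions)\n",
    length(object@contigs), length(object@strongHets),
    sum(!is.na(mcols(object@fragments)$allele)), length(object@fragments),
    sum(mcols(object@contigs)$contradictions)))
})
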