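---
title: "Phasing co-barcoded long-fragment libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing co-barcoded long-fragment libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `lfrphase`. It is the package's methods reference; the
worked example lives in the README.

## 1. The physical model the simulator emulates

A Long Fragment Read (LFR) library disperses a minute amount of high
molecular weight DNA across a 384-well plate, amplifies it per well, and
sequences short barcoded mate-pairs. The simulator reproduces the
statistics that matter for phasing:

* **DNA per well.** Default 0.54 pg per well (`wellDnaPg`), i.e. about
  200 pg per library. With a haploid genome mass of 3.28 pg
  (`haploidGenomePg`, the human value), each well holds ~16 % of one
  haploid genome, and the plate ~31 diploid cell equivalents. The
  expected number of fragments per well is derived from this mass:
  `wellDnaPg / haploidGenomePg * genomeLength / meanFragmentLength`.
  The mass-to-fragment-count mapping is deliberately configurable
  (`meanFragmentsPerWell` overrides it), since fragment recovery in a
  real library is not 100 %.
* **Fragment lengths.** Uncorrelated random breakage produces
  exponentially distributed lengths; the default decay is 30 kb
  (`decayLengthKb`, typical range 20–50 kb). Starts are uniform;
  fragments overhanging the genome end are clipped. Each fragment comes
  from haplotype 0 or 1 with probability 1/2. Fragment counts per well
  are Poisson, and the number of fragments covering a locus is then
  Poisson as well — the package verifies both properties against
  analytic oracles in its test suite.
* **Reads.** 2×35 bp mate-pair arms (`armLen`) with a uniform mate gap
  of 100–500 bp, sampled uniformly within each fragment at
  `readsPerKb = 23` pairs per kb of fragment. At the default fragment
  coverage (~63× across wells) this yields ~100X total read-base
  coverage, matching the deep-coverage regime the well-count filters
  (Section 6) are calibrated for. Base errors are i.i.d. flips to a
  uniformly chosen other base at `perBaseErrorRate = 0.005`;
  `wellContaminationRate = 0.002` of pairs have their well id replaced
  by a uniformly random other well, emulating cross-well contamination.
* **Variants.** Heterozygous SNP density 1/1500 bp; a homozygous-alt
  density of `hetSnpDensity/1.5` gives a Het/Hom ratio around 1.5, and
  transitions are drawn with probability 2/3 (Ts/Tv ≈ 2). Only SNPs are
  simulated and called — every algorithmic statement the pipeline
  implements concerns SNPs.

**What the simulator does not model:** amplification (MDA) chimeras and
GC/coverage bias, base-quality scores, strandedness (all arms are
forward-strand; the mappers are exercised accordingly), indels and
structural variants, and well dropout. Consequently, passing tests
demonstrate correctness of the *algorithms* under the stated statistical
model, not robustness to every artifact of real libraries; in particular
the single-well concentration of MDA errors is represented only by the
fact that each simulated error lives in one well.

## 2. Coordinates

Plain-integer coordinates (read arm positions, bins, site positions in
the second-mapping tables) are 0-based half-open. Bioconductor containers
(`GRanges` for fragments, variants, contigs) use their native 1-based
closed convention. On disk, BED is 0-based half-open and VCF/var-TSV
1-based, as those formats require.

## 3. Fragment map

The first mapping step assigns each pair the position
`(arm1 + arm2) %/% 2` (the average of the arm positions). In `fast` mode
the simulator's positions are trusted; `strict` mode re-derives them by
exact string search (`Biostrings::PDict`), keeping only pairs whose arms
each occur exactly once with a mate gap in range — this preserves the
"unique exact mapping" contract on small inputs without building a
production aligner. Reads carrying any error are dropped by strict mode,
exactly as an exact-match mapper would.

Per well, mate-pairs are counted in 1 kb bins (`binSize`). Fragments are
maximal streaks of bins with `minReadsPerBin >= 2`, tolerating up to
`maxGapBins = 4` under-threshold bins inside a streak (missing coverage
from non-unique regions); streaks spanning less than
`minFragmentLength = 10 kb` are discarded. The bin threshold and gap
tolerance are not fixed by the underlying method description ("several
consecutive, well-populated bins", "some missing coverage"); the defaults
were chosen once on simulated libraries so that a 23 pairs/kb fragment
interior (~23 pairs per bin) is far above threshold while isolated
mis-placed pairs do not seed fragments. Both remain configurable. A
property-based test checks the streak caller against an exhaustive
run-length scanner on random bin vectors.

Called fragment extents are bin-quantized
(`[startBin*binSize, (endBin+1)*binSize)`), which inflates each fragment
by up to two partial bins. The decay-length estimator uses the
memorylessness of the exponential — the mean excess over the 10 kb
truncation equals the decay — and therefore inherits a ~+1 kb
quantization bias on called fragments; distribution-recovery checks at
tight tolerance are run on true sampled lengths, and the called-fragment
estimate is checked against the 20–50 kb plausibility band.

## 4. Second mapping and strong heterozygous SNPs

Reads are re-mapped only against the fragments of their own well; a pair
whose position falls outside every fragment of its well is dropped (in a
contaminated library these are mostly relabeled pairs). At most one
mismatch per arm is allowed; every mismatch is tracked as
(position, base, well, fragment). An arm spanning two nearby SNPs of its
haplotype is legitimately rejected by the one-mismatch rule; at default
densities this affects well under 1 % of pairs.

Strong het sites are positions where exactly two bases each have
`>= minReads` reads from `>= minWells` distinct wells (three-base
positions are excluded). The thresholds are auto-calibrated by default:
with observed per-base mismatch rate $\hat e$ and read depth $d$, the
number of error-driven candidate (position, base) pairs across a genome
of length $G$ is approximately $3G\,P(\mathrm{Pois}(d\hat e/3) \ge k)$;
the smallest $k \ge 2$ keeping this below 0.5 is used, with
`minWells = max(2, k - 1)`. This keeps the collector sensitive in sparse
clean libraries (where $k$ resolves to 2) and strict at 100X with 0.5 %
error (where $k$ resolves to ~7), without hand-tuning per run. Explicit
thresholds override the rule.

## 5. Fragment-to-allele assignment and phased contigs

Each fragment casts a majority vote (its reads' bases; ties abstain) at
every strong het it covers. Fragments become nodes of an agreement graph:
for every site shared by two voting fragments, their edge accumulates one
agreement (same base) or one disagreement (opposite bases). A two-coloring
of each connected component is sought that minimizes the number of
violated pair-site relations — a max-cut-like problem, solved exactly only
at toy sizes. The algorithm of record:

1. **Exact enumeration** for components with at most 15 fragments
   (lowest fragment id fixed, $2^{n-1}$ labelings scored vectorized).
2. **Greedy BFS seeding** for larger components, coloring each fragment
   by the accumulated signed weight to already-colored neighbours
   (discovery order from the lowest fragment id, making ties
   deterministic).
3. **Suffix-flip sweeps in genomic order**: flipping all fragments from
   rank $k$ onward (fragments sorted by start) is evaluated for every
   $k$ in $O(E)$ via a difference array, and the best negative cut is
   applied repeatedly. This move class repairs whole mis-oriented
   sections — the characteristic failure of single-flip local search,
   where a section is internally consistent but globally inverted and
   no single fragment flip improves the cost.
4. **Single-fragment best-improvement flips** until no flip helps,
   alternating with (3) for up to six rounds.

Fragments whose incident pair relations are violated in a fraction above
`maxContradictionFrac = 0.25` are unassigned ("too many contradictions"
is not quantified by the method description; 0.25 tolerates one bad vote
in four while discarding half-and-half chimeric streaks). Lowering the
tolerance can only shrink the assigned set (tested).

Phased contigs are maximal runs of phased strong hets with adequate
linkage: between consecutive sites, each assigned fragment voting at both
either supports their current relative orientation (both votes consistent
with the fragment's color, or both inconsistent) or conflicts with it;
the contig breaks where support minus conflict falls below
`minLinkSupport = 2`. This subsumes the obvious "no co-covering
fragment" break and also breaks junctions whose evidence is
contradictory, which matters because a mis-joined junction silently
inverts every downstream SNP. Allele labels are consistent within a
contig and arbitrary across contigs.

## 6. Phasing-aware calling and well fields

At candidate sites (some non-reference base seen in `minAltReads` reads,
auto-calibrated like the strong-het rule but with a 0.001/bp budget of
error-driven candidates; strong hets are always candidates), ordered
diallelic hypotheses $(A_0, A_1)$ over the observed bases are scored in
log space. Read likelihoods are $1-e$ / $e/3$; reads assigned to allele
0 via the phased fragment map contribute
$(1-\mu)P(\mathrm{mp}|A_0) + \mu P(\mathrm{mp}|A_1)$ (symmetrically for
allele 1, $\mu = 0.01$), unassigned reads the symmetric average. At
$\mu = 0.5$ phased and unphased scoring coincide exactly (tested). The
genotype prior is flat: 0.001 for any non-reference genotype
(configurable); a call must beat the runner-up genotype by 10 dB or it is
emitted as `VQLOW` instead of `PASS`; best-is-hom-ref sites produce no
record. The orientation of the winning ordered pair determines which
haplotype carries the variant, exported as
`hapLink = Phased_<library>_<contig>_<hap>`.

The six well-count fields are computed from the reads observed at the
locus: wells calling the variant (`wellCount`) and reference
(`refWellCount`), wells calling only one allele (exclusive; the
`ecxclusiveWellCount` spelling is preserved verbatim for file
compatibility), wells calling both (`SharedWellCount`), and the min/max
of the two exclusive counts. The high-confidence cascade applies, in
fixed order: `varFilter == PASS`; `wellCount >= 6` for the variant call
and (het sites only) the reference call; and for het sites
`SharedWellCount <= 0.25 × (MinExclusiveWellCountInThisLocus +
SharedWellCount)`. Rejections are labeled with the first failing rule.
Whether the reference-side well-count requirement applies at hom-alt
sites is not specified by the cascade's description; it is implemented
het-only, following its wording. These thresholds presuppose deep
coverage: at ~31 cell-equivalents and 100X, a true het has ~25 wells per
allele; at 3 cell-equivalents it has ~2 and essentially nothing would
pass, which is why the simulator's defaults reproduce the deep-coverage
regime.

## 7. QC metrics and replicate discordance

The phasing rate is the fraction of heterozygous records whose `hapLink`
contig survives in retained blocks (blocks need `minBlockSnps = 10`
SNPs). N50 is the length L such that blocks of span ≥ L cover half the
total span. Cells-worth of DNA is total called fragment bp over twice the
genome length; it underestimates the dispensed mass by the sub-10 kb tail
(~4.5 % of mass at 30 kb decay) and same-well merges, as documented in
the tests. The genome call rate is approximated as the fraction of probe
positions covered by at least one placed read — the full "fully called"
semantics of a production assembler are out of scope.

Replicate comparison pairs blocks one-to-one greedily by positional
overlap ("completely overlapping blocks" is interpreted as comparison
restricted to sites present, with identical alleles, in both blocks).
Each pair is orientation-aligned to minimize mismatches; mismatching
sites split into maximal runs — length-1 runs are short switches (one
discordant SNP each), runs of ≥ 2 are one long switch event each, and
their SNPs count in neither short tally (an isolated flip adjacent to a
long run is absorbed by the maximal-run partition; a run of two at a
block edge counts as long). Rates divide by the total compared phased
SNPs. Comparisons below `minTotalSnps` (default 10^6, the published
reporting threshold) are flagged `belowThreshold` but still reported —
desk-scale runs are always flagged. An empty overlap yields an empty
report with NA rates rather than an error.

## 8. Problem sizes and numerical notes

* Heavy tests and `scripts/acceptance.R` simulate a **2 Mb genome**; at
  the default ~100X coverage this is ~2.9 M mate-pairs and ~2.5 GB peak
  memory per library, and all reported quantities (phasing rate, switch
  rates) are per-SNP and insensitive to genome length. The zero-noise
  recovery runs use ~3 cell-equivalents, where fragment collisions in a
  well are rare and called fragments correspond ~1:1 to true fragments.
* Determinism: every simulation is seeded; the assignment tie-breaks by
  lowest fragment id; equal-cost hypothesis orientations fall back to
  unphased emission.
* Degenerate inputs: empty read sets, empty coverage maps, libraries
  with a single well (no co-barcoding information: no strong het can
  reach two wells, nothing phases), and zero-variant genomes all return
  well-formed empty results and are covered by tests.
* Known limitations: same-well fragment collisions produce merged
  (possibly chimeric) streaks — at default mass ~16 % of a well's bp
  overlaps another fragment — which the contradiction tolerance and
  contig-break margin absorb but do not resolve into separate fragments;
  multi-chromosome references are handled by concatenation or per-contig
  runs; no indels; no population/pedigree phasing across contig breaks.
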