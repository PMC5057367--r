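#' @include varcall.R
NULL

#' High-confidence haplotype filter configuration
#'
#' The printed filter cascade for extracting very high confidence
#' variants from LFR variant files: (1) \code{varFilter} must be PASS;
#' (2) the variant call — and for heterozygous SNPs also the reference
#' call — must have a wellCount of \code{minWellCount} (default 6) or
#' more; (3) for heterozygous SNPs, \code{SharedWellCount <= sharedFrac x
#' (MinExclusiveWellCountInThisLocus + SharedWellCount)} with
#' \code{sharedFrac} defaulting to 0.25.
#'
#' @param requirePass apply rule 1 (default TRUE).
#' @param minWellCount rule-2 threshold (default 6).
#' @param sharedFrac rule-3 multiplier (default 0.25).
#' @param minBlockSnps minimum SNPs per haplotype block (default 10);
#'   used by [haplotypeBlocks()].
#' @return A named list.
#' @export
filterConfig <- function(requirePass = TRUE, minWellCount = 6L,
                         sharedFrac = 0.25, minBlockSnps = 10L) {
  stopifnot(minWellCount >= 0, sharedFrac >= 0, sharedFrac <= 1,
            minBlockSnps >= 1)
  list(requirePass = isTRUE(requirePass),
       minWellCount = as.integer(minWellCount),
       sharedFrac = sharedFrac,
       minBlockSnps = as.integer(minBlockSnps))
}

#' Apply the high-confidence haplotype filters
#'
#' Rules are applied in the fixed printed order, so each rejected record is
#' labeled with the first failing rule: \code{"varFilter"},
#' \code{"wellCount"}, \code{"sharedWellCount"}, or \code{"malformed"}
#' when a required field is missing.
#'
#' @param records LFR variant records from [callVariants()] (or
#'   [readVarTsv()]).
#' @param cfg a [filterConfig()] list.
#' @return A list with \code{kept} (records passing all rules) and
#'   \code{rejected} (records with a \code{reason} column).
#' @export
applyHaplotypeFilters <- function(records, cfg = filterConfig()) {
  need <- c("genotype", "varFilter", "wellCount", "refWellCount",
            "SharedWellCount", "MinExclusiveWellCountInThisLocus")
  missingCols <- setdiff(need, names(records))
  if (length(missingCols))
    stop("records lack required field(s): ",
         paste(missingCols, collapse = ", "))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  bad <- Reduce(`|`, lapply(records[need[need %in% names(records)]],
                            is.na))
  reason[bad] <- "malformed"

  isHet <- records$genotype == "het"
  r1 <- cfg$requirePass & records$varFilter != "PASS"
  reason[is.na(reason) & r1] <- "varFilter"

  r2 <- records$wellCount < cfg$minWellCount |
    (isHet & records$refWellCount < cfg$minWellCount)
  reason[is.na(reason) & r2] <- "wellCount"

  r3 <- isHet & records$SharedWellCount >
    cfg$sharedFrac * (records$MinExclusiveWellCountInThisLocus +
                      records$SharedWellCount)
  reason[is.na(reason) & r3] <- "sharedWellCount"

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Group filtered het SNPs into haplotype blocks
#'
#' Heterozygous records are grouped by the contig encoded in their
#' \code{hapLink} (\code{"Phased_<library>_<contig>_<hap>"}); blocks with
#' fewer than \code{minBlockSnps} SNPs are dropped. Within a block SNPs are
#' sorted by position and carry the 0/1 haplotype from the final hapLink
#' digit.
#'
#' @param records kept records from [applyHaplotypeFilters()] (or any
#'   record set).
#' @param minBlockSnps minimum SNPs per block (default 10).
#' @return A named list of data.frames (\code{position}, \code{ref},
#'   \code{alt}, \code{hap}), one per retained block, named
#'   \code{"<library>_<contig>"}; each has attributes \code{spanBp} and
#'   \code{contigKey}.
#' @export
haplotypeBlocks <- function(records, minBlockSnps = 10L) {
  het <- records[records$genotype == "het" & !is.na(records$hapLink) &
                 records$hapLink != "", , drop = FALSE]
  if (!nrow(het)) return(structure(list(), class = "lfrBlocks"))
  m <- regmatches(het$hapLink,
                  regexec("^Phased_([0-9]+)_([0-9]+)_([01])$", het$hapLink))
  ok <- lengths(m) == 4L
  het <- het[ok, , drop = FALSE]
  m <- m[ok]
  lib <- vapply(m, `[`, character(1), 2L)
  ctg <- vapply(m, `[`, character(1), 3L)
  hap <- as.integer(vapply(m, `[`, character(1), 4L))
  key <- paste(lib, ctg, sep = "_")
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    if (sum(sel) < minBlockSnps) next
    b <- data.frame(position = het$position[sel], ref = het$ref[sel],
                    alt = het$alt[sel], hap = hap[sel])
    b <- b[order(b$position), , drop = FALSE]
    rownames(b) <- NULL
    attr(b, "spanBp") <- max(b$position) - min(b$position) + 1L
    attr(b, "contigKey") <- k
    out[[k]] <- b
  }
  structure(out, class = "lfrBlocks")
}

#' @export
print.lfrBlocks <- function(x, ...) {
  cat(sprintf("lfrBlocks: %d haplotype blocks, %d phased SNPs\n",
              length(x), sum(vapply(x, nrow, integer(1)))))
  invisible(x)
}
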