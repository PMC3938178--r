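#' Build a quality-filtered, strand-aware pileup
#'
#' Projects read bases onto reference coordinates (CIGAR-aware: aligned bases
#' count, inserted/soft-clipped bases contribute nothing, deleted reference
#' positions get no contribution) and tallies base calls per position and
#' bisulfite strand, keeping only calls with PHRED quality >= `minQ` and
#' excluding 'N' calls. All bases are in '+'-strand orientation as stored in
#' SAM. Reads extending past the end of their contig are skipped and counted.
#'
#' @param reads Reads `data.table` (see [bis_reads()]).
#' @param ref Named character vector of reference sequences
#'   (see [load_reference()]).
#' @param minQ Minimum PHRED quality for a base call to be counted.
#' @return A `data.table` with one row per (chrom, pos, bs_strand, base):
#'   `chrom`, `pos` (0-based), `ref_base`, `bs_strand`, `base`, `count`,
#'   `qual_sum`; sorted by position. Attribute `n_skipped` counts reads
#'   dropped for running past the contig end or mapping to an unknown contig.
#' @export
build_pileup <- function(reads, ref, minQ = 20L) {
  minQ <- as.integer(minQ)
  empty <- data.table(chrom = character(0), pos = integer(0),
                      ref_base = character(0), bs_strand = character(0),
                      base = character(0), count = integer(0),
                      qual_sum = integer(0))
  if (nrow(reads) == 0L) {
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  clens <- nchar(ref)
  known <- reads$chrom %in% names(ref)
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(reads$cigar)
  inside <- rep(FALSE, nrow(reads))
  inside[known] <- reads$start[known] + span[known] <= clens[reads$chrom[known]]
  n_skipped <- sum(!inside)
  kept <- reads[inside]
  ex <- .expand_reads(kept)
  ex <- ex[!is.na(pos) & qual >= minQ & base != "N"]
  ex[, bs_strand := kept$bs_strand[rid]]
  pu <- ex[, .(count = .N, qual_sum = sum(qual)),
           by = .(chrom, pos, bs_strand, base)]
  if (nrow(pu) == 0L) {
    attr(empty, "n_skipped") <- n_skipped
    return(empty)
  }
  # annotate reference base; order chroms in reference order
  pu[, ref_base := substring(ref[chrom], pos + 1L, pos + 1L)]
  pu[, chrom := factor(chrom, levels = names(ref))]
  setorder(pu, chrom, pos, bs_strand, base)
  pu[, chrom := as.character(chrom)]
  setcolorder(pu, c("chrom", "pos", "ref_base", "bs_strand", "base",
                    "count", "qual_sum"))
  attr(pu, "n_skipped") <- n_skipped
  pu[]
}

#' Extract one pileup column
#'
#' Convenience accessor returning the per-strand base counts at a single
#' position, the unit the per-site operations
#' ([usable_allele_counts()], [profile_site()]) work on.
#'
#' @param pileup Pileup table from [build_pileup()].
#' @param chrom,pos Position (0-based).
#' @return Subset of the pileup rows at that position.
#' @export
pileup_column <- function(pileup, chrom, pos) {
  ch <- chrom; p <- pos
  pileup[chrom == ch & pos == p]
}
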