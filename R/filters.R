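# Clonal-read selection and bisulfite-conversion-failure read filtering.
#
# Duplicates are PCR copies of one molecule; selecting by start coordinate
# alone would also collapse allelic co-start reads (heterozygous loci,
# imprinting, hemi-methylation), so reads sharing a start are only considered
# clonal when their high-quality 5' seeds are identical.

# sequencing-5'-oriented sequence/quality of a read ('+'-stored reverse reads
# are flipped back)
.seq_5prime <- function(seq, qual, aln_strand) {
  rev_idx <- aln_strand == "-"
  if (any(rev_idx)) {
    revstr <- function(s) vapply(s, function(x)
      intToUtf8(rev(utf8ToInt(x))), "", USE.NAMES = FALSE)
    seq[rev_idx] <- revstr(seq[rev_idx])
    qual[rev_idx] <- revstr(qual[rev_idx])
  }
  list(seq = seq, qual = qual)
}

#' High-quality 5' seed of a read
#'
#' The seed is the subsequence of the first `seedLen` bases from the
#' sequencing 5' end restricted to positions with quality >= `minQ`,
#' concatenated in read order. An empty seed is allowed.
#'
#' @param seq,qual Sequence and PHRED+33 quality strings, '+'-orientation as
#'   stored in SAM.
#' @param aln_strand "+" or "-"; reverse-aligned reads are flipped back to
#'   sequencing orientation before the seed is taken.
#' @param seedLen Seed window length (bases, default 26).
#' @param minQ Minimum PHRED quality.
#' @return Character vector of seed strings.
#' @export
read_seed <- function(seq, qual, aln_strand = "+", seedLen = 26L, minQ = 20L) {
  n <- length(seq)
  aln_strand <- rep_len(aln_strand, n)
  o <- .seq_5prime(seq, qual, aln_strand)
  vapply(seq_len(n), function(i) {
    s <- utf8ToInt(o$seq[i])
    q <- utf8ToInt(o$qual[i]) - 33L
    k <- min(seedLen, length(s))
    if (k < 1L) return("")
    win <- seq_len(k)
    intToUtf8(s[win][q[win] >= minQ])
  }, "")
}

#' Select one read per clonal group
#'
#' Groups reads by (chrom, start, bisulfite strand) and, within a group, by
#' identical high-quality seed ([read_seed()]). Reads with different seeds are
#' never collapsed (they may carry different alleles). Within a seed subgroup
#' exactly one read is kept: the one with the most bases of quality >= `minQ`;
#' ties go to the longest read, remaining ties are broken uniformly at random
#' (reads are ordered by id first, so the choice depends only on the RNG
#' state, not the input order).
#'
#' @param reads Reads `data.table`.
#' @param seedLen,minQ See [read_seed()].
#' @return The kept reads, with attribute `n_removed`.
#' @export
deduplicate <- function(reads, seedLen = 26L, minQ = 20L) {
  if (nrow(reads) == 0L) {
    out <- copy(reads)
    attr(out, "n_removed") <- 0L
    return(out)
  }
  dt <- copy(reads)
  dt[, `:=`(
    .seed = read_seed(seq, qual, aln_strand, seedLen = seedLen, minQ = minQ),
    .hiq = vapply(qual, function(q) sum(utf8ToInt(q) - 33L >= minQ),
                  0L, USE.NAMES = FALSE),
    .len = nchar(seq))]
  setorder(dt, chrom, start, bs_strand, .seed, -.hiq, -.len, read_id)
  grp <- dt[, .I[{
    top <- .hiq == .hiq[1L] & .len == .len[1L]
    if (sum(top) == 1L) 1L else sample(which(top), 1L)
  }], by = .(chrom, start, bs_strand, .seed)]
  out <- dt[sort(grp$V1)]
  n_removed <- nrow(dt) - nrow(out)
  out[, c(".seed", ".hiq", ".len") := NULL]
  attr(out, "n_removed") <- n_removed
  out[]
}

#' Drop reads with putatively failed bisulfite conversion
#'
#' For each read, counts the covered reference cytosines of the read's
#' bisulfite strand that are in a non-CpG context (next base on that strand
#' not G) with call quality >= `minQ`; of these, `u` read as unconverted
#' (C call at a '+' cytosine for OT reads; G call at a '-' cytosine, i.e. a
#' reference G, for OB reads). A read is dropped when it has such evidence
#' (`n > 0`) and `u/n >= frac`. Samples with genuine non-CpG methylation
#' (plants, embryonic stem cells) should disable this filter.
#'
#' @param reads Reads `data.table`.
#' @param ref Named character vector of reference sequences.
#' @param frac Unconverted fraction threshold (default 0.9).
#' @param minQ Minimum PHRED quality of calls that count as evidence.
#' @return Kept reads, with attribute `n_removed`.
#' @export
bisulfite_failure_filter <- function(reads, ref, frac = 0.9, minQ = 20L) {
  if (nrow(reads) == 0L) {
    out <- copy(reads)
    attr(out, "n_removed") <- 0L
    return(out)
  }
  ex <- .expand_reads(reads)
  ex <- ex[!is.na(pos) & qual >= minQ]
  ex[, ref_base := substring(ref[chrom], pos + 1L, pos + 1L)]
  ex[, next_base := substring(ref[chrom], pos + 2L, pos + 2L)]   # 5'->3' on '+'
  ex[, prev_base := substring(ref[chrom], pos, pos)]             # 5'->3' on '-'
  ex[, bs_strand := reads$bs_strand[rid]]
  # non-CpG cytosines on the read's own bisulfite strand
  ev <- ex[(bs_strand == "OT" & ref_base == "C" & next_base != "G" &
              next_base != "") |
           (bs_strand == "OB" & ref_base == "G" & prev_base != "C" &
              prev_base != "")]
  ev[, unconv := (bs_strand == "OT" & base == "C") |
                 (bs_strand == "OB" & base == "G")]
  stat <- ev[, .(n = .N, u = sum(unconv)), by = rid]
  bad <- stat[n > 0L & u / n >= frac, rid]
  out <- reads[setdiff(seq_len(nrow(reads)), bad)]
  attr(out, "n_removed") <- length(bad)
  out
}
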