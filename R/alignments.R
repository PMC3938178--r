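#' @import data.table
#' @importFrom stats pbinom phyper p.adjust rbinom runif setNames
#' @importFrom utils head tail
NULL

# Aligned bisulfite reads are held in a data.table with one row per read:
#   read_id    character
#   chrom      character
#   start      integer, 0-based leftmost aligned position
#   aln_strand "+" or "-"  (alignment orientation, FLAG 0x10)
#   bs_strand  "OT" or "OB" (original-top / original-bottom bisulfite strand)
#   seq        character, '+'-strand orientation as stored in SAM
#   qual       character, PHRED+33 string, same orientation/length as seq
#   cigar      character
#   mapq       integer

#' Construct a table of aligned bisulfite reads
#'
#' Light-weight constructor used by the simulator and by tests; validates the
#' per-read invariants (equal sequence/quality lengths, non-negative starts,
#' defined bisulfite strand).
#'
#' @param read_id,chrom,start,aln_strand,bs_strand,seq,qual,cigar,mapq
#'   Per-read fields; `start` is 0-based. `cigar` defaults to ungapped
#'   (`<len>M`), `aln_strand` defaults to "+" for OT and "-" for OB reads
#'   (directional protocol).
#' @return A `data.table` of reads.
#' @export
bis_reads <- function(read_id, chrom, start, bs_strand, seq, qual,
                      aln_strand = NULL, cigar = NULL, mapq = 60L) {
  n <- length(seq)
  if (is.null(aln_strand)) aln_strand <- ifelse(bs_strand == "OT", "+", "-")
  if (is.null(cigar)) cigar <- paste0(nchar(seq), "M")
  dt <- data.table(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   start = as.integer(start),
                   aln_strand = as.character(aln_strand),
                   bs_strand = as.character(bs_strand),
                   seq = toupper(as.character(seq)),
                   qual = as.character(qual),
                   cigar = as.character(cigar),
                   mapq = rep_len(as.integer(mapq), n))
  if (any(nchar(dt$seq) != nchar(dt$qual)))
    stop("seq and qual must have equal lengths for every read")
  if (any(dt$start < 0L)) stop("read start positions must be >= 0")
  if (!all(dt$bs_strand %in% c("OT", "OB")))
    stop("bs_strand must be 'OT' or 'OB' for every read")
  dt[]
}

#' Assign the bisulfite strand of an aligned read
#'
#' A Bismark-style `XG` tag takes precedence (`CT` = original top strand,
#' `GA` = original bottom); without a tag the FLAG reverse bit is used under
#' the directional-protocol assumption (forward = OT, reverse = OB). A tag
#' contradicting the FLAG raises a warning and the tag wins.
#'
#' @param xg `XG` tag values (character, `NA` when absent).
#' @param flag SAM FLAG integers.
#' @return Character vector of "OT"/"OB", `NA` where unassignable.
#' @export
assign_bisulfite_strand <- function(xg, flag) {
  n <- max(length(xg), length(flag))
  xg <- rep_len(as.character(xg), n)
  flag <- rep_len(as.integer(flag), n)
  from_flag <- ifelse(bitwAnd(flag, 16L) > 0L, "OB", "OT")
  from_tag <- ifelse(is.na(xg), NA_character_,
                     ifelse(xg == "CT", "OT", ifelse(xg == "GA", "OB", NA_character_)))
  bad_tag <- !is.na(xg) & is.na(from_tag)
  if (any(bad_tag))
    warning(sum(bad_tag), " read(s) with unparseable XG tag; skipped")
  out <- ifelse(is.na(from_tag), from_flag, from_tag)
  out[bad_tag] <- NA_character_
  contradict <- !is.na(from_tag) & from_tag != from_flag
  if (any(contradict))
    warning(sum(contradict),
            " read(s) with XG tag contradicting FLAG strand; tag used")
  out
}

#' Read bisulfite alignments from SAM/BAM
#'
#' Loads a coordinate-sorted SAM or BAM file (detected by extension; SAM is
#' converted on the fly), skips unmapped/secondary/supplementary records, and
#' assigns each read its bisulfite strand (see [assign_bisulfite_strand()]).
#'
#' @param path SAM or BAM file.
#' @return A reads `data.table` (see [bis_reads()]) with an attribute
#'   `n_skipped` counting records without an assignable bisulfite strand.
#' @export
read_bs_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  flg <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = "XG", flag = flg)
  res <- Rsamtools::scanBam(bam, param = prm)[[1]]
  n <- length(res$qname)
  if (n == 0L) {
    rd <- bis_reads(character(0), character(0), integer(0), character(0),
                    character(0), character(0))
    attr(rd, "n_skipped") <- 0L
    return(rd)
  }
  bss <- assign_bisulfite_strand(res$tag$XG, res$flag)
  keep <- !is.na(bss)
  n_skipped <- sum(!keep)
  dt <- data.table(
    read_id = res$qname[keep],
    chrom = as.character(res$rname)[keep],
    start = res$pos[keep] - 1L,
    aln_strand = ifelse(bitwAnd(res$flag[keep], 16L) > 0L, "-", "+"),
    bs_strand = bss[keep],
    seq = as.character(res$seq)[keep],
    qual = as.character(res$qual)[keep],
    cigar = res$cigar[keep],
    mapq = res$mapq[keep])
  attr(dt, "n_skipped") <- n_skipped
  dt
}

# decode PHRED+33 quality strings into one long integer vector
.decode_quals <- function(qual) {
  if (length(qual) == 0L) return(integer(0))
  utf8ToInt(paste(qual, collapse = "")) - 33L
}

# per-base reference positions for one read with a gapped CIGAR; NA for
# inserted/soft-clipped bases. qlen is the stored sequence length.
.cigar_refpos <- function(ops, lens, start, qlen) {
  out <- rep(NA_integer_, qlen)
  q <- 0L; r <- start
  for (i in seq_along(ops)) {
    op <- ops[i]; l <- lens[i]
    if (op %in% c("M", "=", "X")) {
      out[(q + 1L):(q + l)] <- r + 0L:(l - 1L)
      q <- q + l; r <- r + l
    } else if (op %in% c("I", "S")) {
      q <- q + l
    } else if (op %in% c("D", "N")) {
      r <- r + l
    } # H, P consume nothing
  }
  if (q != qlen) stop("CIGAR query length does not match sequence length")
  out
}

# Expand reads into one row per stored base:
#   rid (row index into `reads`), chrom, pos (0-based ref, NA for
#   insertions/clips), base (single char), qual (integer PHRED)
.expand_reads <- function(reads) {
  n <- nrow(reads)
  if (n == 0L)
    return(data.table(rid = integer(0), chrom = character(0),
                      pos = integer(0), base = character(0),
                      qual = integer(0)))
  w <- nchar(reads$seq)
  rid <- rep(seq_len(n), w)
  base_int <- utf8ToInt(paste(reads$seq, collapse = ""))
  qual <- .decode_quals(reads$qual)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  pos <- rep(NA_integer_, length(rid))
  offs <- sequence(w) - 1L
  idx_simple <- simple[rid]
  pos[idx_simple] <- reads$start[rid[idx_simple]] + offs[idx_simple]
  if (!all(simple)) {
    which_cx <- which(!simple)
    ops <- GenomicAlignments::explodeCigarOps(reads$cigar[which_cx])
    lens <- GenomicAlignments::explodeCigarOpLengths(reads$cigar[which_cx])
    bounds <- c(0L, cumsum(w))
    for (j in seq_along(which_cx)) {
      i <- which_cx[j]
      pos[(bounds[i] + 1L):bounds[i + 1L]] <-
        .cigar_refpos(ops[[j]], lens[[j]], reads$start[i], w[i])
    }
  }
  data.table(rid = rid, chrom = reads$chrom[rid], pos = pos,
             base = strsplit(intToUtf8(base_int), "", fixed = TRUE)[[1]],
             qual = qual)
}

#' Trim the sequencing 5' end of reads
#'
#' Removes `n` bases from each read's sequencing 5' end (as done for the MspI
#' restriction site of non-directional RRBS). For a forward-aligned read this
#' advances the leftmost position; for a reverse-aligned read the 5' end is
#' the rightmost aligned base, so the right end is clipped and the start is
#' unchanged. Reads shorter than `n + 1` bases are dropped and counted in the
#' `n_dropped` attribute. Only ungapped (all-M) alignments are trimmed; gapped
#' reads are kept untouched and counted in `n_untrimmed`.
#'
#' @param reads Reads `data.table` (see [bis_reads()]).
#' @param n Number of bases to remove from the 5' end.
#' @return Trimmed reads table with attributes `n_dropped`, `n_untrimmed`.
#' @export
trim_5prime <- function(reads, n) {
  n <- as.integer(n)
  if (n < 0L) stop("'n' must be >= 0")
  if (n == 0L || nrow(reads) == 0L) {
    out <- copy(reads)
    attr(out, "n_dropped") <- 0L
    attr(out, "n_untrimmed") <- 0L
    return(out)
  }
  len <- nchar(reads$seq)
  simple <- grepl("^[0-9]+M$", reads$cigar)
  drop <- simple & (len <= n)
  keep <- !drop
  out <- copy(reads[keep])
  lenk <- len[keep]
  simp <- simple[keep]
  fwd <- out$aln_strand == "+"
  ii <- simp & fwd
  out[ii, `:=`(seq = substring(seq, n + 1L),
               qual = substring(qual, n + 1L),
               start = start + n,
               cigar = paste0(lenk[ii] - n, "M"))]
  ii <- simp & !fwd
  out[ii, `:=`(seq = substring(seq, 1L, lenk[ii] - n),
               qual = substring(qual, 1L, lenk[ii] - n),
               cigar = paste0(lenk[ii] - n, "M"))]
  attr(out, "n_dropped") <- sum(drop)
  attr(out, "n_untrimmed") <- sum(!simple)
  out
}
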