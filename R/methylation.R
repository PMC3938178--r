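# Per-cytosine methylation profiling. Cytosines on both genomic strands are
# profiled separately ('+' cytosines from original-top-strand reads, '-'
# cytosines -- reference G on '+' -- from original-bottom-strand reads); the
# two members of a CpG are reported as separate records.

#' Sequence context of a cytosine
#'
#' Classifies a cytosine position into CG, CHG or CHH (H = A, C or T) from
#' the reference sequence, reading 5' to 3' on the cytosine's strand. Returns
#' `NA` when the two downstream bases run off the contig.
#'
#' @param ref_seq Reference sequence (single string).
#' @param pos 0-based position(s), expressed in '+' coordinates. For
#'   `strand = "-"` the '+' base must be G (a cytosine on the minus strand).
#' @param strand "+" or "-" (recycled).
#' @return Character vector: "CG", "CHG", "CHH" or `NA`.
#' @export
assign_context <- function(ref_seq, pos, strand = "+") {
  n <- length(pos)
  strand <- rep_len(strand, n)
  L <- nchar(ref_seq)
  base <- substring(ref_seq, pos + 1L, pos + 1L)
  plus <- strand == "+"
  if (any(plus & base != "C") || any(!plus & base != "G"))
    stop("assign_context called on a non-cytosine position")
  d1 <- d2 <- rep(NA_character_, n)
  if (any(plus)) {
    d1[plus] <- substring(ref_seq, pos[plus] + 2L, pos[plus] + 2L)
    d2[plus] <- substring(ref_seq, pos[plus] + 3L, pos[plus] + 3L)
  }
  # downstream on '-' strand: '+' positions pos-1, pos-2, complemented
  mn <- !plus
  if (any(mn)) {
    d1[mn] <- chartr("ACGT", "TGCA", substring(ref_seq, pos[mn], pos[mn]))
    d2[mn] <- chartr("ACGT", "TGCA",
                     substring(ref_seq, pmax(pos[mn] - 1L, 0L), pos[mn] - 1L))
  }
  out <- ifelse(d1 == "G", "CG", ifelse(d2 == "G", "CHG", "CHH"))
  out[d1 == "" | (d1 != "G" & d2 == "")] <- NA_character_
  out
}

#' All cytosine positions of a reference, with contexts
#'
#' @param ref Named character vector of reference sequences.
#' @return `data.table` with `chrom`, `pos` (0-based '+' coordinate),
#'   `strand`, `context`; cytosines whose context runs off the contig are
#'   omitted, as are reference 'N' positions.
#' @export
cytosine_contexts <- function(ref) {
  res <- lapply(names(ref), function(ch) {
    s <- ref[[ch]]
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    pp <- which(b == "C") - 1L
    pm <- which(b == "G") - 1L
    dt <- rbind(
      data.table(chrom = ch, pos = pp, strand = "+"),
      data.table(chrom = ch, pos = pm, strand = "-"))
    if (nrow(dt) == 0L) return(dt[, context := character(0)])
    dt[, context := assign_context(s, pos, strand)]
    dt[!is.na(context)]
  })
  out <- rbindlist(res)
  setorder(out, chrom, pos, strand)
  out[]
}

#' Profile a single cytosine column
#'
#' Per-site form of the methylation read-out, operating on one pileup column
#' (see [pileup_column()]). Only reads from the matching bisulfite strand are
#' informative (OT for '+' cytosines, OB for '-'); unconverted calls (C on
#' '+', G on '-') count as methylcytosines and converted calls (T on '+',
#' A on '-') as unmethylated; any other base call is evidence of sequence
#' variation and is excluded from the coverage.
#'
#' @param column Pileup rows at one position.
#' @param strand Strand of the cytosine ("+" or "-").
#' @param context Context label to attach.
#' @param minDepthMeth Minimum informative coverage; below it `NULL` is
#'   returned.
#' @return One-row `data.table` (`chrom`, `pos`, `strand`, `context`,
#'   `mc_count`, `cov`, `mean_qual`, `level`) or `NULL`.
#' @export
profile_site <- function(column, strand, context, minDepthMeth = 3L) {
  if (strand == "+") {
    inf <- column[bs_strand == "OT" & base %in% c("C", "T")]
    mc <- sum(inf[base == "C", count])
  } else {
    inf <- column[bs_strand == "OB" & base %in% c("G", "A")]
    mc <- sum(inf[base == "G", count])
  }
  cov <- sum(inf$count)
  if (cov < minDepthMeth) return(NULL)
  data.table(chrom = column$chrom[1L], pos = column$pos[1L], strand = strand,
             context = context, mc_count = as.integer(mc),
             cov = as.integer(cov),
             mean_qual = round(sum(inf$qual_sum) / cov, 2),
             level = mc / cov)
}

#' Profile methylation over a whole pileup
#'
#' Vectorised methylation read-out for every reference cytosine (both
#' strands) with informative coverage >= `minDepthMeth`. Reference 'N'
#' positions and cytosines whose context runs off the contig are never
#' profiled.
#'
#' @param pileup Pileup table from [build_pileup()].
#' @param ref Named character vector of reference sequences.
#' @param minDepthMeth Minimum informative coverage (default 3).
#' @param contexts Context classes to report.
#' @return Sites `data.table`: `chrom`, `pos` (0-based), `strand`, `context`,
#'   `mc_count`, `cov`, `mean_qual`, `level`, sorted by position.
#' @export
profile_methylation <- function(pileup, ref, minDepthMeth = 3L,
                                contexts = c("CG", "CHG", "CHH")) {
  ctx <- cytosine_contexts(ref)
  empty <- data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      mc_count = integer(0), cov = integer(0),
                      mean_qual = numeric(0), level = numeric(0))
  if (nrow(pileup) == 0L || nrow(ctx) == 0L) return(empty)
  inf <- rbind(
    pileup[ref_base == "C" & bs_strand == "OT" & base %in% c("C", "T")
           ][, .(chrom, pos, strand = "+", mc = (base == "C") * count,
                 count, qual_sum)],
    pileup[ref_base == "G" & bs_strand == "OB" & base %in% c("G", "A")
           ][, .(chrom, pos, strand = "-", mc = (base == "G") * count,
                 count, qual_sum)])
  if (nrow(inf) == 0L) return(empty)
  sites <- inf[, .(mc_count = as.integer(sum(mc)), cov = sum(count),
                   mean_qual = round(sum(qual_sum) / sum(count), 2)),
               by = .(chrom, pos, strand)]
  sites <- sites[cov >= minDepthMeth]
  sites <- merge(sites, ctx, by = c("chrom", "pos", "strand"))
  sites <- sites[context %in% contexts]
  sites[, level := mc_count / cov]
  sites[, chrom := factor(chrom, levels = names(ref))]
  setorder(sites, chrom, pos, strand)
  sites[, chrom := as.character(chrom)]
  setcolorder(sites, c("chrom", "pos", "strand", "context", "mc_count",
                       "cov", "mean_qual", "level"))
  sites[]
}
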