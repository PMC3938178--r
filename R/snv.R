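# Strand-aware SNV detection from bisulfite alignments, adapted from the
# VarScan strategy: candidate alleles by relative frequency, a one-sided
# Fisher exact test against the expected sequencing-error rate, and genotype
# assignment from the two most frequent alleles.
#
# Bisulfite conversion confounds base identities in a strand-specific way:
# on original-top-strand (OT) reads a T call may be a converted C, and on
# original-bottom-strand (OB) reads ('+'-oriented, as stored in SAM) an A
# call may be a converted G. Those calls carry no variant information and
# are excluded; everything else is usable on either strand.

.BASES <- c("A", "C", "G", "T")

#' Usable allele counts at a position
#'
#' Sums quality-passing base calls over both bisulfite strands after
#' removing the conversion-confounded identities: T calls from OT reads and
#' A calls from OB reads.
#'
#' @param column Pileup rows at one position (see [pileup_column()]).
#' @return Named integer vector over A/C/G/T (zeros included).
#' @export
usable_allele_counts <- function(column) {
  use <- column[(bs_strand == "OT" & base != "T") |
                (bs_strand == "OB" & base != "A")]
  out <- setNames(integer(4L), .BASES)
  if (nrow(use) > 0L) {
    agg <- use[, .(count = sum(count)), by = base]
    out[agg$base] <- as.integer(agg$count)
  }
  out
}

#' Detect candidate variant alleles
#'
#' A non-reference base is a candidate when its relative frequency among the
#' usable calls is at least `varFraction`; positions with usable depth below
#' `minDepthSNV` yield no candidates.
#'
#' @param counts Named counts from [usable_allele_counts()].
#' @param ref_base Reference base at the position.
#' @param varFraction Minimum relative allele frequency (default 0.1).
#' @param minDepthSNV Minimum usable depth (default 1).
#' @return Character vector of candidate bases (possibly empty).
#' @export
detect_candidates <- function(counts, ref_base, varFraction = 0.1,
                              minDepthSNV = 1L) {
  total <- sum(counts)
  if (total < minDepthSNV || total == 0L) return(character(0))
  cand <- setdiff(names(counts)[counts / total >= varFraction], ref_base)
  cand[counts[cand] > 0L]
}

#' One-sided Fisher exact test for a variant position
#'
#' Tests the observed reference/variant split against the split expected
#' from sequencing error alone, via the exact hypergeometric tail of the
#' 2x2 table `[[n_ref, n_var], [round(N(1-e)), round(N e)]]` with the
#' alternative of variant enrichment.
#'
#' @param n_ref Usable reference-base count.
#' @param n_var Summed usable count of the candidate variant bases.
#' @param depth Total usable depth `N` at the position.
#' @param err_rate Expected per-base error rate `e` (default 0.01).
#' @return The exact tail probability (1 for a degenerate table).
#' @export
variant_pvalue <- function(n_ref, n_var, depth, err_rate = 0.01) {
  stopifnot(length(n_ref) == length(n_var), length(depth) == length(n_ref))
  e_var <- round(depth * err_rate)
  e_ref <- round(depth * (1 - err_rate))
  m <- n_var + e_var            # column margin: variant calls
  n <- n_ref + e_ref            # column margin: reference calls
  k <- n_ref + n_var            # row margin: observed sample
  p <- phyper(n_var - 1, m, n, k, lower.tail = FALSE)
  p[depth == 0 | k == 0] <- 1
  p[n_var == 0] <- 1
  pmin(pmax(p, 0), 1)
}

#' Genotype assignment at a candidate position
#'
#' The two highest-count bases among the reference and the candidates form
#' the putative genotype; when the runner-up's frequency falls below
#' `varFraction` the call is homozygous for the top base. Count ties break
#' by fixed base order A < C < G < T. No call is made when `p_value` is not
#' below `maxPval`, or when the genotype collapses to homozygous reference.
#'
#' @param counts Named counts from [usable_allele_counts()].
#' @param ref_base Reference base.
#' @param candidates Candidate bases from [detect_candidates()].
#' @param p_value Fisher-test p-value for the position.
#' @param varFraction,maxPval See [bs_config()].
#' @return A one-row `data.table` (`a1`, `a2`, `zygosity`) or `NULL`.
#' @export
call_genotype <- function(counts, ref_base, candidates, p_value,
                          varFraction = 0.1, maxPval = 0.05) {
  if (length(candidates) == 0L || p_value >= maxPval) return(NULL)
  pool <- union(ref_base, candidates)
  cnt <- counts[pool]
  ord <- order(-cnt, match(pool, .BASES))
  total <- sum(counts)
  a1 <- pool[ord[1L]]
  a2 <- if (length(pool) > 1L) pool[ord[2L]] else a1
  if (length(pool) > 1L && counts[a2] / total < varFraction) a2 <- a1
  if (a1 == ref_base && a2 == ref_base) return(NULL)
  data.table(a1 = a1, a2 = a2,
             zygosity = if (a1 == a2) "hom" else "het")
}

#' Call SNVs over a whole pileup
#'
#' Vectorised application of [usable_allele_counts()],
#' [detect_candidates()], [variant_pvalue()] and [call_genotype()] to every
#' covered position with a known (non-N) reference base.
#'
#' @param pileup Pileup table from [build_pileup()].
#' @param cfg A [bs_config()] object.
#' @return Calls `data.table`: `chrom`, `pos` (0-based), `ref_base`, `a1`,
#'   `a2`, `zygosity`, `depth_usable`, per-base counts `n_A..n_T`,
#'   `p_value`; sorted by position.
#' @export
call_snvs <- function(pileup, cfg = bs_config()) {
  empty <- data.table(chrom = character(0), pos = integer(0),
                      ref_base = character(0), a1 = character(0),
                      a2 = character(0), zygosity = character(0),
                      depth_usable = integer(0), n_A = integer(0),
                      n_C = integer(0), n_G = integer(0), n_T = integer(0),
                      p_value = numeric(0))
  if (nrow(pileup) == 0L) return(empty)
  use <- pileup[ref_base %in% .BASES &
                ((bs_strand == "OT" & base != "T") |
                 (bs_strand == "OB" & base != "A"))]
  if (nrow(use) == 0L) return(empty)
  wide <- dcast(use, chrom + pos + ref_base ~ base,
                value.var = "count", fun.aggregate = sum, fill = 0L)
  for (b in setdiff(.BASES, names(wide))) wide[, (b) := 0L]
  setnames(wide, .BASES, paste0("n_", .BASES))
  wide[, depth_usable := n_A + n_C + n_G + n_T]
  wide <- wide[depth_usable >= cfg$minDepthSNV]
  if (nrow(wide) == 0L) return(empty)
  cnt <- as.matrix(wide[, .(n_A, n_C, n_G, n_T)])
  colnames(cnt) <- .BASES
  total <- wide$depth_usable
  ridx <- match(wide$ref_base, .BASES)
  n_ref <- cnt[cbind(seq_len(nrow(cnt)), ridx)]
  is_cand <- cnt / total >= cfg$varFraction & cnt > 0L
  is_cand[cbind(seq_len(nrow(cnt)), ridx)] <- FALSE
  n_var <- rowSums(cnt * is_cand)
  keep <- n_var > 0L
  if (!any(keep)) return(empty)
  wide <- wide[keep]; cnt <- cnt[keep, , drop = FALSE]
  is_cand <- is_cand[keep, , drop = FALSE]
  total <- total[keep]; ridx <- ridx[keep]
  n_ref <- n_ref[keep]; n_var <- n_var[keep]
  pv <- variant_pvalue(n_ref, n_var, total, cfg$errRate)
  sig <- pv < cfg$maxPval
  if (!any(sig)) return(empty)
  wide <- wide[sig]; cnt <- cnt[sig, , drop = FALSE]
  is_cand <- is_cand[sig, , drop = FALSE]
  total <- total[sig]; ridx <- ridx[sig]; pv <- pv[sig]
  # genotype: two highest counts among {ref} + candidates, ties A<C<G<T
  pool <- is_cand
  pool[cbind(seq_len(nrow(pool)), ridx)] <- TRUE
  score <- ifelse(pool, cnt, -1)                  # exclude non-pool bases
  rank_key <- score * 8 - matrix(rep(1:4, each = nrow(score)), ncol = 4)
  o1 <- max.col(rank_key, ties.method = "first")
  rk2 <- rank_key
  rk2[cbind(seq_len(nrow(rk2)), o1)] <- -Inf
  o2 <- max.col(rk2, ties.method = "first")
  a1 <- .BASES[o1]
  a2 <- .BASES[o2]
  second_ok <- pool[cbind(seq_len(nrow(pool)), o2)] &
    cnt[cbind(seq_len(nrow(cnt)), o2)] / total >= cfg$varFraction
  a2[!second_ok] <- a1[!second_ok]
  res <- wide[, .(chrom, pos, ref_base, n_A, n_C, n_G, n_T,
                  depth_usable)]
  res[, `:=`(a1 = a1, a2 = a2,
             zygosity = ifelse(a1 == a2, "hom", "het"),
             p_value = pv)]
  res <- res[!(a1 == ref_base & a2 == ref_base)]
  setcolorder(res, c("chrom", "pos", "ref_base", "a1", "a2", "zygosity",
                     "depth_usable", "n_A", "n_C", "n_G", "n_T", "p_value"))
  setorder(res, chrom, pos)
  res[]
}
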