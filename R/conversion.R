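# Bisulfite conversion-rate estimation and the binomial assessment of
# conversion error: given the failure rate p = 1 - conversion rate, the
# probability that more than fmc of the observed methylcytosines are
# conversion failures -- i.e. that the real methylation level lies outside
# the chosen error interval of the observed level.

#' Estimate the bisulfite conversion rate from a control genome
#'
#' The control genome (lambda phage, chloroplast, ...) is assumed fully
#' unmethylated, so every informative cytosine call is either converted
#' (T on the '+' strand / A on the '-') or a conversion failure (C / G).
#' The rate is converted / (converted + unconverted) over the cytosines of
#' both strands, using calls with quality >= `minQ`.
#'
#' @param x Either a pileup `data.table` from [build_pileup()] or a path to
#'   a SAM/BAM file of control alignments.
#' @param ref Named character vector with the control reference.
#' @param minQ Minimum PHRED quality (used when `x` is a file path).
#' @return List of class `bs_convrate`: `rate`, `converted`, `unconverted`,
#'   `by_context` (per-context data.table).
#' @export
estimate_conversion_rate <- function(x, ref, minQ = 20L) {
  pileup <- if (is.character(x)) {
    build_pileup(read_bs_alignments(x), ref, minQ = minQ)
  } else x
  inf <- rbind(
    pileup[ref_base == "C" & bs_strand == "OT" & base %in% c("C", "T")
           ][, .(chrom, pos, strand = "+", conv = (base == "T") * count,
                 count)],
    pileup[ref_base == "G" & bs_strand == "OB" & base %in% c("G", "A")
           ][, .(chrom, pos, strand = "-", conv = (base == "A") * count,
                 count)])
  if (nrow(inf) == 0L || sum(inf$count) == 0L)
    stop("no informative cytosine calls in the control alignments")
  conv <- sum(inf$conv)
  tot <- sum(inf$count)
  ctx <- cytosine_contexts(ref)
  byctx <- merge(inf, ctx, by = c("chrom", "pos", "strand"))[,
    .(converted = sum(conv), total = sum(count)), by = context][,
    rate := converted / total][order(context)]
  structure(list(rate = conv / tot, converted = conv,
                 unconverted = tot - conv, by_context = byctx[]),
            class = "bs_convrate")
}

#' @export
print.bs_convrate <- function(x, ...) {
  cat(sprintf("Bisulfite conversion rate: %.4f (%d converted / %d informative calls)\n",
              x$rate, x$converted, x$converted + x$unconverted))
  if (nrow(x$by_context) > 0L) {
    cat("Per-context rates:\n")
    for (i in seq_len(nrow(x$by_context)))
      cat(sprintf("  %-4s %.4f (%d/%d)\n", x$by_context$context[i],
                  x$by_context$rate[i], x$by_context$converted[i],
                  x$by_context$total[i]))
  }
  invisible(x)
}

#' Maximum tolerated number of false methylcytosines
#'
#' The largest `f` in `[0, mc]` such that removing `f` methylcytosines keeps
#' the level within the error interval:
#' `(mc - f)/cov >= mc/cov - interval`, i.e. `min(mc, floor(interval * cov))`
#' (inclusive at exact equality).
#'
#' @param mc Observed methylcytosine count(s).
#' @param cov Coverage(s), > 0.
#' @param interval Error-interval width in `[0, 1]`.
#' @return Integer vector of maxima.
#' @export
max_false_mc <- function(mc, cov, interval) {
  if (any(cov <= 0)) stop("'cov' must be > 0")
  if (any(mc < 0 | mc > cov)) stop("'mc' must be in [0, cov]")
  if (any(interval < 0 | interval > 1)) stop("'interval' must be in [0, 1]")
  as.integer(pmin(mc, floor(interval * cov + 1e-9)))
}

#' Binomial p-value for bisulfite conversion error
#'
#' Probability of observing more than `fmc` false methylcytosines among `mc`
#' observed ones when each is independently a conversion failure with
#' probability `p`: `1 - CDF_Binomial(fmc; mc, p)`, evaluated with the
#' numerically stable survival form. This is the probability that the real
#' methylation level lies outside the chosen error interval.
#'
#' @param mc Observed methylcytosine count(s).
#' @param fmc Maximum tolerated false methylcytosines, in `[0, mc]`.
#' @param p Bisulfite failure rate (1 - conversion rate), in `[0, 1]`.
#' @return Numeric p-value(s).
#' @export
meth_pvalue <- function(mc, fmc, p) {
  if (any(fmc < 0 | fmc > mc)) stop("'fmc' must be in [0, mc]")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  if (any(mc < 0)) stop("'mc' must be >= 0")
  pbinom(fmc, mc, p, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Standard step-up procedure: with `m` p-values sorted ascending, find the
#' largest `k` with `p(k) <= k * alpha / m` and flag the first `k`;
#' q-values are the usual monotone BH adjustment (`stats::p.adjust`).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level.
#' @return List with `q_values` and logical `significant`, in input order.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(q_values = numeric(0), significant = logical(0)))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  q <- p.adjust(p_values, method = "BH")
  list(q_values = q, significant = q <= alpha)
}

#' Conversion-error test over a methylation sites table
#'
#' Appends `fmc`, `p_value` and (optionally) `q_value` columns to a sites
#' table: `fmc` from [max_false_mc()], `p_value` from [meth_pvalue()] with
#' failure rate `1 - conv_rate`. Sites with `mc_count = 0` have `p_value` 0
#' (no false methylcytosines are possible).
#'
#' @param sites Sites `data.table` (from [profile_methylation()] or
#'   [read_meth_tab()]).
#' @param conv_rate Bisulfite conversion rate from the control genome.
#' @param interval Error-interval width (default 0.1).
#' @param fdr Apply [bh_fdr()] and append `q_value`.
#' @param fdr_alpha FDR level.
#' @return The sites table with appended columns (a copy).
#' @export
meth_test <- function(sites, conv_rate, interval = 0.1, fdr = FALSE,
                      fdr_alpha = 0.05) {
  if (conv_rate < 0 || conv_rate > 1) stop("'conv_rate' must be in [0, 1]")
  out <- copy(sites)
  if (nrow(out) == 0L) {
    out[, `:=`(fmc = integer(0), p_value = numeric(0))]
    if (fdr) out[, q_value := numeric(0)]
    return(out[])
  }
  out[, fmc := max_false_mc(mc_count, cov, interval)]
  out[, p_value := meth_pvalue(mc_count, fmc, 1 - conv_rate)]
  if (fdr) {
    res <- bh_fdr(out$p_value, alpha = fdr_alpha)
    out[, q_value := res$q_values]
  }
  out[]
}
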