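# Benchmarking against simulation truth: SNV sensitivity / positive
# predictive value and the fraction of correctly profiled methylation
# levels (a site counts as correct only when the obtained level equals the
# simulated one exactly).

#' Evaluate calls and methylation sites against simulation truth
#'
#' An SNV call is a true positive when a variant was planted at its
#' position and the called genotype matches the planted one (heterozygous:
#' reference + alternative allele; homozygous: alternative twice); any
#' other call — at a non-variant position or with the wrong genotype — is a
#' false positive. Methylation is scored over profiled cytosines present in
#' the truth table (variant-free reference cytosines): a site is correct
#' only if its level equals the simulated level exactly.
#'
#' @param calls Calls `data.table` from [call_snvs()].
#' @param sites Sites `data.table` from [profile_methylation()].
#' @param truth_variants Truth table from [simulate_diploid()]
#'   (`genome$variants`).
#' @param truth_meth Truth table from [simulate_methylome()]
#'   (`methylome$truth_meth`).
#' @return List of class `bs_eval`: `sn`, `ppv` (`NA` when no calls),
#'   `correct_meth_fraction`, `cpg_coverage_fraction`, and the underlying
#'   counts (`tp`, `fp`, `fn`, `n_calls`, `n_truth`, `n_sites_scored`).
#' @export
evaluate_calls <- function(calls, sites, truth_variants, truth_meth) {
  if (is.null(sites))
    sites <- data.table(chrom = character(0), pos = integer(0),
                        strand = character(0), context = character(0),
                        mc_count = integer(0), cov = integer(0),
                        mean_qual = numeric(0), level = numeric(0))
  tv <- copy(truth_variants)
  tv[, `:=`(t1 = ifelse(zygosity == "het", ref, alt), t2 = alt)]
  tv[, gt_true := paste(pmin(t1, t2), pmax(t1, t2), sep = "/")]
  cl <- copy(calls)
  if (nrow(cl) > 0L) {
    cl[, gt_call := paste(pmin(a1, a2), pmax(a1, a2), sep = "/")]
    m <- merge(cl[, .(chrom, pos, gt_call)],
               tv[, .(chrom, pos, gt_true)], by = c("chrom", "pos"))
    tp <- sum(m$gt_call == m$gt_true)
  } else tp <- 0L
  n_calls <- nrow(cl)
  n_truth <- nrow(tv)
  fp <- n_calls - tp
  fn <- n_truth - tp
  sn <- if (n_truth > 0L) tp / n_truth else NA_real_
  ppv <- if (n_calls > 0L) tp / n_calls else NA_real_
  scored <- merge(sites, truth_meth[, .(chrom, pos, strand, true_level = level)],
                  by = c("chrom", "pos", "strand"))
  correct_meth <- if (nrow(scored) > 0L)
    mean(abs(scored$level - scored$true_level) < 1e-9) else NA_real_
  n_true_cpg <- nrow(truth_meth[context == "CG"])
  n_prof_cpg <- nrow(merge(sites[context == "CG", .(chrom, pos, strand)],
                           truth_meth[context == "CG",
                                      .(chrom, pos, strand)],
                           by = c("chrom", "pos", "strand")))
  cpg_cov <- if (n_true_cpg > 0L) n_prof_cpg / n_true_cpg else NA_real_
  structure(list(sn = sn, ppv = ppv,
                 correct_meth_fraction = correct_meth,
                 cpg_coverage_fraction = cpg_cov,
                 tp = tp, fp = fp, fn = fn, n_calls = n_calls,
                 n_truth = n_truth, n_sites_scored = nrow(scored)),
            class = "bs_eval")
}

#' @export
print.bs_eval <- function(x, ...) {
  cat(sprintf("SNV calling:   Sn = %s, PPV = %s (TP %d, FP %d, FN %d)\n",
              format(x$sn, digits = 4), format(x$ppv, digits = 4),
              x$tp, x$fp, x$fn))
  cat(sprintf("Methylation:   correct fraction = %s over %d scored sites\n",
              format(x$correct_meth_fraction, digits = 4),
              x$n_sites_scored))
  cat(sprintf("CpG coverage:  %s\n", format(x$cpg_coverage_fraction,
                                            digits = 4)))
  invisible(x)
}
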