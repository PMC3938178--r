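# Single-pass pipeline: alignments -> (dedup, trim, conversion-failure
# filter) -> quality-filtered pileup -> SNV calls + methylation map, with
# genotype-aware post-processing of the methylation output and a JSON run
# report.

#' Run the full methylation-profiling and SNV-calling pipeline
#'
#' Reads the reference and the coordinate-sorted alignments, applies the
#' enabled read-level filters (duplicate selection, 5' trimming,
#' bisulfite-conversion-failure elimination), builds the quality-filtered
#' pileup once, and derives both outputs from it: per-cytosine methylation
#' sites and SNV calls. Sites whose genotype call removes the cytosine on
#' both chromosomes are suppressed from the methylation map (no cytosine
#' exists in the sample there); heterozygous sites stay, flagged with their
#' genotype in an extra column.
#'
#' @param aln_path SAM/BAM file of aligned bisulfite reads.
#' @param fasta_path Reference FASTA.
#' @param cfg A [bs_config()] object.
#' @param out_dir Output directory (created if missing); when `NULL`,
#'   nothing is written and results are only returned.
#' @param formats Methylation output formats, subset of tab/bed/wig.
#' @param contexts Context classes to report.
#' @param sample_name Sample name for the VCF column.
#' @return List of class `bs_run`: `sites`, `calls`, `report` (a nested
#'   list of read/site/call counters), invisibly when writing.
#' @export
run_pipeline <- function(aln_path, fasta_path, cfg = bs_config(),
                         out_dir = NULL, formats = c("tab", "bed", "wig"),
                         contexts = c("CG", "CHG", "CHH"),
                         sample_name = "sample1") {
  t0 <- Sys.time()
  set.seed(cfg$rng_seed)
  ref <- load_reference(fasta_path)
  reads <- read_bs_alignments(aln_path)
  report <- list(input = list(alignments = aln_path, reference = fasta_path),
                 reads = list(total = nrow(reads),
                              unassigned_strand = attr(reads, "n_skipped")))
  if (cfg$dedup_enabled) {
    reads <- deduplicate(reads, seedLen = cfg$seedLen, minQ = cfg$minQ)
    report$reads$duplicates_removed <- attr(reads, "n_removed")
  }
  if (cfg$trim5 > 0L) {
    reads <- trim_5prime(reads, cfg$trim5)
    report$reads$trim_dropped <- attr(reads, "n_dropped")
  }
  if (cfg$bisFailureEnabled) {
    reads <- bisulfite_failure_filter(reads, ref, frac = cfg$bisFailureFrac,
                                      minQ = cfg$minQ)
    report$reads$bisulfite_failures_removed <- attr(reads, "n_removed")
  }
  report$reads$kept <- nrow(reads)
  pileup <- build_pileup(reads, ref, minQ = cfg$minQ)
  report$reads$beyond_contig <- attr(pileup, "n_skipped")
  calls <- call_snvs(pileup, cfg)
  sites <- profile_methylation(pileup, ref, minDepthMeth = cfg$minDepthMeth,
                               contexts = contexts)
  sites <- annotate_sites_with_genotype(sites, calls)
  report$sites <- as.list(table(sites$context))
  report$snv <- list(calls = nrow(calls),
                     hom = sum(calls$zygosity == "hom"),
                     het = sum(calls$zygosity == "het"))
  report$timing <- list(started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                        finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  res <- structure(list(sites = sites, calls = calls, report = report),
                   class = "bs_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_meth_outputs(sites, file.path(out_dir, "meth"), formats = formats,
                       contexts = contexts)
    write_vcf(calls, ref, file.path(out_dir, "snv.vcf"),
              sample_name = sample_name)
    jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' Reconcile methylation sites with the called genotypes
#'
#' Removes sites where a homozygous call eliminates the reference cytosine
#' (a '+' cytosine needs a C allele; a '-' cytosine, reference G on '+',
#' needs a G) and flags the remaining sites overlapping a call with the
#' called genotype in a `genotype` column ("." elsewhere).
#'
#' @param sites Sites `data.table`.
#' @param calls Calls `data.table`.
#' @return The annotated sites table (a copy).
#' @export
annotate_sites_with_genotype <- function(sites, calls) {
  out <- copy(sites)
  out[, genotype := "."]
  if (nrow(out) == 0L || nrow(calls) == 0L) return(out[])
  cl <- calls[, .(chrom, pos, a1, a2,
                  gt = paste(a1, a2, sep = "/"))]
  out[cl, on = c("chrom", "pos"), `:=`(genotype = i.gt,
                                       .a1 = i.a1, .a2 = i.a2)]
  needed <- ifelse(out$strand == "+", "C", "G")
  lost <- !is.na(out$.a1) & out$.a1 != needed & out$.a2 != needed
  out <- out[!lost]
  out[, c(".a1", ".a2") := NULL]
  out[]
}

#' @export
print.bs_run <- function(x, ...) {
  r <- x$report
  cat("bsmeth run:\n")
  cat(sprintf("  reads: %d total, %d kept\n", r$reads$total, r$reads$kept))
  cat(sprintf("  methylation sites: %d (%s)\n", nrow(x$sites),
              paste(sprintf("%s %d", names(r$sites), unlist(r$sites)),
                    collapse = ", ")))
  cat(sprintf("  SNV calls: %d (%d hom, %d het)\n", r$snv$calls, r$snv$hom,
              r$snv$het))
  invisible(x)
}
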