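# Minimal single-sample VCF v4.2 writer for the SNV calls.

#' Write SNV calls to VCF
#'
#' Emits a VCF v4.2 file with one record per call: 1-based POS, REF from the
#' reference, ALT = the non-reference genotype alleles, QUAL =
#' `-10 log10(p)` capped at 255, `DP` (usable depth) in INFO and `GT:AD` for
#' the sample (allele depths in REF,ALT order).
#'
#' @param calls Calls `data.table` from [call_snvs()], coordinate-sorted.
#' @param ref Named character vector of reference sequences (for contig
#'   header lines).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref, path, sample_name = "sample1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsmeth",
    sprintf("##contig=<ID=%s,length=%d>", names(ref), nchar(ref)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Usable read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths in REF,ALT order\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t"))
  if (nrow(calls) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  if (is.unsorted(order(match(calls$chrom, names(ref)), calls$pos)))
    stop("calls must be coordinate-sorted")
  n <- nrow(calls)
  cntm <- as.matrix(calls[, .(n_A, n_C, n_G, n_T)])
  colnames(cntm) <- c("A", "C", "G", "T")
  lines <- character(n)
  for (i in seq_len(n)) {
    rb <- calls$ref_base[i]
    alts <- setdiff(unique(c(calls$a1[i], calls$a2[i])), rb)
    gt_alleles <- c(calls$a1[i], calls$a2[i])
    idx <- match(gt_alleles, c(rb, alts)) - 1L
    gt <- paste(sort(idx), collapse = "/")
    ad <- paste(cntm[i, c(rb, alts)], collapse = ",")
    qual <- if (calls$p_value[i] <= 0) 255 else
      min(255, -10 * log10(calls$p_value[i]))
    lines[i] <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\tDP=%d\tGT:AD\t%s:%s",
                        calls$chrom[i], calls$pos[i] + 1L, rb,
                        paste(alts, collapse = ","), qual,
                        calls$depth_usable[i], gt, ad)
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
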