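#' Pipeline configuration
#'
#' Collects every tunable parameter of the methylation-profiling and SNV
#' calling pipeline, with the tool's default values.
#'
#' @param minQ Minimum PHRED base quality; calls below it are ignored
#'   everywhere (pileup, seeds, conversion-failure filter). Default 20.
#' @param seedLen Length of the 5' high-quality seed used to separate clonal
#'   reads from allelic co-start reads. Default 26.
#' @param trim5 Number of bases removed from the sequencing 5' end of every
#'   read (3 for MspI sites of non-directional RRBS). Default 0.
#' @param dedup_enabled Run seed-based duplicate selection. Default `FALSE`
#'   (external duplicate-marking tools can be used upstream instead).
#' @param bisFailureEnabled Drop reads that look like bisulfite-conversion
#'   failures. Default `TRUE`.
#' @param bisFailureFrac Fraction of unconverted non-CpG cytosines at or above
#'   which a read is considered a conversion failure. Default 0.9.
#' @param minDepthMeth Minimum informative coverage to report a cytosine.
#'   Default 3.
#' @param minDepthSNV Minimum usable depth to consider a position for SNV
#'   calling. Default 1.
#' @param varFraction Minimum relative frequency for a non-reference base to
#'   be a variant candidate. Default 0.1.
#' @param maxPval Fisher-test p-value threshold for reporting an SNV.
#'   Default 0.05.
#' @param errRate Expected per-base error rate used for the Fisher-test
#'   reference row. Default 0.01.
#' @param errorInterval Half-width of the tolerated methylation-level interval
#'   in the conversion-error binomial test. Default 0.1.
#' @param fdr_enabled Apply Benjamini-Hochberg FDR to conversion-error
#'   p-values. Default `FALSE`.
#' @param fdr_alpha FDR level. Default 0.05.
#' @param rng_seed Seed for the pipeline RNG (duplicate tie-breaks).
#'
#' @return A list of class `bs_config`.
#' @export
bs_config <- function(minQ = 20L, seedLen = 26L, trim5 = 0L,
                      dedup_enabled = FALSE, bisFailureEnabled = TRUE,
                      bisFailureFrac = 0.9, minDepthMeth = 3L,
                      minDepthSNV = 1L, varFraction = 0.1, maxPval = 0.05,
                      errRate = 0.01, errorInterval = 0.1,
                      fdr_enabled = FALSE, fdr_alpha = 0.05,
                      rng_seed = 1L) {
  cfg <- list(minQ = as.integer(minQ), seedLen = as.integer(seedLen),
              trim5 = as.integer(trim5),
              dedup_enabled = isTRUE(dedup_enabled),
              bisFailureEnabled = isTRUE(bisFailureEnabled),
              bisFailureFrac = as.numeric(bisFailureFrac),
              minDepthMeth = as.integer(minDepthMeth),
              minDepthSNV = as.integer(minDepthSNV),
              varFraction = as.numeric(varFraction),
              maxPval = as.numeric(maxPval),
              errRate = as.numeric(errRate),
              errorInterval = as.numeric(errorInterval),
              fdr_enabled = isTRUE(fdr_enabled),
              fdr_alpha = as.numeric(fdr_alpha),
              rng_seed = as.integer(rng_seed))
  fracs <- c("bisFailureFrac", "varFraction", "maxPval", "errRate",
             "errorInterval", "fdr_alpha")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1], got %s", f, v))
  }
  if (cfg$minDepthSNV < 1L) stop("'minDepthSNV' must be >= 1")
  if (cfg$seedLen < 1L) stop("'seedLen' must be >= 1")
  if (cfg$minQ < 0L) stop("'minQ' must be >= 0")
  if (cfg$trim5 < 0L) stop("'trim5' must be >= 0")
  if (cfg$minDepthMeth < 0L) stop("'minDepthMeth' must be >= 0")
  structure(cfg, class = "bs_config")
}

#' @export
print.bs_config <- function(x, ...) {
  cat("bsmeth pipeline configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
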