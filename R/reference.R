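#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA file and returns the sequences as an uppercase named
#' character vector, keyed by the first whitespace-delimited token of each
#' header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  dss <- Biostrings::readDNAStringSet(path)
  if (length(dss) == 0L) stop("reference FASTA is empty: ", path)
  nms <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(nms))
    stop("duplicate sequence name(s) in reference: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  seqs <- toupper(as.character(dss))
  names(seqs) <- nms
  seqs
}

#' Write a reference genome to FASTA
#'
#' @param ref Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, width = 70L) {
  dss <- Biostrings::DNAStringSet(ref)
  Biostrings::writeXStringSet(dss, path, width = width)
  invisible(path)
}

# split sequences into per-chrom character vectors (cached-free helper)
.ref_chars <- function(ref) lapply(ref, function(s) strsplit(s, "", fixed = TRUE)[[1]])
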