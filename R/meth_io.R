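# Writers and readers for the per-cytosine methylation outputs. Internal
# coordinates are 0-based half-open; conversion to 1-based happens only here.

#' Write methylation sites as native tab output
#'
#' One line per cytosine: chrom, 1-based position, strand, context,
#' methylcytosine count, coverage, mean PHRED quality (2 decimals) and
#' methylation level (2 decimals). When the sites table carries a `genotype`
#' column (heterozygous SNV flagging from the pipeline) it is appended as a
#' ninth column.
#'
#' @param sites Sites `data.table` from [profile_methylation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meth_tab <- function(sites, path) {
  has_gt <- "genotype" %in% names(sites)
  hdr <- "#chrom\tpos\tstrand\tcontext\tmC\tcov\tmeanQ\tlevel"
  if (has_gt) hdr <- paste0(hdr, "\tgenotype")
  if (nrow(sites) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  body <- sprintf("%s\t%d\t%s\t%s\t%d\t%d\t%.2f\t%.2f",
                  sites$chrom, sites$pos + 1L, sites$strand, sites$context,
                  sites$mc_count, sites$cov, sites$mean_qual, sites$level)
  if (has_gt) body <- paste0(body, "\t", sites$genotype)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read native tab methylation output
#'
#' Inverse of [write_meth_tab()]; the level is recomputed from the counts so
#' the round trip is exact, and positions are converted back to 0-based.
#'
#' @param path Path to a native tab file.
#' @return Sites `data.table`.
#' @export
read_meth_tab <- function(path) {
  lines <- readLines(path)
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  dt <- if (length(lines) > 1L)
    fread(text = lines[-1L], header = FALSE, sep = "\t",
          colClasses = list(character = c(1, 3, 4))) else data.table()
  if (nrow(dt) == 0L) {
    out <- data.table(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      mc_count = integer(0), cov = integer(0),
                      mean_qual = numeric(0), level = numeric(0))
    if ("genotype" %in% cols) out[, genotype := character(0)]
    return(out)
  }
  setnames(dt, cols)
  setnames(dt, c("pos", "mC", "cov", "meanQ"),
           c("pos", "mc_count", "cov", "mean_qual"), skip_absent = TRUE)
  setnames(dt, "mC", "mc_count", skip_absent = TRUE)
  setnames(dt, "meanQ", "mean_qual", skip_absent = TRUE)
  dt[, pos := as.integer(pos) - 1L]
  dt[, mc_count := as.integer(mc_count)]
  dt[, cov := as.integer(cov)]
  dt[, level := mc_count / cov]
  dt[]
}

#' Write methylation sites as BED6
#'
#' Single-base 0-based half-open intervals; name = context, score =
#' `round(level * 1000)`, strand column.
#'
#' @inheritParams write_meth_tab
#' @param track_name Name used in the track line.
#' @return `path`, invisibly.
#' @export
write_meth_bed <- function(sites, path, track_name = "methylation") {
  hdr <- sprintf("track name=\"%s\" description=\"per-cytosine methylation level (score = level x 1000)\"",
                 track_name)
  if (nrow(sites) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  body <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                  sites$chrom, sites$pos, sites$pos + 1L, sites$context,
                  as.integer(round(sites$level * 1000)), sites$strand)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED6 methylation track written by [write_meth_bed()]
#'
#' @param path Path to the BED file.
#' @return `data.table` with `chrom`, `pos`, `context`, `score`, `strand`.
#' @export
read_meth_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.table(chrom = character(0), pos = integer(0),
                      context = character(0), score = integer(0),
                      strand = character(0)))
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "context", "score",
                            "strand"))
  dt[, .(chrom = as.character(chrom), pos = as.integer(start),
         context = as.character(context), score = as.integer(score),
         strand = as.character(strand))]
}

#' Write methylation levels as a variableStep WIG track
#'
#' One `variableStep` block per chromosome with 1-based positions and
#' methylation levels (4 decimals). Cytosines of both strands appear in one
#' track (their positions never collide).
#'
#' @inheritParams write_meth_tab
#' @param track_name Name used in the track line.
#' @return `path`, invisibly.
#' @export
write_meth_wig <- function(sites, path, track_name = "methylation") {
  out <- sprintf("track type=wiggle_0 name=\"%s\"", track_name)
  if (nrow(sites) > 0L) {
    for (ch in unique(sites$chrom)) {
      sub <- sites[chrom == ch]
      out <- c(out, sprintf("variableStep chrom=%s", ch),
               sprintf("%d\t%.4f", sub$pos + 1L, sub$level))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a variableStep WIG track written by [write_meth_wig()]
#'
#' @param path Path to the WIG file.
#' @return `data.table` with `chrom`, `pos` (0-based), `level`.
#' @export
read_meth_wig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track")]
  out <- data.table(chrom = character(0), pos = integer(0),
                    level = numeric(0))
  cur <- NA_character_
  rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "variableStep")) {
      cur <- sub("^variableStep chrom=", "", ln)
    } else if (nzchar(ln)) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <-
        data.table(chrom = cur, pos = as.integer(parts[1]) - 1L,
                   level = as.numeric(parts[2]))
    }
  }
  if (length(rows)) out <- rbindlist(rows)
  out
}

#' Write methylation outputs in the selected formats
#'
#' Writes one file per requested context class and format under `prefix`
#' (`<prefix>.<context>.<ext>`).
#'
#' @param sites Sites `data.table`.
#' @param prefix Output path prefix.
#' @param formats Subset of `c("tab", "bed", "wig")`.
#' @param contexts Context classes to write.
#' @return Named character vector of written paths, invisibly.
#' @export
write_meth_outputs <- function(sites, prefix, formats = c("tab", "bed", "wig"),
                               contexts = c("CG", "CHG", "CHH")) {
  formats <- match.arg(formats, several.ok = TRUE)
  paths <- character(0)
  for (ctx in contexts) {
    sub <- sites[context == ctx]
    for (fmt in formats) {
      p <- sprintf("%s.%s.%s", prefix, ctx, fmt)
      switch(fmt,
             tab = write_meth_tab(sub, p),
             bed = write_meth_bed(sub, p, track_name = paste0("meth_", ctx)),
             wig = write_meth_wig(sub, p, track_name = paste0("meth_", ctx)))
      paths[paste(ctx, fmt, sep = ".")] <- p
    }
  }
  invisible(paths)
}
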