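# Synthetic bisulfite data with known truth: a diploid genome with planted
# SNVs, per-cytosine methylation states by context, stochastic bisulfite
# conversion with a configurable failure rate, quality-dependent sequencing
# errors, and truth-perfect SAM emission from both original strands (no
# aligner involved, which isolates downstream stages from alignment
# artifacts).

.int2base <- function(x) strsplit(intToUtf8(x), "", fixed = TRUE)[[1]]

#' Generate a random reference sequence
#'
#' Uniform A/C/G/T sequence; a convenience for building test genomes.
#'
#' @param length Sequence length in bp.
#' @param chrom_name Sequence name.
#' @param gc GC fraction (default 0.42).
#' @return Named character vector of length 1 (a reference, see
#'   [load_reference()]).
#' @export
simulate_reference <- function(length, chrom_name = "chrS", gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  s <- paste(sample(names(p), length, replace = TRUE, prob = p),
             collapse = "")
  setNames(s, chrom_name)
}

#' Plant diploid SNVs into a reference
#'
#' Plants single-nucleotide variants at the given per-bp density at uniform
#' positions (reference 'N' positions are never used). Each variant is
#' heterozygous with probability `het_fraction` (placed on one random
#' haplotype) and homozygous-alternative otherwise.
#'
#' @param ref Named character vector of reference sequences.
#' @param snv_density Expected variants per bp (default 1e-3).
#' @param het_fraction Fraction of heterozygous variants (default 0.5).
#' @return List of class `bs_sim_genome`: `ref`, `haplotypes` (per chrom, a
#'   list of two sequences) and `variants` (`chrom`, `pos` 0-based, `ref`,
#'   `alt`, `zygosity`, `hap`).
#' @export
simulate_diploid <- function(ref, snv_density = 1e-3, het_fraction = 0.5) {
  haplotypes <- list()
  vars <- list()
  for (ch in names(ref)) {
    s <- ref[[ch]]
    L <- nchar(s)
    h <- utf8ToInt(s)
    usable <- which(.int2base(h) %in% c("A", "C", "G", "T"))
    n <- rbinom(1L, length(usable), snv_density)
    h1 <- h; h2 <- h
    if (n > 0L) {
      posn <- sort(sample(usable, n))
      refb <- .int2base(h[posn])
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "", USE.NAMES = FALSE)
      zyg <- ifelse(runif(n) < het_fraction, "het", "hom")
      hap <- ifelse(zyg == "het", sample(1:2, n, replace = TRUE), 0L)
      alt_int <- utf8ToInt(paste(altb, collapse = ""))
      on1 <- zyg == "hom" | hap == 1L
      on2 <- zyg == "hom" | hap == 2L
      h1[posn[on1]] <- alt_int[on1]
      h2[posn[on2]] <- alt_int[on2]
      vars[[ch]] <- data.table(chrom = ch, pos = posn - 1L, ref = refb,
                               alt = altb, zygosity = zyg,
                               hap = as.integer(hap))
    }
    haplotypes[[ch]] <- list(intToUtf8(h1), intToUtf8(h2))
  }
  variants <- if (length(vars)) rbindlist(vars) else
    data.table(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), zygosity = character(0), hap = integer(0))
  structure(list(ref = ref, haplotypes = haplotypes, variants = variants),
            class = "bs_sim_genome")
}

#' Assign methylation states to a simulated genome
#'
#' Sets the methylation level of every cytosine on both strands of both
#' haplotypes: CpG cytosines get `cpg_level`, all others `noncpg_level`
#' (contexts are taken from each haplotype's own sequence). The returned
#' truth table holds the expected level of every reference cytosine not
#' within 2 bp of a planted variant (where reference context and sample
#' context are guaranteed to agree).
#'
#' @param genome A `bs_sim_genome` from [simulate_diploid()].
#' @param cpg_level Methylation level of CpG cytosines: 1 for the fully
#'   methylated preset, 0 for fully unmethylated, or any fraction.
#' @param noncpg_level Level of CHG/CHH cytosines (default 0).
#' @return List of class `bs_sim_methylome`: `levels` (per chrom, per
#'   haplotype, `plus`/`minus` numeric vectors over positions), `truth_meth`
#'   (`chrom`, `pos`, `strand`, `context`, `level`), plus the preset levels.
#' @export
simulate_methylome <- function(genome, cpg_level = 1, noncpg_level = 0) {
  stopifnot(inherits(genome, "bs_sim_genome"))
  levels <- list()
  for (ch in names(genome$ref)) {
    levels[[ch]] <- lapply(1:2, function(k) {
      b <- utf8ToInt(genome$haplotypes[[ch]][[k]])
      L <- length(b)
      C <- utf8ToInt("C"); G <- utf8ToInt("G")
      plus <- numeric(L); minus <- numeric(L)
      isC <- b == C; isG <- b == G
      plus[isC] <- noncpg_level
      minus[isG] <- noncpg_level
      cpg_c <- which(isC[-L] & isG[-1L])         # C of a CpG on '+'
      plus[cpg_c] <- cpg_level
      minus[cpg_c + 1L] <- cpg_level             # paired G on '-'
      list(plus = plus, minus = minus)
    })
  }
  ctx <- cytosine_contexts(genome$ref)
  if (nrow(genome$variants) > 0L) {
    excl <- genome$variants[, .(pos = rep(pos, each = 5L) +
                                  rep(-2L:2L, .N)), by = chrom]
    ctx <- ctx[!excl, on = c("chrom", "pos")]
  }
  ctx[, level := ifelse(context == "CG", cpg_level, noncpg_level)]
  structure(list(levels = levels, truth_meth = ctx[],
                 cpg_level = cpg_level, noncpg_level = noncpg_level),
            class = "bs_sim_methylome")
}

# per-base PHRED qualities under the named model
.sim_quals <- function(n, qual_model) {
  if (identical(qual_model, "q30")) return(rep.int(30L, n))
  if (identical(qual_model, "mixed")) {
    # broad Illumina-like profile: mostly high-quality with a low tail
    qs <- c(2L, 10L, 15L, 20L, 25L, 30L, 35L, 40L)
    w <- c(0.04, 0.05, 0.06, 0.10, 0.15, 0.25, 0.20, 0.15)
    return(sample(qs, n, replace = TRUE, prob = w))
  }
  if (is.numeric(qual_model)) # replay: recycle a supplied quality pool
    return(as.integer(sample(qual_model, n, replace = TRUE)))
  stop("unknown quality model: ", qual_model)
}

#' Simulate bisulfite reads from a diploid genome
#'
#' Draws reads uniformly from both haplotypes and both original strands.
#' On the read's strand, every methylated cytosine stays C; every
#' unmethylated cytosine converts to T with probability `conv_rate`
#' (failures stay C). In '+'-stored orientation this reads as C->T on
#' original-top-strand reads and G->A on original-bottom-strand reads.
#' Sequencing errors are then applied per base with probability
#' `10^(-Q/10)` given the base's simulated quality.
#'
#' @param genome A `bs_sim_genome`.
#' @param methylome A `bs_sim_methylome` for the same genome.
#' @param coverage Mean fold coverage (default 20).
#' @param read_len Read length (default 75).
#' @param conv_rate Bisulfite conversion probability for unmethylated
#'   cytosines (default 0.99).
#' @param qual_model `"q30"` (all bases Q30), `"mixed"` (a broad
#'   Illumina-like quality profile), or an integer vector of PHRED scores to
#'   resample from (replay of real data).
#' @param seq_error Apply quality-driven sequencing errors (default `TRUE`).
#' @return List of class `bs_sim`: `reads` (a [bis_reads()] table with an
#'   extra `hap` column), `genome`, `methylome`, `conv_rate`, `coverage`,
#'   `read_len`.
#' @export
simulate_reads <- function(genome, methylome, coverage = 20, read_len = 75L,
                           conv_rate = 0.99, qual_model = "q30",
                           seq_error = TRUE) {
  stopifnot(inherits(genome, "bs_sim_genome"),
            inherits(methylome, "bs_sim_methylome"))
  if (coverage <= 0) stop("'coverage' must be > 0")
  read_len <- as.integer(read_len)
  C <- utf8ToInt("C"); G <- utf8ToInt("G")
  A <- utf8ToInt("A"); T_ <- utf8ToInt("T")
  all_reads <- list()
  for (ch in names(genome$ref)) {
    L <- nchar(genome$ref[[ch]])
    if (read_len > L)
      stop("read length exceeds contig ", ch, " (", L, " bp)")
    n_reads <- as.integer(round(coverage * L / read_len))
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE) - 1L
    hap <- sample(1:2, n_reads, replace = TRUE)
    bs <- sample(c("OT", "OB"), n_reads, replace = TRUE)
    idx <- rep(starts, each = read_len) + seq_len(read_len)  # 1-based
    rid <- rep(seq_len(n_reads), each = read_len)
    b <- integer(length(idx))
    lev <- numeric(length(idx))
    for (k in 1:2) {
      sel <- hap[rid] == k
      hk <- utf8ToInt(genome$haplotypes[[ch]][[k]])
      b[sel] <- hk[idx[sel]]
      lv <- methylome$levels[[ch]][[k]]
      ot <- sel & bs[rid] == "OT"
      ob <- sel & bs[rid] == "OB"
      lev[ot] <- lv$plus[idx[ot]]
      lev[ob] <- lv$minus[idx[ob]]
    }
    # bisulfite conversion of unmethylated cytosines on the read's strand
    is_cyt <- (bs[rid] == "OT" & b == C) | (bs[rid] == "OB" & b == G)
    meth <- is_cyt & runif(length(b)) < lev
    convert <- is_cyt & !meth & runif(length(b)) < conv_rate
    ot_conv <- convert & bs[rid] == "OT"
    ob_conv <- convert & !(bs[rid] == "OT")
    b[ot_conv] <- T_
    b[ob_conv] <- A
    # quality-driven sequencing errors (uniform over the other three bases)
    q <- .sim_quals(length(b), qual_model)
    if (isTRUE(seq_error)) {
      err <- runif(length(b)) < 10^(-q / 10)
      if (any(err)) {
        wi <- which(err)
        others <- matrix(c(C, G, T_, A, G, T_, A, C, T_, A, C, G),
                         nrow = 4L, byrow = TRUE,
                         dimnames = list(c("A", "C", "G", "T"), NULL))
        cur <- match(b[wi], c(A, C, G, T_))
        pick <- sample.int(3L, length(wi), replace = TRUE)
        ok <- !is.na(cur)   # leave N bases untouched
        b[wi[ok]] <- others[cbind(cur[ok], pick[ok])]
      }
    }
    seq_all <- intToUtf8(b)
    qual_all <- intToUtf8(q + 33L)
    from <- (seq_len(n_reads) - 1L) * read_len + 1L
    seqs <- substring(seq_all, from, from + read_len - 1L)
    quals <- substring(qual_all, from, from + read_len - 1L)
    rd <- bis_reads(read_id = sprintf("%s_r%06d", ch, seq_len(n_reads)),
                    chrom = ch, start = starts, bs_strand = bs,
                    seq = seqs, qual = quals)
    rd[, hap := hap]
    all_reads[[ch]] <- rd
  }
  reads <- rbindlist(all_reads)
  setorder(reads, chrom, start)
  structure(list(reads = reads, genome = genome, methylome = methylome,
                 conv_rate = conv_rate, coverage = coverage,
                 read_len = read_len),
            class = "bs_sim")
}

#' Write simulated reads as coordinate-sorted SAM
#'
#' Truth-perfect alignments: FLAG 0/16 from the alignment strand, ungapped
#' CIGAR, MAPQ 60, and a Bismark-style `XG` tag carrying the bisulfite
#' strand.
#'
#' @param reads Reads `data.table`.
#' @param ref Named character vector of reference sequences.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sim_sam <- function(reads, ref, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref), nchar(ref)))
  if (nrow(reads) == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  rd <- copy(reads)
  rd[, chrom := factor(chrom, levels = names(ref))]
  setorder(rd, chrom, start)
  rd[, chrom := as.character(chrom)]
  flag <- ifelse(rd$aln_strand == "-", 16L, 0L)
  xg <- ifelse(rd$bs_strand == "OT", "CT", "GA")
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tXG:Z:%s",
                  rd$read_id, flag, rd$chrom, rd$start + 1L, rd$mapq,
                  rd$cigar, rd$seq, rd$qual, xg)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated reads as FASTQ (as-sequenced orientation)
#'
#' @param reads Reads `data.table`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_sim_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  o <- .seq_5prime(reads$seq, reads$qual, reads$aln_strand)
  sq <- o$seq
  rev_idx <- reads$aln_strand == "-"
  # .seq_5prime reverses; FASTQ needs the reverse complement of the stored
  # sequence for reverse-aligned reads
  sq[rev_idx] <- chartr("ACGTN", "TGCAN", sq[rev_idx])
  writeLines(as.vector(rbind(paste0("@", reads$read_id), sq, "+", o$qual)),
             path)
  invisible(path)
}

#' Write the simulation truth tables
#'
#' Two tab files: `<prefix>.variants.tab` (planted variants) and
#' `<prefix>.meth.tab` (expected methylation level per reference cytosine
#' away from variants).
#'
#' @param sim A `bs_sim` from [simulate_reads()].
#' @param prefix Output path prefix.
#' @return Named character vector of paths, invisibly.
#' @export
write_sim_truth <- function(sim, prefix) {
  pv <- paste0(prefix, ".variants.tab")
  pm <- paste0(prefix, ".meth.tab")
  fwrite(sim$genome$variants, pv, sep = "\t")
  fwrite(sim$methylome$truth_meth, pm, sep = "\t")
  invisible(c(variants = pv, meth = pm))
}
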