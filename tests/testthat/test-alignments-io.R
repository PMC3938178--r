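test_that("load_reference reads, case-folds and validates FASTA", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "ACGT", ">c2", "acgt"), p)
  ref <- load_reference(p)
  expect_identical(ref, c(c1 = "ACGT", c2 = "ACGT"))

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), p)
  expect_error(load_reference(p), "duplicate")
  expect_error(load_reference(tempfile()), "not found")
})

test_that("bisulfite strand assignment: tag precedence and FLAG fallback", {
  expect_identical(assign_bisulfite_strand(c("CT", "GA"), c(0L, 16L)),
                   c("OT", "OB"))
  expect_identical(assign_bisulfite_strand(c(NA, NA), c(0L, 16L)),
                   c("OT", "OB"))
  # contradictory tag vs FLAG: warn, tag wins
  expect_warning(res <- assign_bisulfite_strand("CT", 16L), "contradict")
  expect_identical(res, "OT")
  # unparseable tag: warn, NA (read to be skipped)
  expect_warning(res <- assign_bisulfite_strand("XX", 0L), "unparseable")
  expect_true(is.na(res))
})

test_that("5' trimming is orientation-aware", {
  rd <- bis_reads(read_id = c("f", "r"), chrom = "c1",
                  start = c(100L, 100L), bs_strand = c("OT", "OB"),
                  seq = c(strrep("A", 50), strrep("G", 50)),
                  qual = c(qconst(30, 50), qconst(30, 50)))
  tr <- trim_5prime(rd, 3L)
  expect_equal(tr$start, c(103L, 100L))
  expect_equal(nchar(tr$seq), c(47L, 47L))
  expect_equal(nchar(tr$qual), c(47L, 47L))
  expect_equal(tr$cigar, c("47M", "47M"))
  # n = 0 is the identity
  tr0 <- trim_5prime(rd, 0L)
  expect_equal(tr0$seq, rd$seq)
  expect_equal(tr0$start, rd$start)
  # reads shorter than n are dropped and counted
  short <- bis_reads("s", "c1", 0L, "OT", "AC", qconst(30, 2))
  trs <- trim_5prime(short, 2L)
  expect_equal(nrow(trs), 0L)
  expect_equal(attr(trs, "n_dropped"), 1L)
})

test_that("trimming clips the sequencing 5' end, not the left end, of reverse reads", {
  rd <- bis_reads("r", "c1", 10L, "OB", "ACGTT", qstr(c(10, 20, 30, 40, 41)))
  tr <- trim_5prime(rd, 2L)
  # 5' end of a reverse-aligned read is its right end
  expect_equal(tr$seq, "ACG")
  expect_equal(tr$qual, qstr(c(10, 20, 30)))
  expect_equal(tr$start, 10L)
})

test_that("build_pileup projects bases with quality and N filtering", {
  ref <- c(c1 = "AACGTACGTA")
  # one OT read with a single C call (q30) over the reference C at pos 2
  rd <- bis_reads("r1", "c1", 2L, "OT", "C", qstr(30))
  pu <- build_pileup(rd, ref, minQ = 20)
  expect_equal(nrow(pu), 1L)
  expect_equal(pu$pos, 2L)
  expect_equal(pu$ref_base, "C")
  expect_equal(pu$count, 1L)
  expect_equal(pu$qual_sum, 30L)
  # a q10 base is excluded entirely under minQ 20
  rd2 <- bis_reads("r2", "c1", 2L, "OT", "C", qstr(10))
  expect_equal(nrow(build_pileup(rd2, ref, minQ = 20)), 0L)
  # two reads contribute separate base rows at one position
  rd3 <- bis_reads(c("a", "b"), "c1", 2L, "OT", c("C", "T"),
                   c(qstr(30), qstr(30)))
  pu3 <- build_pileup(rd3, ref, minQ = 20)
  expect_equal(sort(pu3$base), c("C", "T"))
  expect_equal(pu3$count, c(1L, 1L))
  # N calls never counted
  rdN <- bis_reads("n", "c1", 2L, "OT", "N", qstr(30))
  expect_equal(nrow(build_pileup(rdN, ref, minQ = 20)), 0L)
})

test_that("pileup is CIGAR-aware: insertions skipped, deletions advance", {
  ref <- c(c1 = "AACGTACGTA")
  # 2M 2I 2M: inserted bases contribute nothing, flanks map to 0-3
  rd <- bis_reads("i", "c1", 0L, "OT", "AATTCG", qconst(30, 6),
                  cigar = "2M2I2M")
  pu <- build_pileup(rd, ref, minQ = 20)
  expect_equal(pu$pos, 0:3)
  expect_equal(pu$base, c("A", "A", "C", "G"))
  # 2M 2D 2M: deleted reference positions get no contribution
  rd2 <- bis_reads("d", "c1", 0L, "OT", "AATA", qconst(30, 4),
                   cigar = "2M2D2M")
  pu2 <- build_pileup(rd2, ref, minQ = 20)
  expect_equal(pu2$pos, c(0L, 1L, 4L, 5L))
})

test_that("reads past the contig end are skipped and counted", {
  ref <- c(c1 = "ACGT")
  rd <- bis_reads(c("in", "out"), "c1", c(0L, 2L), "OT",
                  c("ACGT", "GTAA"), c(qconst(30, 4), qconst(30, 4)))
  pu <- build_pileup(rd, ref, minQ = 20)
  expect_equal(attr(pu, "n_skipped"), 1L)
  expect_equal(max(pu$pos), 3L)
  expect_equal(sum(pu$count), 4L)
})

test_that("single-read pileup equals the direct per-read walk", {
  set.seed(11)
  ref <- c(cX = paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                      collapse = ""))
  for (i in 1:20) {
    len <- sample(20:60, 1)
    rd <- bis_reads(
      paste0("r", i), "cX", sample(0:(500 - len), 1),
      sample(c("OT", "OB"), 1),
      paste(sample(c("A", "C", "G", "T", "N"), len, TRUE,
                   prob = c(.24, .24, .24, .24, .04)), collapse = ""),
      qstr(sample(2:40, len, TRUE)))
    pu <- build_pileup(rd, ref, minQ = 20)
    oracle <- walk_read(as.list(rd[1]), minQ = 20)
    expect_equal(pu$pos, oracle$pos)
    expect_equal(pu$base, oracle$base)
    expect_equal(pu$qual_sum, oracle$qual)
    expect_true(all(pu$count == 1L))
    expect_true(all(pu$qual_sum >= 20 * pu$count))
  }
})

test_that("trim-then-pileup equals pileup of pre-trimmed reads", {
  fx <- small_sim(len = 5000L, seed = 21L)
  trimmed <- trim_5prime(fx$sim$reads, 3L)
  pu1 <- build_pileup(trimmed, fx$ref, minQ = 20)
  # manually pre-trimmed equivalents
  rd <- data.table::copy(fx$sim$reads)
  fwd <- rd$aln_strand == "+"
  n <- nchar(rd$seq)
  pre <- bis_reads(rd$read_id, rd$chrom,
                   ifelse(fwd, rd$start + 3L, rd$start),
                   rd$bs_strand,
                   ifelse(fwd, substring(rd$seq, 4L),
                          substring(rd$seq, 1L, n - 3L)),
                   ifelse(fwd, substring(rd$qual, 4L),
                          substring(rd$qual, 1L, n - 3L)),
                   aln_strand = rd$aln_strand)
  pu2 <- build_pileup(pre, fx$ref, minQ = 20)
  expect_equal(pu1, pu2, ignore_attr = TRUE)
})

test_that("column counts never exceed overlapping reads, with equality when all pass", {
  fx <- small_sim(len = 3000L, seed = 31L, seq_error = FALSE)
  pu <- build_pileup(fx$sim$reads, fx$ref, minQ = 20)
  percol <- pu[, .(n = sum(count)), by = .(chrom, pos)]
  # overlap count from read intervals (all Q30, no N -> equality)
  st <- fx$sim$reads$start
  en <- st + nchar(fx$sim$reads$seq) - 1L
  ov <- data.table(pos = unlist(Map(seq, st, en)))[, .N, by = pos]
  m <- merge(percol, ov, by = "pos")
  expect_equal(m$n, m$N)
})

test_that("SAM round trip preserves reads and skips non-primary records", {
  fx <- small_sim(len = 2000L, seed = 41L)
  sam <- tempfile(fileext = ".sam")
  write_sim_sam(fx$sim$reads, fx$ref, sam)
  back <- read_bs_alignments(sam)
  orig <- data.table::copy(fx$sim$reads)[, hap := NULL]
  data.table::setorder(orig, chrom, start, read_id)
  data.table::setorder(back, chrom, start, read_id)
  expect_equal(back$seq, orig$seq)
  expect_equal(back$start, orig$start)
  expect_equal(back$bs_strand, orig$bs_strand)
  expect_equal(back$qual, orig$qual)
  # append an unmapped and a secondary record: both skipped
  lines <- readLines(sam)
  extra <- c("u\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII",
             sprintf("s\t272\t%s\t1\t60\t4M\t*\t0\t0\tACGT\tIIII",
                     names(fx$ref)[1]))
  writeLines(c(lines, extra), sam)
  back2 <- read_bs_alignments(sam)
  expect_equal(nrow(back2), nrow(orig))
})
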