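mk_col <- function(bs_strand, base, count, ref_base = "C", pos = 10L) {
  data.table(chrom = "c1", pos = pos, ref_base = ref_base,
             bs_strand = bs_strand, base = base, count = as.integer(count),
             qual_sum = as.integer(count) * 30L)
}

test_that("usable counts drop conversion-confounded identities", {
  # heterozygous A/G pattern on the '+' strand at a reference G:
  # 5 G + 6 A from OT reads are all usable
  col <- mk_col(c("OT", "OT"), c("G", "A"), c(5, 6), ref_base = "G")
  expect_equal(usable_allele_counts(col),
               c(A = 6L, C = 0L, G = 5L, T = 0L))
  # T calls on OT reads may be converted cytosines: discarded
  col2 <- mk_col(c("OT", "OT"), c("C", "T"), c(7, 12))
  expect_equal(usable_allele_counts(col2),
               c(A = 0L, C = 7L, G = 0L, T = 0L))
  # A calls on OB reads may be converted guanines: discarded
  col3 <- mk_col(c("OB", "OB"), c("G", "A"), c(4, 9), ref_base = "G")
  expect_equal(usable_allele_counts(col3),
               c(A = 0L, C = 0L, G = 4L, T = 0L))
  # counts sum across strands per base
  col4 <- rbind(mk_col("OT", "C", 3), mk_col("OB", "C", 2))
  expect_equal(usable_allele_counts(col4)[["C"]], 5L)
})

test_that("homozygous variant at a cytosine is visible through the bottom strand", {
  # sample genotype T/T at a reference C: OT reads show T (confounded,
  # discarded) while OB reads show T (a '-'-strand A/G mismatch in molecule
  # space), which is usable evidence
  col <- rbind(mk_col("OT", "T", 12), mk_col("OB", "T", 11))
  cnt <- usable_allele_counts(col)
  expect_equal(cnt, c(A = 0L, C = 0L, G = 0L, T = 11L))
  cand <- detect_candidates(cnt, "C", varFraction = 0.1)
  expect_equal(cand, "T")
  pv <- variant_pvalue(cnt[["C"]], cnt[["T"]], sum(cnt))
  gt <- call_genotype(cnt, "C", cand, pv)
  expect_equal(gt$a1, "T")
  expect_equal(gt$a2, "T")
  expect_equal(gt$zygosity, "hom")
})

test_that("candidate detection applies varFraction and minDepthSNV", {
  cnt <- c(A = 6L, C = 0L, G = 5L, T = 0L)
  expect_equal(detect_candidates(cnt, "G", varFraction = 0.1), "A")
  expect_equal(detect_candidates(c(A = 0L, C = 100L, G = 0L, T = 5L), "C",
                                 varFraction = 0.1), character(0))
  expect_equal(detect_candidates(c(A = 0L, C = 0L, G = 0L, T = 0L), "C",
                                 varFraction = 0.1, minDepthSNV = 1),
               character(0))
  expect_equal(detect_candidates(cnt, "G", varFraction = 0.1,
                                 minDepthSNV = 12), character(0))
})

test_that("variant p-value equals the enumeration oracle", {
  # the heterozygous 5/6 example: frozen from the enumeration oracle
  expect_equal(variant_pvalue(5, 6, 11, 0.01), 6.1919504644e-3,
               tolerance = 1e-10)
  expect_equal(variant_pvalue(5, 6, 11, 0.01),
               enum_fisher_tail(5, 6, round(11 * 0.99), round(11 * 0.01)),
               tolerance = 1e-12)
  # no variant evidence: p = 1; degenerate table: p = 1
  expect_equal(variant_pvalue(10, 0, 10, 0.01), 1)
  expect_equal(variant_pvalue(0, 0, 0, 0.01), 1)
  # more variant reads at fixed reference count never increase p
  p1 <- variant_pvalue(5, 3, 8, 0.01)
  p2 <- variant_pvalue(5, 6, 11, 0.01)
  expect_lte(p2, p1)
  # random spot checks against enumeration and fisher.test
  set.seed(3)
  for (i in 1:25) {
    nr <- sample(0:30, 1); nv <- sample(0:15, 1); if (nr + nv == 0) nv <- 1
    N <- nr + nv
    e <- sample(c(0.001, 0.01, 0.05), 1)
    got <- variant_pvalue(nr, nv, N, e)
    expect_equal(got, enum_fisher_tail(nr, nv, round(N * (1 - e)),
                                       round(N * e)), tolerance = 1e-12)
    ft <- fisher.test(rbind(c(nv, nr), c(round(N * e), round(N * (1 - e)))),
                      alternative = "greater")
    expect_equal(got, ft$p.value, tolerance = 1e-9)
  }
})

test_that("genotype assignment follows counts, varFraction and maxPval", {
  cnt <- c(A = 6L, C = 0L, G = 5L, T = 0L)
  pv <- variant_pvalue(5, 6, 11)
  gt <- call_genotype(cnt, "G", "A", pv)
  expect_equal(sort(c(gt$a1, gt$a2)), c("A", "G"))
  expect_equal(gt$zygosity, "het")
  # above maxPval: no call
  expect_null(call_genotype(cnt, "G", "A", 0.2, maxPval = 0.05))
  # runner-up below varFraction collapses to homozygous top base
  cnt2 <- c(A = 19L, C = 0L, G = 1L, T = 0L)
  gt2 <- call_genotype(cnt2, "G", "A", 1e-6, varFraction = 0.1)
  expect_equal(c(gt2$a1, gt2$a2), c("A", "A"))
  # count ties break deterministically in base order A < C < G < T
  cnt3 <- c(A = 5L, C = 5L, G = 0L, T = 5L)
  gt3 <- call_genotype(cnt3, "G", c("A", "C", "T"), 1e-6,
                       varFraction = 0.1)
  expect_equal(c(gt3$a1, gt3$a2), c("A", "C"))
})

test_that("call_snvs agrees with the per-column operations", {
  fx <- small_sim(len = 20000L, seed = 81L, snv_density = 2e-3)
  cfg <- bs_config()
  pu <- build_pileup(fx$sim$reads, fx$ref, minQ = cfg$minQ)
  calls <- call_snvs(pu, cfg)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$depth_usable >= cfg$minDepthSNV))
  expect_true(all(calls$p_value < cfg$maxPval))
  for (i in sample(nrow(calls), min(15, nrow(calls)))) {
    col <- pileup_column(pu, calls$chrom[i], calls$pos[i])
    cnt <- usable_allele_counts(col)
    cand <- detect_candidates(cnt, calls$ref_base[i], cfg$varFraction,
                              cfg$minDepthSNV)
    expect_true(length(cand) > 0)
    pv <- variant_pvalue(cnt[[calls$ref_base[i]]], sum(cnt[cand]), sum(cnt),
                         cfg$errRate)
    expect_equal(pv, calls$p_value[i], tolerance = 1e-12)
    gt <- call_genotype(cnt, calls$ref_base[i], cand, pv, cfg$varFraction,
                        cfg$maxPval)
    expect_equal(gt$a1, calls$a1[i])
    expect_equal(gt$a2, calls$a2[i])
  }
  # every truth position without a call must genuinely lack support
  expect_true(all(calls$n_A + calls$n_C + calls$n_G + calls$n_T ==
                  calls$depth_usable))
})

test_that("no calls are emitted below the minimum usable depth", {
  # single OT read with one A call at a reference G
  ref <- c(c1 = "AAGAA")
  rd <- bis_reads("r", "c1", 2L, "OT", "A", qstr(30))
  pu <- build_pileup(rd, ref, minQ = 20)
  expect_equal(nrow(call_snvs(pu, bs_config(minDepthSNV = 2))), 0L)
  # with minDepthSNV = 1 a perfect single-read variant is callable only if
  # its Fisher p-value clears maxPval; at depth 1 it cannot
  calls1 <- call_snvs(pu, bs_config(minDepthSNV = 1))
  expect_equal(nrow(calls1), 0L)
})

test_that("VCF output is well-formed and re-parses", {
  ref <- c(c1 = paste(rep("ACGTG", 20), collapse = ""))
  calls <- data.table(chrom = "c1", pos = c(41L, 61L), ref_base = "G",
                      a1 = c("G", "A"), a2 = c("A", "A"),
                      zygosity = c("het", "hom"),
                      depth_usable = c(11L, 9L),
                      n_A = c(6L, 9L), n_C = 0L, n_G = c(5L, 0L), n_T = 0L,
                      p_value = c(6.19e-3, 1e-8))
  p <- tempfile(fileext = ".vcf")
  write_vcf(calls, ref, p)
  lines <- readLines(p)
  body <- lines[!startsWith(lines, "#")]
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_equal(f1[1:5], c("c1", "42", ".", "G", "A"))
  expect_equal(f1[8], "DP=11")
  expect_equal(f1[10], "0/1:5,6")
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(strsplit(f2[10], ":")[[1]][1], "1/1")
  # independent parser validation
  vcf <- VariantAnnotation::readVcf(p)
  expect_equal(length(vcf), 2L)
  expect_equal(as.integer(BiocGenerics::start(vcf)), c(42L, 62L))
  expect_equal(as.character(VariantAnnotation::ref(vcf)), c("G", "G"))
  gt <- VariantAnnotation::geno(vcf)$GT
  expect_equal(as.vector(gt), c("0/1", "1/1"))
  # empty call set: header-only file that still validates
  p0 <- tempfile(fileext = ".vcf")
  write_vcf(calls[0], ref, p0)
  expect_equal(length(VariantAnnotation::readVcf(p0)), 0L)
})
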