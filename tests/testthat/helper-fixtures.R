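library(data.table)

# PHRED integer vector -> PHRED+33 string
qstr <- function(q) intToUtf8(q + 33L)

# constant-quality string
qconst <- function(q, n) qstr(rep.int(q, n))

ref_tmpfile <- function(ref) {
  path <- tempfile(fileext = ".fa")
  write_reference(ref, path)
  path
}

# direct per-read walk: the independent oracle for pileup projection of a
# single ungapped read (quality filter + N exclusion applied)
walk_read <- function(read, minQ) {
  b <- strsplit(read$seq, "", fixed = TRUE)[[1]]
  q <- utf8ToInt(read$qual) - 33L
  keep <- q >= minQ & b != "N"
  data.table(chrom = read$chrom, pos = read$start + which(keep) - 1L,
             bs_strand = read$bs_strand, base = b[keep], qual = q[keep])
}

# independent hypergeometric tail by explicit enumeration of all 2x2 tables
# with the observed margins (log-factorial arithmetic, no phyper)
enum_fisher_tail <- function(n_ref, n_var, E_ref, E_var) {
  k <- n_ref + n_var             # row-1 margin
  m <- n_var + E_var             # variant column margin
  tot <- n_ref + n_var + E_ref + E_var
  xs <- max(0L, k - (tot - m)):min(k, m)
  lp <- lgamma(m + 1) - lgamma(xs + 1) - lgamma(m - xs + 1) +
    lgamma(tot - m + 1) - lgamma(k - xs + 1) - lgamma(tot - m - k + xs + 1) -
    (lgamma(tot + 1) - lgamma(k + 1) - lgamma(tot - k + 1))
  sum(exp(lp)[xs >= n_var])
}

# naive term-by-term binomial summation of the conversion-error p-value
naive_meth_pvalue <- function(mc, fmc, p) {
  k <- 0:fmc
  1 - sum(choose(mc, k) * p^k * (1 - p)^(mc - k))
}

# small simulated dataset for integration-style tests
small_sim <- function(len = 30000L, seed = 101L, snv_density = 1e-3,
                      cpg_level = 1, coverage = 20, conv_rate = 0.99,
                      qual_model = "q30", seq_error = TRUE) {
  set.seed(seed)
  ref <- simulate_reference(len)
  genome <- simulate_diploid(ref, snv_density = snv_density)
  methylome <- simulate_methylome(genome, cpg_level = cpg_level)
  sim <- simulate_reads(genome, methylome, coverage = coverage,
                        conv_rate = conv_rate, qual_model = qual_model,
                        seq_error = seq_error)
  list(ref = ref, genome = genome, methylome = methylome, sim = sim)
}
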