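---
title: "Methylation profiling and SNV calling from bisulfite reads: methods and design"
author: "bsmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation profiling and SNV calling from bisulfite reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmeth)
library(data.table)
```

## The problem

Bisulfite treatment converts unmethylated cytosines to uracil (read as
thymine after PCR) while 5-methylcytosine is protected. After aligning the
treated reads to a reference, the methylation level of every cytosine can in
principle be read off as C/(C+T) among the calls covering it. In practice
four error sources corrupt this read-out, and the same read-out is entangled
with genetic variation:

* **sequencing errors** masquerade as spurious methylation or variation;
* **bisulfite conversion failures** leave unmethylated cytosines as C calls,
  inflating methylation;
* **clonal (PCR-duplicated) reads** give single molecules multiple votes;
* **single-nucleotide variants (SNVs)**: a C→T variant is indistinguishable,
  on the top strand, from a fully converted cytosine. A homozygous C→T site
  has no cytosine at all in the sample, so any methylation value reported
  there is meaningless.

`bsmeth` profiles per-cytosine methylation (CG, CHG, CHH contexts, both
strands) and calls SNVs from the same pileup in one pass, applying all four
error controls, and provides a binomial test that asks whether an observed
methylation level could be an artifact of conversion failure.

## Read-level controls

**Base quality (`minQ`, default 20).** Every base call with PHRED quality
below `minQ` is ignored everywhere: pileup counts, duplicate seeds,
conversion-failure evidence, SNV frequencies. At Q20 the contribution of
miscalls to either output is bounded by 1%.

**Duplicate selection (`dedup_enabled`, default off).** Reads are grouped by
(chromosome, start, bisulfite strand). Grouping by coordinates alone would
also collapse allelic co-start reads — at a heterozygous locus two reads
starting at the same position may carry different alleles and are not
clonal. Groups are therefore subdivided by the *high-quality seed*: the
bases among the first `seedLen` (default 26) positions from the sequencing
5' end with quality ≥ `minQ`. Within a seed subgroup one read is kept: most
high-quality bases, then longest, then a uniformly random choice from the
pipeline RNG (reads are pre-sorted by identifier so the choice depends only
on the seed, not input order). The stage is off by default so that external
coordinate-based duplicate tools remain usable upstream.

**5' trimming (`trim5`, default 0).** Removes bases from the sequencing 5'
end (3 bp for the MspI fill-in positions of non-directional RRBS). For
reverse-aligned reads the sequencing 5' end is the rightmost aligned base,
so the right end is clipped and the leftmost coordinate is unchanged.
Trimming is implemented for ungapped alignments; gapped reads — for which
the stage is not meaningful in the RRBS use case — are passed through
untouched and counted.

**Conversion-failure filter (`bisFailureEnabled`, default on;
`bisFailureFrac`, default 0.9).** A read whose non-CpG-context cytosines are
at least 90% unconverted most likely escaped bisulfite conversion
altogether. Only quality-passing calls count as evidence, consistent with
`minQ` elsewhere; reads with no evidence (`n = 0`) are kept. No minimum
evidence count beyond `n > 0` is imposed — the 90% threshold is already
conservative, and a configurable minimum would be the natural extension.
The filter assumes non-CpG methylation is rare; for plants or embryonic
stem cells it should be disabled, otherwise genuinely methylated non-CpG
reads are purged and the analysis is biased.

## Methylation profiling

All internal coordinates are 0-based, half-open; writers convert to 1-based.
Bases are kept in '+'-strand orientation exactly as SAM stores them, for
both strands; a cytosine on the '−' strand is a reference G in this
orientation, and its reads come from the original-bottom (OB) bisulfite
strand.

At a '+' cytosine, only original-top (OT) reads are informative: C calls are
methylated, T calls converted. At a '−' cytosine, only OB reads: G calls
methylated, A calls converted. Any other base call is evidence of sequence
variation and is excluded from the coverage — the level is always
mC/(mC + converted). Sites with informative coverage below `minDepthMeth`
(default 3, a conventional floor for stable level estimates) are not
reported. The mean PHRED score is averaged over all counted calls, not only
the methylated ones (the alternative is not observably different in
practice and the pooled mean describes the evidence actually used).

Context (CG/CHG/CHH, H = A/C/T) is assigned from the reference, reading
5'→3' on the cytosine's strand; cytosines whose two downstream bases run
off the contig get no context and are not reported. Context is *not*
corrected by the inferred genotype: genotype-aware context reassignment has
no agreed procedure and is out of scope. The two cytosines of a CpG are
reported as separate records.

**Interaction with SNV calls.** After genotyping, a site whose call removes
the cytosine from both chromosomes (e.g. homozygous T/T at a reference C)
is suppressed — no cytosine exists in the sample, so no level is reported.
Heterozygous sites stay, flagged with the called genotype in an extra
column, so downstream analyses can treat allele-biased levels separately.

## SNV calling

Conversion destroys information asymmetrically: on OT reads a T call may be
a converted C, on OB reads ('+'-oriented) an A call may be a converted G.
Those calls are discarded; all other identities on either strand are usable,
and counts are summed per base across strands at each position. A
consequence worth spelling out: a homozygous C→T variant is invisible on
the top strand (all T, all discarded) but fully visible through the bottom
strand, where the T allele appears as usable T calls at the same column —
the classic strand-resolution argument for bisulfite variant calling. The
more conservative reading that only G/A (OT) and C/T (OB) calls are usable
would also discard genuine C evidence on OT reads, which can never be a
conversion artifact; we keep it.

The caller then follows the VarScan recipe:

1. positions with usable depth < `minDepthSNV` (default 1) are skipped;
2. every non-reference base with relative frequency ≥ `varFraction`
   (default 0.1) is a candidate — one candidate suffices, since a
   heterozygous reference/alternative site has exactly two alleles;
3. the observed (reference, variant) split is tested with a one-sided
   Fisher exact test against the split expected from sequencing error
   alone, via the 2×2 table `[[n_ref, n_var], [round(N(1−e)), round(N·e)]]`
   with `e = errRate` (default 0.01, matching the Q20 error bound;
   configurable — deriving `e` from `minQ` as `10^(−minQ/10)` would be the
   natural refinement). The p-value is the exact hypergeometric tail
   (`stats::phyper`), verified in the tests against brute-force table
   enumeration to 1e−12;
4. positions with p < `maxPval` (default 0.05) are reported; the genotype
   is the two highest-count bases among the reference and the candidates,
   collapsing to homozygous when the runner-up falls below `varFraction`.
   Count ties break deterministically in base order A < C < G < T.

Defaults `varFraction = 0.1`, `maxPval = 0.05` are the operating point at
which sensitivity and precision balance on simulated 20× data; raising
`varFraction` toward 0.5 steadily loses heterozygous loci with uneven
allelic coverage (the package's own sweep in the acceptance tests
reproduces this direction). Calls are written as single-sample VCF v4.2
(`GT:AD`, `DP`, QUAL = −10·log10 p capped at 255).

Indels are not called; bases inserted relative to the reference contribute
nothing and deleted positions get no contribution — the minimal consistent
treatment. Paired-end mates are processed as independent reads; an
overlap-aware correction would avoid double-counting the overlapping
segment and is a known limitation. Reference N positions are never profiled
nor tested.

## Conversion-error statistics

The conversion rate is estimated from alignments to a fully unmethylated
control genome (lambda phage, chloroplast): over all cytosine positions of
both strands, `rate = converted / (converted + unconverted)`, with
per-context rates reported alongside.

For a profiled site with `mc` observed methylcytosines out of `cov`, the
largest number of *false* methylcytosines that keeps the level within an
error interval `d` of the observed level is
`fmc = min(mc, floor(d·cov))` (inclusive at exact equality, so a level
landing exactly on the boundary still counts as inside; the closed form is
verified against brute force in the tests). With failure rate
`p = 1 − rate`, the probability that more than `fmc` of the observed
methylcytosines are failures is the binomial survival value
`1 − CDF(fmc; mc, p)` — the probability that the real level lies outside
the interval. Coverage enters only through `fmc`: higher coverage tolerates
more false methylcytosines and yields smaller p-values. Sites with
`mc = 0` have p-value 0 by construction (no false methylcytosine is
possible). This is deliberately a test on methylation *levels*, not a
binary methylated/unmethylated state call: intermediate levels
(allele-specific methylation near 0.5, partial methylation) are biological
signal here, not noise. Benjamini–Hochberg FDR control is available
(`stats::p.adjust` q-values; off by default).

The worked default: a site with 21 reads and 17 methylcytosines has level
0.81; with `d = 0.1`, two false methylcytosines keep the level at
(17−2)/21 = 0.714, inside the interval, while three drop it to 0.67,
outside — so `fmc = 2`, and at `p = 0.01` the p-value is ≈ 6.12e−4.

## The simulator and what it does (not) show

`simulate_reference` → `simulate_diploid` → `simulate_methylome` →
`simulate_reads` build a fully truth-tracked dataset:

* a diploid genome with SNVs planted at density 1e−3/bp, 50% heterozygous
  (one random haplotype) — the density and mix used across the validation
  runs;
* methylation presets per haplotype: all CpGs at `cpg_level` (1 for the
  fully methylated dataset, 0 for the fully unmethylated one), non-CpG
  cytosines at `noncpg_level` (default 0, the typical mammalian situation);
* per-read stochastic conversion: unmethylated cytosines on the read's
  strand convert with probability `conv_rate` (default 0.99, i.e. 1%
  failure);
* per-base sequencing errors with probability `10^(−Q/10)` under a quality
  model: `"q30"` (uniform Q30), `"mixed"` (a broad Illumina-like profile
  with a low-quality tail, used where a quality *gradient* is needed, e.g.
  the `minQ` response tests), or an arbitrary quality pool to resample
  (replay of real data);
* truth-perfect coordinate-sorted SAM plus FASTQ and truth tables.

Emitting perfect alignments deliberately bypasses an aligner: profiling
results are known to be nearly independent of the bisulfite aligner used,
and the shortcut isolates the caller from mapping artifacts. This also
bounds what passing tests show: real data adds mapping errors and biases,
non-uniform coverage, chimeric and contaminant reads, and real quality
distributions. The methylation truth table excludes cytosines within 2 bp
of a planted variant (where reference context and sample context can
disagree), so methylation accuracy is scored only where "correct" is
unambiguous; an SNV call counts as correct only when position *and*
genotype match.

Validation problem sizes: the SNV performance run uses a 1 Mb genome at
20× (≈267k reads, ≈1000 planted SNVs); conversion-rate recovery and the
zero-noise identity use 100 kb at 20×; unit-level properties run on 3–60 kb
genomes. At these sizes the whole suite completes in a few minutes; the
1 Mb run reproduces the expected operating regime (sensitivity in the high
80s–low 90s percent, false-positive fraction ≈ 1%, estimated conversion
rate within 3 binomial standard errors of 99%).

## Numerical and I/O choices

* Exact tests delegate to R's stable tail implementations (`phyper`,
  `pbinom(lower.tail = FALSE)`), never `1 − CDF` in floating point.
* `floor(d·cov)` is computed with a 1e−9 guard so that exact boundary
  products (e.g. 0.1 × 30) are not truncated by binary rounding.
* The native tab format prints levels and mean qualities to 2 decimals;
  the parser recomputes the level from the integer counts, so round trips
  are exact. BED scores are `round(level × 1000)`; WIG levels carry 4
  decimals.
* SAM/BAM input goes through `Rsamtools` (SAM converted on the fly);
  unmapped, secondary and supplementary records are skipped. The bisulfite
  strand comes from a Bismark-style `XG` tag when present, else from the
  FLAG reverse bit under the directional-protocol assumption; contradictory
  tags win with a warning.
* Outputs are deterministic given the configuration seed: two runs on the
  same inputs are byte-identical (the only RNG consumer is the duplicate
  tie-break).

## Known limitations

* No paired-end overlap correction (mates are independent reads).
* Context is reference-based; genotype-aware context correction is not
  attempted.
* No indel calling, joint genotyping, or annotation — the VCF is meant for
  downstream annotation tools.
* The conversion-failure filter must be disabled for samples with high
  non-CpG methylation.
* The simulator does not model RRBS fragmentation, mapping error, or
  coverage bias.
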