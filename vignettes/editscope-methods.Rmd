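---
title: "Methods: RNA-editing-based RBP target discovery with editscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RNA-editing-based RBP target discovery with editscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The experimental design being modelled

When an RNA-binding protein (RBP) is fused to the catalytic domain of ADAR
(ADARcd), mRNAs that come into close contact with the RBP acquire
adenosine-to-inosine edits near the binding sites.  Inosine is read as
guanosine by reverse transcriptase, so in RNA-seq these events appear as
A-to-G mismatches on the gene's sense strand (genomic T-to-C for genes on
the minus strand).  Comparing per-position nucleotide tallies between
fusion-expressing samples and a matched control, thresholding, and
intersecting replicates yields a set of edit sites; the genes carrying
them are the RBP's targets.  Downstream, the questions are *where* on the
transcript the RBP sits (region and metagene distribution, sequence
context) and *what it does* to its targets (stability under RBP
knockdown, with an intron-read control separating transcriptional from
posttranscriptional effects).

`editscope` implements this full downstream analysis and ships a seeded
simulator so that every stage can be validated against planted truth.

# Edit calling

A site is reported when

* experiment coverage >= 20 reads and edited fraction >= 15% (both
  inclusive -- "at least" thresholds are closed bounds, and the boundary
  is tested exactly),
* the control is covered by >= 20 reads and shows an edited fraction of
  at most `ctrl_max_alt_frac` (default 0, i.e. a perfectly unedited
  control; configurable because control types differ between genomic-DNA
  and non-fusion-RNA designs),
* the site's sense-strand reference base is A.  For non-strand-specific
  libraries the annotated gene strand decides orientation.

Experiment sites whose control is missing or under-covered are excluded
conservatively (never called) and counted in a `no_control` diagnostic so
the filtering funnel stays auditable.  Replicate intersection keys sites
by `(contig, position, strand)` and keeps each replicate's edit fraction,
which is the substrate for the usual replicate heatmap.

At the pileup stage (`pileup_site_counts()`), bases below Q20 and reads
below MAPQ 10 are discarded; the MAPQ filter approximates the
unique-mapping restriction of aligner-level filtering.

# Coordinates, regions and the metagene

All internal coordinates are 0-based half-open; GTF (1-based inclusive)
and bedGraph are converted only at the I/O boundary, so no off-by-one
drift can accumulate.  Each gene is represented by one transcript -- the
longest mRNA, ties broken by smallest transcript id -- a deterministic
rule chosen because annotation-based analyses must not depend on file
order.  Non-coding transcripts are kept and label their edits
`noncoding_exon` rather than being dropped, which keeps edit accounting
conservative.

The metagene coordinate rescales the 5'UTR, CDS and 3'UTR each to unit
length: a site at fraction *f* of its region maps to *f*, 1 + *f* or
2 + *f*.  No smoothing is applied; binning is left to plotting.  When two
genes' exons overlap a site, the gene whose representative places the
site in a UTR wins, then the lexicographically smaller gene id -- again a
determinism-over-cleverness choice, with both candidates recoverable from
the annotation table.

# Motif windows and k-mer enrichment

Windows of +/-100 nt are taken around each edit *in mRNA coordinates* of
the representative transcript, so they are intronless by construction and
truncated at transcript ends without padding.  Motif discovery is a
self-contained k-mer statistic rather than an external motif suite: every
8-mer's observed count across windows is compared with its distribution
over per-window dinucleotide-preserving shuffles (Altschul-Erickson
Euler-path shuffling, which preserves doublet composition and end bases
exactly; the property is unit-tested).  The score is
`z = (obs - mean_null) / sd_null` with an empirical p-value
`(1 + #rounds >= obs) / (n_shuffles + 1)`.

Two numerical choices matter.  The null sd is floored at 0.5 counts:
k-mers seen once and never re-created by any shuffle would otherwise get
an infinite z and outrank genuine signal; half a count is below the
resolution of integer count data.  And k = 8 is the default because the
AU-rich element reported for this class of RBP is the octamer
`UAUAUAUA`.  The empirical p-value of a single k-mer is not
multiplicity-corrected; the ranking, not the p-value, is the primary
output, and a family-wise claim about "some enriched k-mer" would need a
max-statistic null instead.

# ARE scoring

AU-rich-element strength of a 3'UTR is scored from `AUUUA` pentamers with
a clustering-and-context parameterization: 1.0 point per occurrence
(overlapping occurrences counted via a positional scan), +1.5 for
consecutive pentamer starts <= 10 nt apart, +0.75 for 11-20 nt, and +0.5
for a pentamer whose immediate neighbours on both sides exist and are A
or U.  Sequences of 10 nt or shorter are not scored (a sentinel, not a
zero).  Per gene, the highest-scoring isoform is kept, ties again
resolved by transcript id.  The weights are package parameters
(`are_params()`), exposed because different ARE scoring tools weight
context differently; every comparison inside a run uses the same
parameterization on both sides, so the downstream statistics
(target-vs-transcriptome, down-vs-not-down) are self-consistent.  The
implementation is verified against an independent character-by-character
oracle on 10^4 random sequences.

# Stability statistics

**Normalization** is median-of-ratios: the reference is the per-gene
geometric mean across samples over genes with no zero count; each
sample's size factor is the (log-space) median ratio to that reference.
The log-space median matches the reference implementation used by
standard DE tools, against which the size factors are cross-checked in
the tests.  By construction each sample's median log-ratio to the
reference is zero, and this invariant is asserted on every call.  A
consequence worth remembering: if a majority of genes share a true fold
change, the normalization absorbs it; stability analyses here assume the
affected targets are a minority of the transcriptome.

**Differential expression** uses a two-sided permutation test on the
difference of mean `log2(normalized + 0.5)` between conditions (the 0.5
pseudocount keeps zeros finite).  All label arrangements are enumerated
when there are at most 1000, otherwise 10^4 Monte-Carlo permutations are
drawn under the run seed.  The permutation p-value is discrete with floor
`2 / C(n1+n2, n1)`: with 3 vs 3 samples the smallest achievable p is 0.1,
so no gene can be called at alpha = 0.05 -- five replicates per condition
(floor ~0.008) is the minimum design this classifier can resolve at the
conventional threshold, and it is the count simulator's default.

Classes are `down` / `unchanged` / `up` from the sign of the log2 fold
change and `p < alpha`.  Raw-p thresholding is the default; with
permutation p-values floored well above `alpha / n_genes`,
Benjamini-Hochberg across thousands of genes would leave every gene
unclassified, so BH is available (`p_adjust = "BH"`) but not the default.
No fold-change floor is imposed on the classes; a configurable `lfc_null`
exists for analyses that want one.

**Stratification.**  The 3x2 class-by-group (target/background) table is
tested with Pearson's chi-square without continuity correction; classes
observed in neither group are dropped from the statistic (they carry no
information and would make it undefined), and cells with expected counts
below 5 are flagged.  Bootstrap resampling (default 1000 draws with
replacement of both the target set and the background) yields
2.5/97.5-percentile intervals per class fraction and a chi-square p per
resample; the per-resample p-values are combined with Fisher's method,
`-2 * sum(log p) ~ chi-square(2k)`, applied globally over resamples.
Combining per-class rather than globally is possible in principle; the
global form is the default because the per-resample test is already a
joint test over classes.

**Nascent control.**  Intron intervals are each gene's span minus the
union of *every* exon of *every* transcript of *every* gene, so no
interval overlaps any annotated exon (asserted on every build); genes
left with nothing are absent.  The intron count matrix is pushed through
the same normalization and classifier as the exonic arm, so the
exon/intron verdicts are methodologically comparable: exonic `down` with
intronic `unchanged` is the posttranscriptional signature.

# What the simulator emulates, and what it does not

`simulate_reference()` builds a single-contig genome of gene models
(5'UTR 50-150 nt, CDS 300-900 nt, 3'UTR 150-500 nt, zero to two introns
of 61-200 nt) on random strands.  Defaults encode the study conditions
this class of experiment reports:

* two experiment replicates plus one control;
* planted edit sites distributed over 5'UTR/CDS/3'UTR with weights
  4 : 26.7 : 69.5, the regional split observed for a 3'UTR-binding RBP;
* true edit fractions uniform on [0.25, 0.8], i.e. sites at or above the
  fraction regime the 15% threshold is meant to capture;
* per-site coverage negative-binomial with mean 100 and size 10,
  mimicking RNA-seq overdispersion at typical brain RNA-seq depth;
* per-base sequencing error 2e-4, the error rate corresponding to the
  ~Q37 mean base quality of modern Illumina reads after adaptor
  trimming;
* an exact `UAUAUAUA` element written into 80% of target 3'UTRs (most,
  not all, targets carry the motif).

Sites are simulated as pileup tallies, not reads: the caller consumes
per-position tallies, and simulating reads would add alignment confounds
that are upstream of this pipeline (alignments enter only through
`pileup_site_counts()`, which is integration-tested from a small SAM).
At a planted site with fraction *f* and coverage *n*, the edited count is
Binomial(*n*, *f*); all remaining reads are subject to the error rate,
split over the three non-reference bases.  The control is an
error-only sample -- both genomic-DNA and non-fusion-RNA controls reduce
to "no planted edits" at this level.  Every stream is seeded and the draw
order is documented in the source, so runs are byte-reproducible and a
test replays the protocol with an independent re-derivation.

`simulate_counts()` draws negative-binomial counts (log-normal gene
means around 300, dispersion 0.05, five samples per condition) and
applies the knockdown effect (default log2FC -1, i.e. the RBP stabilizes
its targets) to target genes' exonic means only; the intronic matrix
(means at 30% of exonic) takes an independent, default-zero effect, so a
purely posttranscriptional scenario is the default and a transcriptional
one is a parameter away.

Deliberately not modelled: read-level error profiles and PCR duplicates,
splice-aware read placement, ADARcd nearest-neighbour sequence
preference around edited adenosines (edits are planted uniformly within
regions), SNP contamination of the control, and isoform-level expression
differences.  Passing the planted-truth tests therefore demonstrates the
pipeline's correctness and calibration, not robustness to alignment
artefacts or variant confounds in real data.

# Problem sizes and calibration checks

The test suite validates, among others: exact equivalence of the edit
caller with a brute-force reference on 10^4 random tally rows including
the exact 20-read/15% boundary; >= 95% recovery of planted sites with
zero false positives after replicate intersection over 20 simulator
seeds; a 3'UTR fraction of exactly 1.0 when edits are planted only in
3'UTRs, with strictly monotone metagene coordinates; top-rank recovery
of the planted octamer in >= 95% of seeds (50 windows, 100 shuffles);
ARE-scorer equality with the brute-force oracle on 10^4 sequences;
the hand-computable size factors (1/sqrt(2), sqrt(2)) of a
doubled-sample toy matrix; the df-4 closed form of Fisher's method;
type-I error of the permutation classifier within [0.035, 0.065] on a
2000-gene, 5-vs-5 null; uniformity (Kolmogorov-Smirnov) of the
contingency chi-square p over 200 null simulations; and, over 20 seeds,
the full posttranscriptional signature -- target down-fraction above
background with chi-square p < 0.05 while the intron arm reports the
majority of targets unchanged.  These sizes were chosen so the whole
suite exercises every claim at meaningful statistical resolution while
remaining comfortable to run on a laptop.

# Known limitations

* The permutation classifier needs >= 5 replicates per condition to call
  anything at alpha = 0.05; it trades the parametric power of NB-GLM
  tools for assumption-free calibration.
* Median-of-ratios assumes most genes are unaffected; global shifts are
  normalized away by design.
* Gene assignment uses one representative isoform; regions for genes
  with strongly divergent isoform structure inherit that choice,
  and alternative-isoform quantification is out of scope.
* The k-mer statistic ranks fixed-length words; degenerate or
  variable-length motifs would be diluted across related k-mers.
* Edit calling performs no SNP masking beyond the control comparison and
  no hyper-editing cluster detection.
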