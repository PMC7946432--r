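# editscope

RNA-editing-based discovery of RNA-binding-protein (RBP) targets, and
analysis of what the RBP does to them.

## The problem

Fusing an RBP to the catalytic domain of ADAR (ADARcd) causes mRNAs near
the RBP's binding sites to acquire A-to-I edits, read out as A-to-G
mismatches in RNA-seq (genomic T-to-C on minus-strand genes).  This gives
an in vivo map of RBP-mRNA contacts from ordinary RNA-seq of small tissue
samples.  `editscope` is for groups running such fusion-editing
experiments who need the downstream computation: calling edit sites from
experiment-vs-control pileups, locating them on transcripts, describing
their sequence context, and quantifying the RBP's effect on target-mRNA
stability.

## What it computes

* **Edit calling** — at every sense-strand adenosine, a site is reported
  iff experiment coverage ≥ 20 reads with edited fraction ≥ 15% (both
  inclusive) and a control covered ≥ 20 reads shows no edited reads;
  replicate sets are intersected by `(contig, position, strand)`.
  Input is BAM (via a Q20/MAPQ10-filtered pileup) or per-position tally
  tables; output is bedGraph (percent scale) and a per-replicate
  fraction table.
* **Region & metagene assignment** — each edit is mapped through its
  gene's representative transcript into 5′UTR/CDS/3′UTR (or
  noncoding-exon/intron/intergenic), with metagene coordinate
  *x* = region_index + fractional position, each region scaled to unit
  length.
* **Motif context** — intronless ±100 nt windows around edits; k-mer
  enrichment *z* = (obs − mean_null)/sd_null against per-window
  dinucleotide-preserving shuffles (MEME-free, self-contained).
* **ARE scoring** — AU-rich-element strength of 3′UTRs from AUUUA
  pentamers (1.0 each) plus clustering bonuses (+1.5 at ≤ 10 nt,
  +0.75 at 11–20 nt) and AU-flank context (+0.5); best isoform per gene;
  UTRs ≤ 10 nt unscored.
* **Stability** — median-of-ratios normalization; permutation-test
  differential expression classes (down/unchanged/up at p < 0.05);
  3×2 target-vs-background contingency with Pearson χ² (df = 2);
  1000× bootstrap class-fraction CIs with per-resample χ² p-values
  combined by Fisher's method, −2Σln p ~ χ²(2k).
* **Nascent-transcription control** — reads in exon-purged intron
  intervals, classified identically to the exonic arm: exonic *down*
  with intronic *unchanged* is the posttranscriptional signature.
* **Synthetic data** — seeded generator of genomes, annotations,
  edit-bearing pileups (binomial edits at programmed fractions on
  negative-binomial coverage) and NB count matrices with planted truth,
  so every stage is verifiable without downloads.

## Worked example

```r
library(editscope)

cfg     <- sim_config(seed = 42)                  # 60 genes, 12 targets
ref     <- simulate_reference(cfg)
pileups <- simulate_tribe_pileups(ref, cfg)       # R1, R2, control
index   <- build_gene_index(ref$models)

tribe <- run_tribe(pileups[c("R1", "R2")], pileups$control,
                   index, ref$genome, seed = 42)
tribe$region_summary
#> RegionSummary: 36 edits in 12 genes (0 single-site)
#>   5'UTR 5.6%  CDS 25.0%  3'UTR 69.4%
head(tribe$common, 3)
#>   contig pos0 strand   frac_R1   frac_R2
#> 1  chrS1 7939      - 0.6081081 0.5796178
#> 2  chrS1 9094      - 0.6105263 0.6486486
#> 3  chrS1 9106      - 0.5679012 0.5692308

counts <- simulate_counts(ref, ref$truth, count_sim_config(seed = 42))
stab <- run_stability(counts$exonic, counts$labels, ref$truth$target_genes,
                      intron_counts = counts$intronic, n_boot = 1000, seed = 42)
stab$contingency
#>            grp
#>             target background
#>   down          10          0
#>   unchanged      2         43
#>   up            0          5
#> chi-square 48.056, df 2, p 3.67e-11 (cells with expected < 5)
round(stab$nascent$fractions, 3)
#>      down unchanged        up
#>         0         1         0
```

All 36 planted edit sites are recovered (no false positives), their
regional split matches the programmed 3′UTR-dominant binding, knockdown
reduces 10/12 targets versus 0/48 background genes (χ² p ≈ 4e-11), and
the intron arm reports every target unchanged — the programmed
posttranscriptional stabilization, recovered end to end.

A command-line wrapper for the common steps lives in
`inst/scripts/editscope.R` (subcommands `simulate`, `call`,
`stability`).

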