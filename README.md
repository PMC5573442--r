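# nucmiR

Some mature microRNAs are not exported to the cytoplasm but accumulate in the
nucleus, where they can engage Argonaute complexes, transcription factors and
the splicing machinery. `nucmiR` is an R/Bioconductor-style package for the
computational side of such a study: it takes compartment-fractionated
(nuclear vs. cytoplasmic) expression matrices, calls nucleus-enriched miRNAs,
characterizes the sequence motif they share, scans their precursor hairpins
for MAZ transcription-factor GA-box elements, integrates Ago1/Ago2 RIP-seq
count tables with seed-site target scanning, and screens exon-level
expression for compartment-differential splicing. A synthetic-data generator
with recorded ground truth stands in for the raw arrays and sequencing, so
the whole pipeline is testable offline.

## The methods in brief

**Enrichment calling.** Given a probe × sample matrix of raw signals with
per-sample compartment labels (triplicate nuclear and cytoplasmic fractions),
three methods are provided:

1. *Moderated t* — cross-sample quantile normalization, then a per-probe
   two-group statistic on log2 signals with empirical-Bayes variance
   shrinkage: posterior variance `(d0·s0² + d·s²)/(d0 + d)` with the prior
   `(d0, s0²)` fit by moment matching, `t` referred to `d0 + d` degrees of
   freedom, BH-adjusted q-values.
2. *Rank separation* — within each sample, probes are ranked by signal and
   scored by their distance from the median position; a probe is enriched
   when every nuclear sample scores strictly above every cytoplasmic sample.
3. *Nuclear percentage* — no normalization: signals are averaged across
   replicates, probes with raw signal < 30 in all samples are dropped, and
   `Nuclear % = 100·nuc/(nuc + cyt)` is thresholded strictly at 70%.

**Motif analysis.** k-mer (default 4 nt) presence counting over the enriched
mature sequences; association between motif carriage and enrichment is tested
with a log-space exact hypergeometric (Fisher) test on the 2×2 table of
carriers in the enriched versus least-nuclear groups. A GA-box scanner
reports all `GnAGn` (n = 2..6) MAZ consensus elements in precursor hairpins,
maximal arm per A-center.

**RIP targets.** Genes with total read count < 10 are removed; remaining
genes are scanned for canonical seed sites (8mer, 7mer-m8, 7mer-A1, 6mer —
matches to the reverse complement of miRNA positions 2–7 graded by the
position-8 pair and the A opposite position 1) of the nucleus-enriched
miRNAs, and the Ago1/Ago2 target sets are partitioned into unique and shared
genes.

**Splicing screen.** Per exon, a splicing index
`si = log2((exon/gene)_nuc / (exon/gene)_cyt)` on replicate-averaged,
gene-normalized signal, and a per-transcript two-way ANOVA on log2 signals
whose exon × compartment interaction is tested per exon
(single-exon-vs-rest contrast); exons with BH q < 0.01 and linear fold > 2
flag their transcript, and flagged transcripts are paired with the
nucleus-enriched miRNAs that target them.

## Worked example

```r
library(nucmiR)

# simulate a triplicate fractionation array: 847 probes, 13 planted enriched
sim <- simulateExpression(seed = 1)
tab <- enrichmentTable(sim$experiment, analysisConfig())
sum(tab$method3_call)
#> [1] 13
setequal(tab$probe_id[tab$method3_call], sim$truth$enriched_probe_ids)
#> [1] TRUE

# motif discovery on a synthetic 13-vs-30 mature-miRNA design
ms <- simulateMirnaSet(seed = 1)
findRecurrentMotif(ms$enriched, k = 4)
#>   motif support  n
#> 1  GAGG      12 13
ct <- motifContingency(ms$enriched, ms$background, "GAGG")
fisherExact(ct, alternative = "greater")
#> [1] 8.475307e-10

# GA-box elements in a precursor hairpin
mazScan(simulatePremir(elementN = 3, seed = 2))
#>     name start n matched
#> 1 premir    10 3 GGGAGGG
```

The enrichment table reports, per probe retained by the signal floor, the
replicate-mean signals, the nuclear percentage with its strict >70% call
(`method3_call`), the rank-separation call (`method2_call`) and the
moderated-t statistics. The Fisher p-value above is the exact one-sided tail
`31 / C(43,13)` of the 12-of-13 versus 0-of-30 carrier table — the
association between the GAGG motif and nuclear enrichment is significant far
below the 1e-4 level.

A full simulated run of every stage, with TSV outputs and a run log:

```r
runPipeline(analysisConfig(rng_seed = 5), "nucmir-out")
```

A thin command-line wrapper with subcommands (`simulate`, `enrich`, `motif`,
`maz-scan`, `rip`, `splice`, `pipeline`) is installed at
`inst/scripts/nucmir-cli.R`.

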