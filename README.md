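# patrseq

Genome-wide assessment of post-transcriptional control from paired
polyA-selected and total (rRNA-depleted) RNA-seq quantifications.

## The problem and the statistic

Steady-state mRNA levels are set jointly by transcription and degradation,
and most post-transcriptional effectors (miRNAs, RNA-binding proteins)
destabilize their targets by shortening the polyA tail. A total
(rRNA-depleted) library captures all RNA species — nascent transcripts and
deadenylated molecules included — whereas a polyA-selected library captures
only transcripts with long polyA tails. For a transcript *t* quantified in
paired libraries (same replicate and timepoint), the per-sample ratio

    r_{t,k} = PA_RPKM_{t,k} / TR_RPKM_{t,k}

and its average over the *K* replicate-timepoint pairs,

    PA/TR_t = (1/K) * sum_k r_{t,k}

estimate the fraction of transcript *t*'s molecules that are fully
polyadenylated. A high PA/TR marks a stable, weakly regulated transcript; a
low PA/TR marks strong post-transcriptional control. The coefficient is
relative (it does not estimate half-lives), so downstream analyses operate
on log2 values and ranks:

- **Validation** — intronic total-library signal tracks nascent
  transcription, so the intron/exon ratio I/E is an independent turnover
  proxy; transcripts in the top PA/TR tail should occupy low I/E ranks and
  vice versa.
- **Gene-set analysis** — two-sided Mann–Whitney shift tests of each set's
  PA/TR values against all other transcripts, and one-sided hypergeometric
  over-representation of sets in the extreme 5% tails against the expressed
  background, both with Benjamini–Hochberg FDR.
- **Expression association** — OLS of log2 PA/TR on log2 polyA RPKM,
  globally and stratified at 1 RPKM; unit-width RPKM bins with one-way
  ANOVA across the 20–80 RPKM range.
- **miRNA targets** — Mann–Whitney plus a seeded 10,000-sample stratified
  bootstrap (difference of group median log2 PA/TR, percentile CI) comparing
  predicted miRNA targets with non-targets; per-family shift tests with
  FDR; Spearman correlation between family expression and target-median
  PA/TR.

A fully seeded synthetic-data generator with known ground truth
(transcription rate, degradation rate, polyadenylated fraction per
transcript) makes every stage testable without external downloads.

## Worked example

```r
library(patrseq)

sim <- simulateDataset(defaultStudyShapedConfig())   # 5000 transcripts, seeded
d   <- tempfile()
p   <- writeDatasetBundle(sim, d)
cfg <- pipelineConfig(p$expression, p$metadata, p$signals, p$gene_sets,
                      p$mirna_targets, p$mirna_expression,
                      output_dir = file.path(d, "out"),
                      bootstrap_samples = 10000)
res <- runPipeline(cfg)
res$stability
#> StabilityTable with 3814 transcripts, 4 sample pairs
#>   patr: median 0.6603 [7.478e-05, 1.842]
#>   I/E ratio available for 3209 transcripts
#>   tails: 190 top, 190 bottom
```

3814 of 5000 transcripts survive the filters (232 non-coding, 954 in the
bottom 20% of mean RPKM); each carries the mean of 4 per-sample PA/TR
ratios (2 replicates x 2 timepoints), and 190 transcripts (5%) are flagged
per extreme tail. The miRNA-target comparison on this run:

```r
tvn <- res$mirna$test
#> MW p = 5.96e-17 ; bootstrap diff = -0.214, 95% CI [-0.301, -0.138], p = 0.0001
```

Predicted targets (n = 1603) sit about 0.21 log2 units below non-targets
(n = 2211) in median PA/TR — the planted target skew toward the unstable
class is recovered, and the bootstrap p is at its 1/b floor. Family
expression, drawn independently of target stability, shows no significant
correlation with target-median PA/TR (rho = 0.20, p = 0.059, 90 families).
The gene-set shift panel ranks the planted low-stability set first:

```r
head(res$geneset_shift, 2)
#>   term_id n_in_set median_patr      p_value          fdr direction
#> 1  SET001      114   0.4465953 8.065528e-08 4.032764e-06  low_patr
#> 2  SET007      112   0.5073127 1.372887e-04 3.426273e-03  low_patr
```

All per-stage tables plus a YAML run manifest (parameters, seed, record
counts) are written to the output directory. A command-line wrapper for
the simulate/run steps is in `inst/scripts/run-pipeline.R`, and
`vignettes/patr-methods.Rmd` documents the model, the generator, and the
numerical choices.

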