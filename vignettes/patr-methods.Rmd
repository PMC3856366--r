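---
title: "Estimating post-transcriptional control from paired polyA and total RNA-seq"
author: "patrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating post-transcriptional control from paired polyA and total RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patrseq)
```

## The model

A transcript's abundance in a total (rRNA-depleted) library reflects all of
its molecules — nascent, deadenylated and mature alike — while its
abundance in a polyA-selected library reflects only the fully
polyadenylated fraction, because short-tailed molecules bind oligo-dT
poorly. Writing $M_t$ for the steady-state abundance of transcript $t$ and
$f_t \in (0, 1]$ for its polyadenylated fraction, the two library signals
are ideally $TR_t = M_t$ and $PA_t = f_t M_t$, so the per-sample ratio
$PA_t / TR_t$ estimates $f_t$ directly, with the abundance cancelling.
Because deadenylation is the convergent step of most decay pathways, $f_t$
rises with stability: a high PA/TR marks a long-lived transcript, a low
PA/TR strong post-transcriptional control. PA/TR is a *relative*
coefficient — no absolute half-life is estimated — so every downstream
analysis works on its log2 or its rank.

The pipeline mirrors the design it was built for: two replicates at two
circadian timepoints (ZT0, ZT12), polyA and total libraries for each, so
each transcript has four per-sample ratios whose arithmetic mean is the
coefficient. Averaging is ratio-then-mean, not a ratio of summed RPKM:
with per-sample sequencing-depth noise the per-sample quotient cancels
pair-specific scale factors, and the mean of the four quotients is the
unbiased summary of the paired design.

### Filtering

Non-coding transcripts are removed (they are never polyadenylated and
only pollute the ratio), then the bottom 20% of coding transcripts by mean
RPKM over *all* samples (polyA and total pooled). Pooling is deliberate:
filtering on one library alone would bias PA/TR near the threshold in a
known direction, while the pooled mean is symmetric in the two channels.
The quantile is the inverse-ECDF (type-1) empirical quantile and the rule
keeps transcripts *strictly above* it, so on distinct summaries exactly
$\lceil nq \rceil$ transcripts are removed — a deterministic sort-and-slice
with no interpolation ambiguity. Transcripts with a zero total-library
value in any pair are dropped afterwards (the ratio is undefined there);
their count is recorded in the provenance.

### Intron/exon validation

Intronic signal in the total library is only present in unspliced, nascent
molecules, so intronic RPKM tracks the transcription rate while exonic
RPKM tracks steady-state abundance. Their ratio I/E is therefore high for
high-turnover transcripts (much nascent relative to mature) and low for
stable ones — an anti-correlated, independent check on the PA/TR ranking.
The package computes I/E as intron over exon; an orientation switch
(`computeIeRatio(..., orientation = "exon_over_intron")`) is provided
because the ratio is reported in both orientations in the literature, and
only ranks matter downstream. Transcripts without annotated introns or
with zero exonic signal carry no I/E value and are excluded from rank
comparisons, never silently assigned one. Comparisons between PA/TR and
I/E use ranks only, which removes the unknown proportionality constants of
both ratios.

## Tests and their conventions

**Rank-shift tests.** Gene sets, expression bins and miRNA-family target
sets are all compared with the *complement* of the set within the analysed
table (not the full table including the set), by a two-sided Mann–Whitney
U test. The p-value is exact when the combined sample is at most 20 and
tie-free, and uses the normal approximation with tie and continuity
correction otherwise. Direction (`low_patr` / `high_patr`) is reported
separately from the p-value, as the sign of the set median against the
population median. If both groups are a single constant the test is
degenerate and reports p = 1 with a flag.

**Over-representation.** For the extreme tails, enrichment of a set in the
selection is the upper-tail hypergeometric probability
$P(X \ge \text{overlap})$ with the expressed (filtered) table as the
background; set members outside the background are ignored, and terms with
no member in the background are skipped and counted. p-values are
Benjamini–Hochberg adjusted within each analysis batch (one tail's run,
one panel of shift tests), matching the per-figure grouping in which such
results are read.

**Expression association.** OLS of log2 PA/TR on log2 mean polyA RPKM;
the logged predictor is used because the relationship is multiplicative
and the plot of interest is log–log. Strata are all transcripts, those at
or above 1 RPKM (inclusive), and those below (exclusive), so the strata
partition the table. Expression bins are half-open $[l, u)$ unit-width
intervals at 1–1.5, 10–11 and each decade step 20–21 … 80–81; the ANOVA
runs over the 20–80 bins (those populated with at least two values) and
bin-vs-complement shift tests are BH-adjusted across bins.

**miRNA targets.** The target set is the union of all family target lists
intersected with the table; its complement is the non-target set. Two
tests are run on log2 PA/TR: the Mann–Whitney above, and a bootstrap whose
scheme is fully specified here because the quantity of interest is a
difference of medians, for which no finite-sample exact test exists:
stratified case resampling (each group resampled with replacement at its
own size), $b = 10{,}000$ replicates, percentile 95% CI, two-sided
sign-crossing p-value $2\min(\hat F(0), 1 - \hat F(0^-))$ floored at
$1/b$, all driven by one recorded seed — identical seed and inputs give a
bit-identical result. Per-family tests reuse the shift machinery; a family
is flagged `lower_than_population` when its direction is low and its FDR
clears the configurable 0.05 threshold. The expression–stability
correlation is Spearman's rho between family mean expression (arithmetic
mean over the six array timepoints) and family target-median PA/TR, with
an exact p for nine or fewer tie-free pairs and the t-approximation
otherwise.

## The synthetic-data generator

`simulateDataset()` draws, per transcript: a stability class (unstable
with probability 0.3), a degradation rate $k_{deg}$
(log-normal, median 0.25 for stable and 1.0 for unstable — a four-fold
regime gap), a transcription rate $k_{tx}$ (log-normal, median 20, one
log-unit spread), abundance $M = k_{tx} / k_{deg}$, and a polyadenylated
fraction $f$ from a class-specific Beta law — stable Beta(2, 1), unstable
Beta(0.6, 4) — coupled anti-monotonically to $k_{deg}$ within each class
(the slowest-degrading members get the largest $f$). Noise-free signals
are $PA = f M$, exonic $TR = M$, intronic $0.1\,k_{tx}$ (the nascent
proportionality constant is arbitrary; only ranks are used); observed
RPKM multiplies each by independent log-normal noise (default
$\sigma = 0.25$) per sample. Gene sets can be planted with odds-weighted
sampling toward one class; miRNA families draw their targets from a pool
covering ~48% of transcripts, itself odds-weighted toward the unstable
class, so the union of family targets stays near the realistic half-way
coverage rather than saturating the transcriptome; family expression is
drawn independently of target stability.

The Beta shapes and regime gap are the generator's central calibration,
and two requirements pull against each other. Rank recovery of $f$ from
noisy PA/TR needs wide within-class spread of $\log f$ and, critically, no
boundary pile-up: shapes with $b < 1$ concentrate mass at $f = 1$, where
neighbouring transcripts differ by less than the measurement noise and
ranks become uninformative, capping the achievable Spearman correlation.
Planted-effect power, by contrast, needs the two classes well separated
relative to their spread. The defaults satisfy both: at
$\sigma = 0.25$ and $n = 5000$ the pipeline recovers
$\rho(\text{PA/TR}, f) \approx 0.92$, and a planted 200-member set with
4:1 odds toward the unstable class is detected at FDR < 0.05 essentially
always. The regime gap interacts with the expression filter: a much wider
gap would make unstable transcripts so much less abundant that the
bottom-20% filter strips a large share of any planted unstable set before
it is tested, so the four-fold gap keeps the class contrast while leaving
planted sets observable downstream.

What the generator does *not* emulate: read-level sampling noise (RPKM
noise is a single multiplicative log-normal, with no mean–variance
relationship), circadian oscillation between the two timepoints, gene-level
isoform structure, correlated gene-set overlaps, and miRNA families with
heterogeneous per-target efficacy. Passing tests therefore certify the
statistics and their calibration under the stated generative assumptions,
not the biological correctness of PA/TR on any real dataset. One
consequence worth naming: because $M = k_{tx}/k_{deg}$, abundance and
stability are mechanistically coupled in the generator, so the global
expression–stability regression on synthetic data shows a much larger
$R^2$ than a real transcriptome would; the stratified *pattern* (the
below-1-RPKM stratum far exceeding the above-1 stratum when the
low-expression/instability coupling dial is on) is the meaningful
qualitative output there.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `bottom_quantile` | 0.20 | expression filter on pooled mean RPKM |
| `tail_fraction` | 0.05 | extreme-tail size, `floor(f*n)` per tail |
| `stratum_threshold` | 1 RPKM | regression stratum split on mean polyA RPKM |
| `bootstrap_samples` | 10,000 | bootstrap replicates; p floored at 1/b |
| `fdr_threshold` | 0.05 | per-family `lower_than_population` flag |
| `noise_sigma` | 0.25 | log-normal measurement noise SD (generator) |
| `unstable_fraction` | 0.3 | unstable-class prevalence (generator) |

Numerical conventions, collected: log base 2 throughout (base affects no
rank, test or $R^2$); average ranks on ties; extreme-tail boundary ties
broken lexicographically by transcript id so tail membership is
deterministic; half-open bins; filter threshold strict; TSV interchange at
17 significant digits so write–read round-trips are exact.

## Known limitations

PA/TR conflates stability with nuclear retention, cytoplasmic
polyadenylation and splicing efficiency — it measures post-transcriptional
control broadly, not turnover specifically. The hypergeometric ORA treats
gene sets as flat lists with no ontology-graph propagation and no
annotation weighting, so its absolute p-values are not comparable to
annotation-service outputs built on different backgrounds. The bootstrap
compares medians only; distributional differences with equal medians are
invisible to it. And the per-family tests inherit the usual caveat of
target-prediction inputs: families are only as good as the target lists
supplied.

## Problem sizes

The test suite and the acceptance script run at desk scale: 5000-transcript
simulations for recovery and power, 2500 for null calibration, 1200 with 60
families for the correlation null, 10,000 bootstrap replicates in the
single full-pipeline run and reduced b inside replicated loops. These sizes
give Monte-Carlo error comfortably inside the asserted bounds while keeping
a full run in minutes.
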