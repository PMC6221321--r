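# odmap — opioid dependence mapping from time-course expression data

`odmap` is an R package for finding **opioid-dependence-associated
genes**, their candidate **transcription regulators**, and
**signature-reversing compounds** from multi-drug time-course expression
data in brain striatum — the design in which mice receive a single dose
of one of six drugs of abuse (morphine, heroin, cocaine,
methamphetamine, ethanol, nicotine) and striatal expression is profiled
at 1, 2, 4, 8 h against a shared naive 0 h control, with three
biological replicates per group.

It is written for computational biologists who want every stage of such
an analysis as a tested, reusable function rather than a one-off script:
each stage has planted-ground-truth synthetic data behind it, so its
sensitivity, error control, and calibration are measured, not assumed.

## The statistics at the core

**Differential expression over time.** Each gene × drug time course is
fitted by local quadratic regression (tricube weights; bandwidth chosen
per gene by leave-one-out cross validation summed across drugs). A gene
is DE when the Sun–Loader (tube-formula) simultaneous band around the
fitted difference curve d(t) = f̂(t) − f̂(0) excludes zero at some time —
with the band-exclusion p Bonferroni-corrected across genes at α = 0.05
— and the fold change 2^max|d(t)| is ≥ 1.2. The time of maximal
response assigns the phase: Immediate-Early (0–2 h], Middle (2–4 h],
Late (4–8 h].

**Temporal patterns.** Hartigan–Wong k-means (Euclidean, 1000 restarts)
on the smoothed log2-ratio profiles; the number of clusters maximizes
the average silhouette width; clusters are labelled up/down × IE/M/L.

**Enrichment.** Exact hypergeometric over-representation of functional
gene sets (GMT) per cluster, and of regulator target sets — genes whose
1000-bp TSS/TTS window overlaps a binding peak — among the
dependence-associated DEGs, with Benjamini–Hochberg FDR in regulator
mode.

**Harm association.** For each opioid DEG, its cross-drug vector of
smoothed log2 ratios is tested against each of twelve expert drug-harm
ratings (dependence, physical/psychological dependence, pleasure,
physical/social harm subscales, conditioned place preference) by
Pearson correlation and quadratic regression; significant if either
p < 0.05.

**Regulator scores.** A regulator's *dependence score* in a phase is
the sum of its regulated dependence-associated DEGs' maximal absolute
fold changes in that phase; per-effect association scores are the
analogous sums.

**Compound reversal.** Compound signatures are compared with the
dependence signature by a connectivity-map-style weighted
Kolmogorov–Smirnov statistic in [−1, 1] (negative = the compound
opposes the signature), with gene-label permutation p-values.

## Worked example

Everything below runs from a synthetic bundle with planted ground
truth; replace the file paths with your own TSV/CSV/GMT/BED/GFF3 inputs
for real data.

```r
library(odmap)

cfg <- simulation_config(n_genes = 500, seed = 42)
bundle <- write_synthetic_bundle("demo", cfg)

pc  <- bundle_config("demo", n_restarts = 200, seed = 42)
res <- run_pipeline(pc)
#> [de] 93 DE calls across 2 opioid(s) from 500 genes
#> [cluster] morphine: K = 6 (ASW = 0.668)
#> [cluster] heroin: K = 6 (ASW = 0.632)
#> [associate] 192 significant (gene, effect) pairs
#> [enrich-regulator] morphine: 7 enriched regulator(s)
#> [reverse] morphine: top compound CMP0012 (score = -0.795)
```

The DE table (also written to `demo/results/degs.tsv`):

```r
degs <- subset(res$degs, is_de & drug == "morphine")
head(degs[, c("gene", "adj_p", "signed_fc", "t_max", "phase", "direction")], 4)
#>      gene    adj_p signed_fc t_max phase direction
#> 2 G000002 3.46e-05      1.94  4.25     L        up
#> 3 G000003 1.29e-04      2.00  8.00     L        up
#> 4 G000004 7.04e-08     -2.09  2.00    IE      down
#> 5 G000005 3.30e-02     -1.76  3.75     M      down
```

`adj_p` is the Bonferroni-adjusted band-exclusion p; `signed_fc` the
linear fold change (negative = down); `phase` the response window of the
strongest deviation. K = 6 patterns (up/down × three phases) maximize
the silhouette width for both opioids, as planted.

The reversal ranking (`demo/results/reversal.tsv`) lists candidate
reversers of the morphine dependence signature, strongest first:

```r
head(subset(res$reversal$morphine,
            select = c(compound, n_shared, score, perm_p, n_opposite)), 4)
#>   compound n_shared  score perm_p n_opposite
#> 1  CMP0012        2 -0.795  0.020          2
#> 2  CMP0010        2 -0.744  0.045          1
#> 3  CMP0147        2 -0.744  0.085          2
#> 4 CMP_R001        7 -0.733  0.040          7
```

`CMP_R001` is the planted exact negation of the *true* dependence
signature: it shares 7 genes with the detected signature, all regulated
in opposite directions. Compounds above it share only 2 genes each —
small overlaps reach extreme scores easily, which is why the table
should be read jointly: a strong candidate combines a negative score, a
substantial `n_shared`/`n_opposite`, and a small permutation p. Against
the exact planted signature (no detection noise), `CMP_R001` ranks
first in 100/100 simulations.

## Command line

A thin CLI wraps the same functions:

```sh
inst/cli/odmap simulate --out bundle --n-genes 1000 --seed 1
inst/cli/odmap de --bundle bundle --drug morphine --out degs.tsv
inst/cli/odmap run --config pipeline.yaml
```
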